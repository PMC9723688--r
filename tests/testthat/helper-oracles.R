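# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately use naive, loop-based logic so they share no code
# path with the package implementation they check.

ACGT <- c("A", "C", "G", "T")

# --- SAM fixture builder ----------------------------------------------------

# records: data.frame with qname, flag, contig, pos, mapq, cigar, seq
write_sam <- function(records, ref, path = tempfile(fileext = ".sam")) {
    hdr <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(ref), Biostrings::width(ref)))
    rec <- if (nrow(records))
        paste(records$qname, records$flag, records$contig, records$pos,
              records$mapq, records$cigar, "*", 0L, 0L, records$seq, "*",
              sep = "\t")
    else character()
    writeLines(c(hdr, rec), path)
    path
}

random_seq <- function(n) paste(sample(ACGT, n, replace = TRUE),
                                collapse = "")

# --- naive per-read, per-base pileup oracle ---------------------------------

# Walks each CIGAR with an explicit per-op loop and tallies bases in a plain
# nested list; returns a data.frame(contig, pos, base, count).
naive_pileup <- function(records) {
    tally <- list()
    for (i in seq_len(nrow(records))) {
        cig <- records$cigar[i]
        seq <- records$seq[i]
        toks <- regmatches(cig, gregexpr("[0-9]+[A-Z=]", cig))[[1]]
        rpos <- records$pos[i]
        qpos <- 1L
        for (tk in toks) {
            n <- as.integer(sub("[A-Z=]$", "", tk))
            op <- sub("^[0-9]+", "", tk)
            if (op %in% c("M", "=", "X")) {
                for (j in seq_len(n)) {
                    b <- substr(seq, qpos, qpos)
                    if (b %in% ACGT) {
                        key <- paste(records$contig[i], rpos, b)
                        tally[[key]] <- (tally[[key]] %||% 0L) + 1L
                    }
                    rpos <- rpos + 1L
                    qpos <- qpos + 1L
                }
            } else if (op %in% c("I", "S")) {
                qpos <- qpos + n
            } else if (op %in% c("D", "N")) {
                rpos <- rpos + n
            } # H consumes nothing
        }
    }
    if (!length(tally))
        return(data.frame(contig = character(), pos = integer(),
                          base = character(), count = integer()))
    parts <- strsplit(names(tally), " ", fixed = TRUE)
    data.frame(contig = vapply(parts, `[[`, "", 1L),
               pos = as.integer(vapply(parts, `[[`, "", 2L)),
               base = vapply(parts, `[[`, "", 3L),
               count = unlist(tally, use.names = FALSE),
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pileup object -> long data.frame(contig, pos, base, count) for comparison
pileup_long <- function(pileup) {
    df <- siteCounts(pileup)
    out <- do.call(rbind, lapply(ACGT, function(b) {
        d <- df[df[[b]] > 0, c("contig", "pos"), drop = FALSE]
        if (!nrow(d)) return(NULL)
        d$base <- b
        d$count <- df[[b]][df[[b]] > 0]
        d
    }))
    if (is.null(out))
        return(data.frame(contig = character(), pos = integer(),
                          base = character(), count = integer()))
    out[order(out$contig, out$pos, out$base), , drop = FALSE]
}

# random mapped SAM records over a reference, mixing plain, spliced,
# inserted, deleted and soft-clipped CIGARs
random_records <- function(n, ref) {
    recs <- lapply(seq_len(n), function(i) {
        ctg <- sample(names(ref), 1L)
        clen <- Biostrings::width(ref[ctg])
        style <- sample(c("m", "splice", "ins", "del", "clip"), 1L)
        m1 <- sample(5:20, 1L); m2 <- sample(5:20, 1L)
        if (style == "m") {
            cig <- sprintf("%dM", m1); qlen <- m1; span <- m1
        } else if (style == "splice") {
            gap <- sample(5:40, 1L)
            cig <- sprintf("%dM%dN%dM", m1, gap, m2)
            qlen <- m1 + m2; span <- m1 + gap + m2
        } else if (style == "ins") {
            ins <- sample(1:4, 1L)
            cig <- sprintf("%dM%dI%dM", m1, ins, m2)
            qlen <- m1 + ins + m2; span <- m1 + m2
        } else if (style == "del") {
            del <- sample(1:5, 1L)
            cig <- sprintf("%dM%dD%dM", m1, del, m2)
            qlen <- m1 + m2; span <- m1 + del + m2
        } else {
            s <- sample(1:5, 1L)
            cig <- sprintf("%dS%dM", s, m1)
            qlen <- s + m1; span <- m1
        }
        pos <- sample.int(max(1L, clen - span + 1L), 1L)
        data.frame(qname = sprintf("r%03d", i), flag = 0L, contig = ctg,
                   pos = pos, mapq = 60L, cigar = cig,
                   seq = random_seq(qlen), stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
}

# --- brute-force pooled-read search oracle ----------------------------------

# exact containment of the shorter sequence, covering variant offset vpos of
# the query; plain character scanning, no index
brute_pair_match <- function(query, vpos, pool_read) {
    if (nchar(pool_read) >= nchar(query)) {
        return(grepl(query, pool_read, fixed = TRUE))
    }
    m <- gregexpr(pool_read, query, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(FALSE)
    any(m <= vpos & vpos <= m + nchar(pool_read) - 1L)
}

rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))

# distinct pool read indices matched by any (query, vpos), optionally also
# via reverse complement
brute_pool_search <- function(queries, vpos, pool, revcomp = TRUE) {
    hits <- integer(0)
    for (p in seq_along(pool)) {
        for (q in seq_along(queries)) {
            ok <- brute_pair_match(queries[q], vpos[q], pool[p])
            if (!ok && revcomp)
                ok <- brute_pair_match(rc(queries[q]),
                                       nchar(queries[q]) - vpos[q] + 1L,
                                       pool[p])
            if (ok) { hits <- c(hits, p); break }
        }
    }
    hits
}

# --- brute-force 3' quality trim oracle -------------------------------------

# enumerate every suffix cut length m, score it with an explicit sum, keep
# the best positive score; among ties of the maximum, trim as little as
# necessary (smallest m)
brute_trim_keep <- function(q, cutoff) {
    n <- length(q)
    scores <- vapply(seq_len(n), function(m)
        sum(cutoff - q[(n - m + 1L):n]), numeric(1))
    best <- max(scores)
    if (best <= 0) return(n)
    n - min(which(scores == best))
}

# --- small alignment/call builders shared by filter tests -------------------

mk_pileup <- function(counts, source = "DNA") {
    new("Pileup", sampleId = "s", source = source, counts = counts,
        nSkipped = 0L)
}

one_call <- function(contig = "chr", pos = 10L, ref = "A", alt = "G",
                     depth = 50L, alt_count = 25L) {
    data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
               depth = depth, alt_count = alt_count,
               alt_frac = alt_count / depth, sample_id = "s",
               source = "RNA", stringsAsFactors = FALSE)
}

# an alignment set with reads supporting G at position `pos` of `ref`
support_aln <- function(ref, pos, n_sup = 3, n_ref = 3, read_len = 30L) {
    refchr <- as.character(ref[[1]])
    starts <- pmax(1L, pos - read_len + 5L) + seq_len(n_sup + n_ref) - 1L
    recs <- lapply(seq_along(starts), function(i) {
        s <- starts[i]
        sq <- substr(refchr, s, s + read_len - 1L)
        if (i <= n_sup) substr(sq, pos - s + 1L, pos - s + 1L) <- "G"
        data.frame(qname = sprintf("sup%d", i), flag = 0L,
                   contig = names(ref)[1], pos = s, mapq = 60L,
                   cigar = sprintf("%dM", nchar(sq)), seq = sq,
                   stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    readSamAlignments(write_sam(recs, ref), ref)
}

# --- shared simulated fixtures (built once per test run) --------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
    if (is.null(.fixture_cache[[name]]))
        assign(name, maker(), envir = .fixture_cache)
    get(name, envir = .fixture_cache)
}

small_config <- function(...) {
    defaults <- list(genomeLength = 6000L, nParalogPairs = 2L,
                     segmentLength = 1000L, divergence = 0.01,
                     nEditSites = 5L, editRate = 0.3, dnaDepth = 60,
                     rnaDepth = 60, readLength = 60L, errorRate = 0.005,
                     seed = 11L)
    do.call(simConfig, utils::modifyList(defaults, list(...)))
}

small_sim <- function() cached("small_sim", function()
    simulateEditingData(small_config()))
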