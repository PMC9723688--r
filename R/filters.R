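## The three elimination filters and their precedence-ordered composition.
## A candidate RNA variant site is explained away when (in this order):
##   1. the genomic DNA alignment shows the identical substitution at the
##      site (> dnaPresenceFrac of mapped DNA reads) -> DNA_MATCH;
##   2. an independent re-alignment of the same RNA reads no longer supports
##      the variant at calling thresholds -> ABSENT_IN_REALIGNMENT;
##   3. raw pooled gDNA reads contain a variant-supporting RNA read at 100%
##      identity over the full length of the shorter sequence, covering the
##      variant base -> POOLED_GENOMIC_MATCH (the remedy for collapsed
##      regions whose second copy never made it into the assembly);
## anything left is RETAINED as a credible editing / strain-variant site.

#' Eliminate RNA calls matched by genomic DNA polymorphisms
#'
#' A call is matched when the *identical* substitution (same site, same
#' alternate base) is present in the DNA pileup at a fraction strictly above
#' `dnaPresenceFrac` of the mapped DNA reads. A different alternate base at
#' the same site does not match. Sites with zero DNA coverage are *not*
#' matched and pass onward: absence of the locus from the assembly is
#' exactly the failure mode the pooled-read search addresses.
#'
#' @param calls a candidate-call `data.frame` from [callCandidates()].
#' @param dnaPileup a DNA [Pileup-class] built against the same reference,
#'   or `NULL` to skip the filter (all calls pass; a warning is emitted).
#' @param thresholds a [CallerThresholds-class] (uses `dnaPresenceFrac`).
#' @return A list with `matched` and `passed` data.frames; both carry
#'   evidence columns `dna_depth` and `dna_frac`.
#' @export
filterDnaMatch <- function(calls, dnaPileup,
                           thresholds = callerThresholds()) {
    if (is.null(dnaPileup)) {
        warning("no DNA pileup supplied; DNA-match filter skipped")
        calls$dna_depth <- rep(NA_integer_, nrow(calls))
        calls$dna_frac <- rep(NA_real_, nrow(calls))
        return(list(matched = calls[0, , drop = FALSE], passed = calls))
    }
    stopifnot(is(dnaPileup, "Pileup"))
    if (!nrow(calls)) {
        calls$dna_depth <- integer(0)
        calls$dna_frac <- numeric(0)
        return(list(matched = calls, passed = calls))
    }
    lk <- .pileupLookup(dnaPileup, calls$contig, calls$pos, calls$alt)
    calls$dna_depth <- lk$depth
    calls$dna_frac <- ifelse(lk$depth > 0L, lk$alt_count / lk$depth, 0)
    matched <- calls$dna_depth > 0L &
        calls$dna_frac > thresholds@dnaPresenceFrac
    list(matched = calls[matched, , drop = FALSE],
         passed = calls[!matched, , drop = FALSE])
}

#' Eliminate calls absent under an independent re-alignment
#'
#' Given a second pileup built from an independent alignment of the same RNA
#' reads (e.g. a newer spliced aligner with a restricted intron length), a
#' call is eliminated when the site/allele no longer satisfies the calling
#' thresholds there: insufficient depth, too few variant reads, or too low a
#' variant fraction. Zero coverage in the re-alignment eliminates the call.
#'
#' @param calls surviving candidate calls.
#' @param secondPileup the re-alignment RNA [Pileup-class], or `NULL` to
#'   skip the filter (all calls pass through unchanged; a warning is
#'   emitted).
#' @param thresholds a [CallerThresholds-class].
#' @return A list with `absent` and `passed` data.frames; both carry
#'   evidence columns `realn_depth`, `realn_alt_count`, `realn_frac`.
#' @export
filterAbsentInRealignment <- function(calls, secondPileup,
                                      thresholds = callerThresholds()) {
    if (is.null(secondPileup)) {
        warning("no re-alignment pileup supplied; absence filter skipped")
        calls$realn_depth <- rep(NA_integer_, nrow(calls))
        calls$realn_alt_count <- rep(NA_integer_, nrow(calls))
        calls$realn_frac <- rep(NA_real_, nrow(calls))
        return(list(absent = calls[0, , drop = FALSE], passed = calls))
    }
    stopifnot(is(secondPileup, "Pileup"))
    if (!nrow(calls)) {
        calls$realn_depth <- integer(0)
        calls$realn_alt_count <- integer(0)
        calls$realn_frac <- numeric(0)
        return(list(absent = calls, passed = calls))
    }
    lk <- .pileupLookup(secondPileup, calls$contig, calls$pos, calls$alt)
    calls$realn_depth <- lk$depth
    calls$realn_alt_count <- lk$alt_count
    calls$realn_frac <- ifelse(lk$depth > 0L, lk$alt_count / lk$depth, 0)
    still_called <- calls$realn_depth >= thresholds@minDepth &
        calls$realn_alt_count >= thresholds@minAltReads &
        calls$realn_frac >= thresholds@minAltFrac
    list(absent = calls[!still_called, , drop = FALSE],
         passed = calls[still_called, , drop = FALSE])
}

## --- pooled raw-read search -------------------------------------------------

## k-mer index over the pool: anchor k-mers at stride k (positions 1, k+1,
## 2k+1, ...). Any exact containment of a query of length >= 2k-1 within a
## pool read is guaranteed to share at least one anchor; shorter queries and
## pool reads shorter than k are handled by direct scan.
.poolKmerIndex <- function(pool_chr, k) {
    w <- nchar(pool_chr)
    long <- which(w >= k)
    if (!length(long)) {
        return(list(kmer = character(), read = integer(),
                    short_reads = seq_along(pool_chr), k = k))
    }
    n_anchor <- (w[long] - k) %/% k + 1L
    read_rep <- rep(long, n_anchor)
    starts <- (sequence(n_anchor) - 1L) * k + 1L
    kmers <- substring(pool_chr[read_rep], starts, starts + k - 1L)
    list(kmer = kmers, read = read_rep,
         short_reads = which(w < k), k = k)
}

## Distinct pool reads exactly matching `query` (full length of the shorter
## sequence, match covering variant offset `vpos` of the query). Index-based
## candidate retrieval with exact verification.
.poolMatches <- function(query, vpos, pool_chr, index) {
    k <- index$k
    q <- nchar(query)
    if (q >= 2L * k - 1L && length(index$kmer)) {
        qk <- substring(query, seq_len(q - k + 1L),
                        seq_len(q - k + 1L) + k - 1L)
        cand <- unique(index$read[index$kmer %in% qk])
        cand <- union(cand, index$short_reads)
    } else {
        cand <- seq_along(pool_chr)
    }
    if (!length(cand)) return(integer(0))
    hits <- logical(length(cand))
    pw <- nchar(pool_chr[cand])
    ## pool read at least as long as the query: query must appear verbatim
    ## (it contains the variant base by construction)
    ge <- pw >= q
    if (any(ge))
        hits[ge] <- grepl(query, pool_chr[cand[ge]], fixed = TRUE)
    ## pool read shorter: it must appear inside the query at an offset
    ## covering the variant base
    lt <- which(!ge)
    for (i in lt) {
        p <- pool_chr[cand[i]]
        m <- gregexpr(p, query, fixed = TRUE)[[1L]]
        if (m[1L] == -1L) next
        if (any(m <= vpos & vpos <= m + nchar(p) - 1L)) hits[i] <- TRUE
    }
    cand[hits]
}

#' Search raw pooled gDNA reads for variant-supporting RNA reads
#'
#' For each surviving call, the RNA reads whose aligned base at the site
#' equals the alternate allele are collected (sequences as aligned,
#' reference-forward). A call is eliminated as `POOLED_GENOMIC_MATCH` when
#' at least `minHits` distinct gDNA reads from the raw pool contain one of
#' those sequences at 100% identity over the full length of the shorter of
#' the two reads, with the match covering the variant base; reverse
#' complements are searched as well when `searchRevcomp` is set. This
#' rescues the case where the genomic copy carrying the allele was never
#' assembled, so no DNA alignment can reveal it.
#'
#' @param calls surviving candidate calls.
#' @param rnaAln the RNA `GAlignments` the calls were made from.
#' @param pool raw (post-QC, unaligned) gDNA reads as a `DNAStringSet`,
#'   `QualityScaledDNAStringSet` or character vector; `NULL` or empty skips
#'   the filter with a warning.
#' @param params a [PooledSearchParams-class].
#' @param thresholds a [CallerThresholds-class] (read-level filters, applied
#'   to `rnaAln` exactly as in [buildPileup()]).
#' @return A list with `matched` and `passed` data.frames; both carry the
#'   evidence column `pool_hits` (distinct matching gDNA reads).
#' @export
pooledGenomicSearch <- function(calls, rnaAln, pool,
                                params = pooledSearchParams(),
                                thresholds = callerThresholds()) {
    stopifnot(is(params, "PooledSearchParams"))
    if (is.null(pool) || length(pool) == 0L) {
        warning("empty gDNA read pool; pooled-read search skipped")
        calls$pool_hits <- rep(NA_integer_, nrow(calls))
        return(list(matched = calls[0, , drop = FALSE], passed = calls))
    }
    if (!nrow(calls)) {
        calls$pool_hits <- integer(0)
        return(list(matched = calls, passed = calls))
    }
    pool_chr <- as.character(pool)
    index <- .poolKmerIndex(pool_chr, params@kmerSize)
    aln <- .filterAlignments(rnaAln, thresholds)
    tab <- .alignedBaseTable(aln)
    seq_chr <- as.character(mcols(aln)$seq)
    hits <- integer(nrow(calls))
    for (i in seq_len(nrow(calls))) {
        sup <- tab[tab$contig == calls$contig[i] &
                   tab$pos == calls$pos[i] &
                   tab$base == calls$alt[i], , drop = FALSE]
        if (!nrow(sup)) next
        queries <- seq_chr[sup$read]
        vpos <- sup$qpos
        keep <- !duplicated(queries)
        queries <- queries[keep]; vpos <- vpos[keep]
        matched_reads <- integer(0)
        for (j in seq_along(queries)) {
            matched_reads <- union(
                matched_reads,
                .poolMatches(queries[j], vpos[j], pool_chr, index))
            if (params@searchRevcomp) {
                rc <- as.character(reverseComplement(DNAString(queries[j])))
                matched_reads <- union(
                    matched_reads,
                    .poolMatches(rc, nchar(queries[j]) - vpos[j] + 1L,
                                 pool_chr, index))
            }
        }
        hits[i] <- length(matched_reads)
    }
    calls$pool_hits <- hits
    matched <- hits >= params@minHits
    list(matched = calls[matched, , drop = FALSE],
         passed = calls[!matched, , drop = FALSE])
}

#' Classify every candidate site into exactly one category
#'
#' Applies the three elimination filters in fixed precedence order --
#' `DNA_MATCH`, then `ABSENT_IN_REALIGNMENT`, then `POOLED_GENOMIC_MATCH` --
#' and labels the survivors `RETAINED`. Optional inputs that are absent
#' (`NULL`) cause their filter to pass all calls through with a warning, so
#' every input call always receives exactly one category and the category
#' counts sum to the number of input calls.
#'
#' @param calls candidate calls from [callCandidates()] (or an external
#'   candidate list re-evaluated against the current pileups).
#' @param dnaPileup DNA [Pileup-class], or `NULL`.
#' @param rnaAln RNA `GAlignments` (needed for the pooled search), or
#'   `NULL`.
#' @param secondRnaPileup independent re-alignment RNA pileup, or `NULL`.
#' @param gdnaPool raw gDNA reads, or `NULL`.
#' @param thresholds a [CallerThresholds-class].
#' @param searchParams a [PooledSearchParams-class].
#' @return A `data.frame`: the input calls plus `category`, the per-filter
#'   evidence columns (`dna_depth`, `dna_frac`, `realn_depth`,
#'   `realn_alt_count`, `realn_frac`, `pool_hits`; `NA` where a filter never
#'   evaluated a call) and a compact text `evidence` column. Ordered by
#'   (contig, pos, alt).
#' @export
classifySites <- function(calls, dnaPileup = NULL, rnaAln = NULL,
                          secondRnaPileup = NULL, gdnaPool = NULL,
                          thresholds = callerThresholds(),
                          searchParams = pooledSearchParams()) {
    ev_cols <- c("dna_depth", "dna_frac", "realn_depth", "realn_alt_count",
                 "realn_frac", "pool_hits")
    s1 <- filterDnaMatch(calls, dnaPileup, thresholds)
    s2 <- filterAbsentInRealignment(s1$passed, secondRnaPileup, thresholds)
    if (!is.null(gdnaPool) && length(gdnaPool) && is.null(rnaAln))
        stop("pooled-read search requires the RNA alignments (rnaAln)")
    s3 <- if (is.null(gdnaPool) || !length(gdnaPool)) {
        p <- s2$passed
        p$pool_hits <- rep(NA_integer_, nrow(p))
        list(matched = p[0, , drop = FALSE], passed = p)
    } else {
        pooledGenomicSearch(s2$passed, rnaAln, gdnaPool, searchParams,
                            thresholds)
    }
    parts <- list(DNA_MATCH = s1$matched,
                  ABSENT_IN_REALIGNMENT = s2$absent,
                  POOLED_GENOMIC_MATCH = s3$matched,
                  RETAINED = s3$passed)
    out <- list()
    for (cat in names(parts)) {
        p <- parts[[cat]]
        if (is.null(p)) next
        for (cc in ev_cols)
            if (!cc %in% names(p))
                p[[cc]] <- rep(if (cc %in% c("dna_frac", "realn_frac"))
                    NA_real_ else NA_integer_, nrow(p))
        p$category <- rep(cat, nrow(p))
        out[[cat]] <- p
    }
    out <- do.call(rbind, out)
    if (is.null(out) || !nrow(out)) {
        out <- calls
        for (cc in ev_cols) out[[cc]] <- numeric(0)
        out$category <- character(0)
        out$evidence <- character(0)
        return(out)
    }
    out$evidence <- .verdictEvidence(out)
    out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.verdictEvidence <- function(v) {
    vapply(seq_len(nrow(v)), function(i) {
        switch(v$category[i],
            DNA_MATCH = sprintf("dna_frac=%.4g;dna_depth=%d",
                                v$dna_frac[i], v$dna_depth[i]),
            ABSENT_IN_REALIGNMENT = sprintf(
                "realn_depth=%d;realn_alt=%d;realn_frac=%.4g",
                v$realn_depth[i], v$realn_alt_count[i], v$realn_frac[i]),
            POOLED_GENOMIC_MATCH = sprintf("pool_hits=%d", v$pool_hits[i]),
            RETAINED = "")
    }, character(1L))
}
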