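## Deterministic desk-scale simulator of the three phenomena the pipeline
## must separate:
##   PARALOG_ARTIFACT  a near-identical segmental duplication collapsed to a
##                     single copy in the reference: reads from both copies
##                     stack on one locus and the copies' divergent positions
##                     masquerade as ~50% "RNA variants" (with matching DNA
##                     variants -- unless the DNA alignment is withheld, in
##                     which case only the raw gDNA pool knows the truth);
##   TRUE_EDIT         genuine per-molecule A-to-G editing at a configurable
##                     rate, with no genomic support;
##   STRAIN_SNP        the RNA-source isolate differs from the DNA-source
##                     isolate at engineered positions, so RNA shows a
##                     near-fixed variant that DNA lacks.

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.INTRON_LEN <- 300L

#' Simulation configuration
#'
#' Defines the synthetic study conditions: a haploid genome in which each of
#' `nParalogPairs` segments of `segmentLength` bases exists in two copies
#' diverged at a per-base rate `divergence`, but is collapsed to a single
#' copy in the reference; genuine A-to-G editing at `nEditSites` transcript
#' positions with per-molecule rate `editRate`; and `nStrainSnps`
#' strain-difference SNPs carried only by the RNA-source isolate (0 disables
#' strain mode). Reads of `readLength` bases are drawn to mean fold-coverage
#' `dnaDepth` / `rnaDepth` with per-base error `errorRate`.
#'
#' @slot genomeLength reference contig length in bases.
#' @slot nParalogPairs number of collapsed duplication pairs.
#' @slot segmentLength length of each duplicated / transcribed segment.
#' @slot divergence per-base substitution probability between paralog
#'   copies.
#' @slot nEditSites number of engineered genuine editing sites.
#' @slot editRate fraction of RNA molecules edited per site.
#' @slot nStrainSnps number of strain-difference SNPs (0 = same isolate).
#' @slot dnaDepth,rnaDepth mean fold-coverage of the DNA / RNA libraries.
#' @slot readLength read length in bases.
#' @slot errorRate per-base sequencing error probability.
#' @slot includeIntron insert a 300 bp intron into the edited transcript so
#'   spliced (M,N,M) RNA alignments occur.
#' @slot withholdDnaFor paralog-pair indices whose DNA alignments are
#'   omitted from the DNA SAM (the raw pool keeps the reads), exercising the
#'   pooled-read search.
#' @slot seed integer seed; identical seeds give byte-identical outputs.
#' @export
setClass("SimConfig", representation(
    genomeLength   = "integer",
    nParalogPairs  = "integer",
    segmentLength  = "integer",
    divergence     = "numeric",
    nEditSites     = "integer",
    editRate       = "numeric",
    nStrainSnps    = "integer",
    dnaDepth       = "numeric",
    rnaDepth       = "numeric",
    readLength     = "integer",
    errorRate      = "numeric",
    includeIntron  = "logical",
    withholdDnaFor = "integer",
    seed           = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    for (p in c("divergence", "editRate", "errorRate")) {
        v <- slot(object, p)
        if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0,1]", p))
    }
    if (object@segmentLength < 3L * object@readLength)
        msg <- c(msg, "segmentLength must be >= 3 * readLength")
    if (object@dnaDepth < 1 || object@rnaDepth < 1)
        msg <- c(msg, "depths must be >= 1")
    n_feat <- object@nParalogPairs + 2L
    spacer <- (object@genomeLength - n_feat * object@segmentLength) %/%
        (n_feat + 1L)
    if (spacer < object@readLength)
        msg <- c(msg, paste0("genomeLength too small for the requested ",
                             "features (spacers must be >= readLength)"))
    if (length(object@withholdDnaFor) &&
        (any(object@withholdDnaFor < 1L) ||
         any(object@withholdDnaFor > object@nParalogPairs)))
        msg <- c(msg, "withholdDnaFor indices out of range")
    if (length(msg)) msg else TRUE
})

#' @param genomeLength,nParalogPairs,segmentLength,divergence,nEditSites,editRate,nStrainSnps,dnaDepth,rnaDepth,readLength,errorRate,includeIntron,withholdDnaFor,seed
#'   see slot documentation.
#' @return A `SimConfig` object.
#' @rdname SimConfig-class
#' @examples
#' simConfig(seed = 1)
#' @export
simConfig <- function(genomeLength = 30000L, nParalogPairs = 2L,
                      segmentLength = 5000L, divergence = 0.01,
                      nEditSites = 20L, editRate = 0.3, nStrainSnps = 0L,
                      dnaDepth = 60, rnaDepth = 60, readLength = 100L,
                      errorRate = 0.005, includeIntron = FALSE,
                      withholdDnaFor = integer(0), seed = 1L) {
    new("SimConfig",
        genomeLength = as.integer(genomeLength),
        nParalogPairs = as.integer(nParalogPairs),
        segmentLength = as.integer(segmentLength),
        divergence = as.numeric(divergence),
        nEditSites = as.integer(nEditSites),
        editRate = as.numeric(editRate),
        nStrainSnps = as.integer(nStrainSnps),
        dnaDepth = as.numeric(dnaDepth),
        rnaDepth = as.numeric(rnaDepth),
        readLength = as.integer(readLength),
        errorRate = as.numeric(errorRate),
        includeIntron = isTRUE(includeIntron),
        withholdDnaFor = as.integer(withholdDnaFor),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: %d bp genome, %d paralog pair(s) of %d bp at ",
        "divergence %.3g,\n  %d edit site(s) at rate %.3g, %d strain ",
        "SNP(s); depth DNA %gx / RNA %gx,\n  reads %d bp, error %.3g, ",
        "seed %d\n"),
        object@genomeLength, object@nParalogPairs, object@segmentLength,
        object@divergence, object@nEditSites, object@editRate,
        object@nStrainSnps, object@dnaDepth, object@rnaDepth,
        object@readLength, object@errorRate, object@seed))
})

## Feature layout on the collapsed reference contig: paralog segments first,
## then the edited transcript, then the strain-SNP transcript, evenly spaced.
.simLayout <- function(config) {
    n_feat <- config@nParalogPairs + 2L
    L <- config@segmentLength
    spacer <- (config@genomeLength - n_feat * L) %/% (n_feat + 1L)
    starts <- spacer + (seq_len(n_feat) - 1L) * (L + spacer) + 1L
    data.frame(
        feature = c(if (config@nParalogPairs)
                        paste0("paralog", seq_len(config@nParalogPairs)),
                    "edit_tx", "snp_tx"),
        type = c(rep("paralog", config@nParalogPairs), "edit_tx", "snp_tx"),
        start = starts, end = starts + L - 1L,
        stringsAsFactors = FALSE)
}

#' Generate the true genome, the collapsed reference and the truth table
#'
#' Builds a random haploid genome on one contig (`chr1`), adds for each
#' paralog pair a second, diverged copy of its segment as an extra contig of
#' the *true* genome (`dup1`, `dup2`, ...) that is missing from the
#' collapsed reference, engineers editing sites (reference base A, alternate
#' G, on the edited transcript) and strain SNPs (transitions, on the strain
#' transcript), and records every engineered site in a truth table with its
#' expected variant allele fraction (0.5 for paralog divergence,
#' `editRate` for genuine edits, 1 for strain SNPs). Engineered positions
#' never collide by construction.
#'
#' @param config a [SimConfig-class].
#' @return A list with elements `trueGenome` (`DNAStringSet`: `chr1` +
#'   duplicate contigs), `collapsedRef` (`DNAStringSet`: `chr1` only),
#'   `truth` (`data.frame`: `contig`, `pos`, `truth_class`, `ref`, `alt`,
#'   `expected_alt_frac`), `features` (the layout table), `dupSeqs`
#'   (character, diverged copy per pair), `strainSnps`, `editSites`,
#'   `intron` (`NULL` unless `includeIntron`), and `config`.
#' @export
simulateGenome <- function(config = simConfig()) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    bases <- c("A", "C", "G", "T")
    chr1 <- sample(bases, config@genomeLength, replace = TRUE)
    feats <- .simLayout(config)
    L <- config@segmentLength

    truth <- list()
    dup_seqs <- character(0)
    for (i in seq_len(config@nParalogPairs)) {
        f <- feats[feats$feature == paste0("paralog", i), ]
        seg <- chr1[f$start:f$end]
        div_pos <- which(stats::runif(L) < config@divergence)
        dup <- seg
        if (length(div_pos)) {
            dup[div_pos] <- .TRANSITION[seg[div_pos]]
            truth[[length(truth) + 1L]] <- data.frame(
                contig = "chr1", pos = f$start + div_pos - 1L,
                truth_class = "PARALOG_ARTIFACT",
                ref = seg[div_pos], alt = dup[div_pos],
                expected_alt_frac = 0.5, paralog_pair = i,
                stringsAsFactors = FALSE)
        }
        dup_seqs[paste0("dup", i)] <- paste(dup, collapse = "")
    }

    fe <- feats[feats$feature == "edit_tx", ]
    intron <- NULL
    edit_candidates <- fe$start:fe$end
    if (config@includeIntron) {
        i_start <- fe$start + (L - .INTRON_LEN) %/% 2L
        intron <- list(start = i_start, end = i_start + .INTRON_LEN - 1L)
        edit_candidates <- setdiff(edit_candidates, intron$start:intron$end)
    }
    edit_candidates <- edit_candidates[chr1[edit_candidates] == "A"]
    ## keep sites clear of segment ends so reads can cover them
    edit_candidates <- edit_candidates[
        edit_candidates >= fe$start + config@readLength &
        edit_candidates <= fe$end - config@readLength]
    if (length(edit_candidates) < config@nEditSites)
        stop("segment too short (or too few A bases) for ",
             config@nEditSites, " edit sites")
    edit_pos <- sort(edit_candidates[
        sample.int(length(edit_candidates), config@nEditSites)])
    if (config@nEditSites > 0L)
        truth[[length(truth) + 1L]] <- data.frame(
            contig = "chr1", pos = edit_pos, truth_class = "TRUE_EDIT",
            ref = "A", alt = "G", expected_alt_frac = config@editRate,
            paralog_pair = NA_integer_, stringsAsFactors = FALSE)

    fs <- feats[feats$feature == "snp_tx", ]
    snps <- NULL
    if (config@nStrainSnps > 0L) {
        cand <- (fs$start + config@readLength):(fs$end - config@readLength)
        snp_pos <- sort(cand[sample.int(length(cand), config@nStrainSnps)])
        snps <- data.frame(
            contig = "chr1", pos = snp_pos,
            ref = chr1[snp_pos],
            alt = unname(.TRANSITION[chr1[snp_pos]]),
            stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
            contig = "chr1", pos = snps$pos, truth_class = "STRAIN_SNP",
            ref = snps$ref, alt = snps$alt, expected_alt_frac = 1,
            paralog_pair = NA_integer_, stringsAsFactors = FALSE)
    }

    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(contig = character(), pos = integer(),
                   truth_class = character(), ref = character(),
                   alt = character(), expected_alt_frac = numeric(),
                   paralog_pair = integer(), stringsAsFactors = FALSE)
    truth <- truth[order(truth$contig, truth$pos), , drop = FALSE]
    rownames(truth) <- NULL

    chr1_str <- paste(chr1, collapse = "")
    true_genome <- DNAStringSet(c(c(chr1 = chr1_str), dup_seqs))
    list(trueGenome = true_genome,
         collapsedRef = DNAStringSet(c(chr1 = chr1_str)),
         truth = truth, features = feats, dupSeqs = dup_seqs,
         strainSnps = snps,
         editSites = if (config@nEditSites) edit_pos else integer(0),
         intron = intron, config = config)
}

## Draw uniformly placed reads from one sequence; returns data.frame of
## (start, seq) before error injection. n = round(depth * len / readLength).
.drawReads <- function(seq_chr, depth, read_len) {
    len <- nchar(seq_chr)
    n <- max(0L, as.integer(round(depth * len / read_len)))
    if (n == 0L || len < read_len)
        return(data.frame(start = integer(), seq = character(),
                          stringsAsFactors = FALSE))
    starts <- sample.int(len - read_len + 1L, n, replace = TRUE)
    data.frame(start = starts,
               seq = substring(seq_chr, starts, starts + read_len - 1L),
               stringsAsFactors = FALSE)
}

## Per-base sequencing errors at rate `rate` on a character vector of reads.
.injectErrors <- function(seqs, rate) {
    if (rate <= 0 || !length(seqs)) return(seqs)
    bases <- c("A", "C", "G", "T")
    vapply(seqs, function(s) {
        n <- nchar(s)
        hit <- which(stats::runif(n) < rate)
        if (!length(hit)) return(s)
        v <- strsplit(s, "", fixed = TRUE)[[1L]]
        for (h in hit) {
            v[h] <- sample(setdiff(bases, v[h]), 1L)
        }
        paste(v, collapse = "")
    }, character(1L), USE.NAMES = FALSE)
}

#' Simulate DNA and RNA sequencing reads
#'
#' DNA reads are drawn uniformly from every true-genome contig (so both
#' copies of each duplication contribute); RNA reads are drawn from the
#' transcribed intervals: both paralog copies, the edited transcript (with
#' the intron spliced out when enabled) and the strain transcript carrying
#' the RNA-isolate SNP alleles. Each RNA read covering an engineered edit
#' site carries G there with probability `editRate` (each read standing for
#' one cDNA molecule). Per-base errors are applied at `errorRate` and a
#' constant Phred quality consistent with that rate is emitted. Each read is
#' assigned a random strand; FASTQ sequences are in read orientation,
#' provenance keeps the reference-forward sequence for alignment placement.
#'
#' @param sim output of [simulateGenome()].
#' @param config a [SimConfig-class]; defaults to the one inside `sim`.
#' @return A list with `dna`/`rna` (`QualityScaledDNAStringSet`, read
#'   orientation) and `dnaInfo`/`rnaInfo` provenance tables (`id`, `origin`
#'   contig or template, `start` in origin coordinates, `strand`, `fwd_seq`).
#' @export
simulateReads <- function(sim, config = sim$config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed + 1L)
    rl <- config@readLength
    feats <- sim$features

    ## DNA: uniformly from every true-genome contig
    dna_parts <- list()
    for (ctg in names(sim$trueGenome)) {
        d <- .drawReads(as.character(sim$trueGenome[[ctg]]),
                        config@dnaDepth, rl)
        d$origin <- rep(ctg, nrow(d))
        dna_parts[[ctg]] <- d
    }
    dna <- do.call(rbind, dna_parts)

    ## RNA templates mapped back to chr1 by placeAlignments()
    chr1 <- as.character(sim$collapsedRef[["chr1"]])
    templates <- list()
    for (i in seq_len(config@nParalogPairs)) {
        f <- feats[feats$feature == paste0("paralog", i), ]
        templates[[paste0("tx_paralog", i, "_refcopy")]] <-
            substring(chr1, f$start, f$end)
        templates[[paste0("tx_paralog", i, "_dupcopy")]] <-
            sim$dupSeqs[[paste0("dup", i)]]
    }
    fe <- feats[feats$feature == "edit_tx", ]
    edit_template <- substring(chr1, fe$start, fe$end)
    if (!is.null(sim$intron)) {
        e1 <- substring(chr1, fe$start, sim$intron$start - 1L)
        e2 <- substring(chr1, sim$intron$end + 1L, fe$end)
        edit_template <- paste0(e1, e2)
    }
    templates[["tx_edit"]] <- edit_template
    fs <- feats[feats$feature == "snp_tx", ]
    snp_template <- substring(chr1, fs$start, fs$end)
    if (!is.null(sim$strainSnps)) {
        v <- strsplit(snp_template, "", fixed = TRUE)[[1L]]
        off <- sim$strainSnps$pos - fs$start + 1L
        v[off] <- sim$strainSnps$alt
        snp_template <- paste(v, collapse = "")
    }
    templates[["tx_snp"]] <- snp_template

    rna_parts <- list()
    for (tx in names(templates)) {
        d <- .drawReads(templates[[tx]], config@rnaDepth, rl)
        d$origin <- rep(tx, nrow(d))
        rna_parts[[tx]] <- d
    }
    rna <- do.call(rbind, rna_parts)

    ## per-molecule editing on the edited transcript (template coordinates)
    if (length(sim$editSites) && nrow(rna)) {
        tpos <- sim$editSites - fe$start + 1L
        if (!is.null(sim$intron)) {
            after <- sim$editSites > sim$intron$end
            tpos[after] <- tpos[after] - .INTRON_LEN
        }
        is_edit_tx <- rna$origin == "tx_edit"
        for (k in seq_along(tpos)) {
            covers <- is_edit_tx & rna$start <= tpos[k] &
                rna$start + rl - 1L >= tpos[k]
            idx <- which(covers)
            if (!length(idx)) next
            edited <- idx[stats::runif(length(idx)) < config@editRate]
            if (!length(edited)) next
            off <- tpos[k] - rna$start[edited] + 1L
            tmp <- rna$seq[edited]
            substring(tmp, off, off) <- "G"
            rna$seq[edited] <- tmp
        }
    }

    dna$seq <- .injectErrors(dna$seq, config@errorRate)
    rna$seq <- .injectErrors(rna$seq, config@errorRate)

    q <- if (config@errorRate > 0)
        min(40L, as.integer(round(-10 * log10(config@errorRate)))) else 40L
    finish <- function(df, prefix) {
        if (is.null(df) || !nrow(df)) {
            info <- data.frame(id = character(), origin = character(),
                               start = integer(), strand = character(),
                               fwd_seq = character(),
                               stringsAsFactors = FALSE)
            reads <- QualityScaledDNAStringSet(DNAStringSet(),
                                               PhredQuality(character()))
            return(list(reads = reads, info = info))
        }
        df$id <- sprintf("%s_%06d", prefix, seq_len(nrow(df)))
        df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
        out_seq <- DNAStringSet(df$seq)
        rev <- df$strand == "-"
        if (any(rev))
            out_seq[rev] <- reverseComplement(out_seq[rev])
        names(out_seq) <- df$id
        quals <- PhredQuality(vapply(width(out_seq), function(w)
            paste(rep(rawToChar(as.raw(q + 33L)), w), collapse = ""),
            character(1L)))
        reads <- QualityScaledDNAStringSet(out_seq, quals)
        info <- data.frame(id = df$id, origin = df$origin,
                           start = df$start, strand = df$strand,
                           fwd_seq = df$seq, stringsAsFactors = FALSE)
        list(reads = reads, info = info)
    }
    d <- finish(dna, "gdna")
    r <- finish(rna, "rna")
    list(dna = d$reads, rna = r$reads,
         dnaInfo = d$info, rnaInfo = r$info)
}

#' Place simulated reads on the collapsed reference
#'
#' Emits alignments directly from known read provenance instead of running
#' an aligner: every read is placed at its origin coordinate mapped onto the
#' collapsed reference, duplicate-copy origins mapped to the reference-copy
#' coordinates. CIGARs are all-M except RNA reads spanning the optional
#' intron, which get an M,N,M CIGAR. DNA reads overlapping a paralog pair
#' listed in `withholdDnaFor` are omitted from the DNA alignments (the raw
#' pool still has them). SEQ is reference-forward; minus-strand reads carry
#' flag 16.
#'
#' @param reads output of [simulateReads()].
#' @param sim output of [simulateGenome()].
#' @param config a [SimConfig-class]; defaults to the one inside `sim`.
#' @return A list with `dna` and `rna` `GAlignments` (mcols `qname`, `flag`,
#'   `mapq`, `seq`), ready for [buildPileup()] or [writeSamAlignments()].
#' @export
placeAlignments <- function(reads, sim, config = sim$config) {
    stopifnot(is(config, "SimConfig"))
    feats <- sim$features
    rl <- config@readLength
    feat_start <- stats::setNames(feats$start, feats$feature)

    ## --- DNA ---
    di <- reads$dnaInfo
    dup_origin <- grepl("^dup", di$origin)
    pair_of <- rep(NA_integer_, nrow(di))
    pair_of[dup_origin] <- as.integer(sub("^dup", "", di$origin[dup_origin]))
    pos <- unname(ifelse(dup_origin,
                         feat_start[paste0("paralog", pair_of)] +
                             di$start - 1L,
                         di$start))
    keep <- rep(TRUE, nrow(di))
    for (i in config@withholdDnaFor) {
        f <- feats[feats$feature == paste0("paralog", i), ]
        keep <- keep & !(pos <= f$end & pos + rl - 1L >= f$start)
    }
    dna_aln <- .makeGAlignments(
        qname = di$id[keep], contig = "chr1", pos = as.integer(pos[keep]),
        cigar = sprintf("%dM", rl), strand = di$strand[keep],
        seq = di$fwd_seq[keep], reference = sim$collapsedRef)

    ## --- RNA ---
    ri <- reads$rnaInfo
    n <- nrow(ri)
    pos <- integer(n); cig <- character(n)
    fe <- feats[feats$feature == "edit_tx", ]
    fs <- feats[feats$feature == "snp_tx", ]
    e1len <- if (!is.null(sim$intron)) sim$intron$start - fe$start else NA
    for (j in seq_len(n)) {
        org <- ri$origin[j]; s <- ri$start[j]
        if (startsWith(org, "tx_paralog")) {
            pair <- as.integer(sub("^tx_paralog([0-9]+)_.*$", "\\1", org))
            pos[j] <- feat_start[paste0("paralog", pair)] + s - 1L
            cig[j] <- sprintf("%dM", rl)
        } else if (org == "tx_snp") {
            pos[j] <- fs$start + s - 1L
            cig[j] <- sprintf("%dM", rl)
        } else {  # tx_edit, possibly spliced
            if (is.null(sim$intron)) {
                pos[j] <- fe$start + s - 1L
                cig[j] <- sprintf("%dM", rl)
            } else if (s + rl - 1L <= e1len) {
                pos[j] <- fe$start + s - 1L
                cig[j] <- sprintf("%dM", rl)
            } else if (s > e1len) {
                pos[j] <- sim$intron$end + 1L + (s - e1len - 1L)
                cig[j] <- sprintf("%dM", rl)
            } else {
                a <- e1len - s + 1L
                pos[j] <- fe$start + s - 1L
                cig[j] <- sprintf("%dM%dN%dM", a, .INTRON_LEN, rl - a)
            }
        }
    }
    rna_aln <- .makeGAlignments(
        qname = ri$id, contig = "chr1", pos = pos, cigar = cig,
        strand = ri$strand, seq = ri$fwd_seq,
        reference = sim$collapsedRef)
    list(dna = dna_aln, rna = rna_aln)
}

.makeGAlignments <- function(qname, contig, pos, cigar, strand, seq,
                             reference) {
    n <- length(qname)
    contig <- rep_len(contig, n)
    cigar <- rep_len(cigar, n)
    gal <- GAlignments(
        seqnames = Rle(factor(contig, levels = names(reference))),
        pos = as.integer(pos), cigar = cigar,
        strand = BiocGenerics::strand(strand))
    mcols(gal) <- DataFrame(
        qname = qname,
        flag = ifelse(strand == "-", 16L, 0L),
        mapq = rep(60L, n),
        seq = DNAStringSet(seq))
    metadata(gal)$nSkippedUnmapped <- 0L
    gal
}

#' Write the simulator truth table
#'
#' @param truth the truth `data.frame` from [simulateGenome()].
#' @param path output TSV path (1-based positions, sorted by contig, pos).
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
    truth <- truth[order(truth$contig, truth$pos), , drop = FALSE]
    utils::write.table(truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a simulator truth table
#'
#' @param path path written by [writeTruthTable()].
#' @return A `data.frame`.
#' @export
readTruthTable <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset, optionally writing all files
#'
#' Runs [simulateGenome()], [simulateReads()] and [placeAlignments()] and,
#' when `outdir` is given, writes `true_genome.fa`, `collapsed_ref.fa`,
#' `gdna.fastq`, `rna.fastq`, `gdna.sam`, `rna.sam`, `truth.tsv` and a
#' `config.txt` echo of the resolved parameters.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory, or `NULL` for in-memory only.
#' @return A list with `sim`, `reads`, `aln` and (when written) `paths`.
#' @export
simulateEditingData <- function(config = simConfig(), outdir = NULL) {
    sim <- simulateGenome(config)
    reads <- simulateReads(sim, config)
    aln <- placeAlignments(reads, sim, config)
    out <- list(sim = sim, reads = reads, aln = aln)
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        p <- function(f) file.path(outdir, f)
        writeReferenceGenome(sim$trueGenome, p("true_genome.fa"))
        writeReferenceGenome(sim$collapsedRef, p("collapsed_ref.fa"))
        writeReads(reads$dna, p("gdna.fastq"))
        writeReads(reads$rna, p("rna.fastq"))
        writeSamAlignments(aln$dna, sim$collapsedRef, p("gdna.sam"))
        writeSamAlignments(aln$rna, sim$collapsedRef, p("rna.sam"))
        writeTruthTable(sim$truth, p("truth.tsv"))
        slots <- slotNames(config)
        writeLines(sprintf("%s: %s", slots,
                           vapply(slots, function(s)
                               paste(format(slot(config, s)),
                                     collapse = ","), character(1L))),
                   p("config.txt"))
        out$paths <- stats::setNames(
            as.list(vapply(c("true_genome.fa", "collapsed_ref.fa",
                             "gdna.fastq", "rna.fastq", "gdna.sam",
                             "rna.sam", "truth.tsv", "config.txt"),
                           p, character(1L))),
            c("true_genome", "collapsed_ref", "gdna_fastq", "rna_fastq",
              "gdna_sam", "rna_sam", "truth", "config"))
    }
    out
}

#' Genome-to-genome alignment blocks for a simulated reassembly
#'
#' Emulates what a whole-genome aligner reports when the collapsed reference
#' is compared against the true (fully resolved) genome: one full-length
#' self block for `chr1`, plus, for every paralog pair, a block mapping the
#' reference copy's segment onto the duplicate contig at the pair's percent
#' identity. Sites inside collapsed segments therefore lift to two separate
#' regions (`SPLIT_MULTI`), the collapse signature.
#'
#' @param sim output of [simulateGenome()].
#' @return A block `data.frame` in the [readCoordsBlocks()] layout.
#' @export
collapsedCoordsBlocks <- function(sim) {
    config <- sim$config
    feats <- sim$features
    blocks <- data.frame(
        old_contig = "chr1", old_start = 1,
        old_end = config@genomeLength,
        new_contig = "chr1", new_start = 1,
        new_end = config@genomeLength,
        pct_identity = 100, reverse = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(config@nParalogPairs)) {
        f <- feats[feats$feature == paste0("paralog", i), ]
        seg <- substring(as.character(sim$collapsedRef[["chr1"]]),
                         f$start, f$end)
        dup <- sim$dupSeqs[[paste0("dup", i)]]
        nd <- sum(strsplit(seg, "")[[1L]] != strsplit(dup, "")[[1L]])
        ident <- 100 * (1 - nd / nchar(seg))
        blocks <- rbind(blocks, data.frame(
            old_contig = "chr1", old_start = f$start, old_end = f$end,
            new_contig = paste0("dup", i), new_start = 1,
            new_end = nchar(dup), pct_identity = ident, reverse = FALSE,
            stringsAsFactors = FALSE))
    }
    blocks
}
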