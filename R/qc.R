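#' @importFrom IRanges narrow
NULL

## Replicates the read preprocessing applied before alignment:
## exact de-duplication -> 3' quality trimming at Q20 -> length filter at
## 40 bp, in that fixed order.

#' Remove exact duplicate reads
#'
#' Keeps the first occurrence of each exact full-length sequence and drops
#' later identical ones (PCR-duplicate removal on raw reads). Sequences of
#' different length are never duplicates; no reverse-complement collapsing
#' is attempted.
#'
#' @param reads a `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @return The de-duplicated read set, with attributes `nKept` and
#'   `nDropped`.
#' @examples
#' r <- Biostrings::DNAStringSet(c(a = "AAAA", b = "AAAA", c = "CCCC"))
#' dedupReads(r)
#' @export
dedupReads <- function(reads) {
    dup <- duplicated(as.character(reads))
    out <- reads[!dup]
    attr(out, "nKept") <- sum(!dup)
    attr(out, "nDropped") <- sum(dup)
    out
}

## Optimal 3' suffix cut for one quality vector: walking in from the 3' end,
## accumulate (cutoff - q); cut where the running sum is maximal and
## positive. Returns the number of bases to keep.
.trim_keep_length <- function(q, cutoff) {
    s <- cumsum(cutoff - rev(q))
    m <- which.max(s)
    if (s[m] > 0L) length(q) - m else length(q)
}

#' Trim low-quality 3' ends
#'
#' Applies the standard partial-sums 3' trimmer (the rule used by
#' cutadapt-family trimmers): from the 3' end accumulate
#' `cutoff - quality` and cut at the position where the running sum is
#' maximal and positive. A read of uniformly high quality is untouched; a
#' read entirely below the cutoff is trimmed to length zero. Sequence and
#' qualities are truncated consistently.
#'
#' @param reads a `QualityScaledDNAStringSet` (qualities required).
#' @param params a [QcParams-class] object.
#' @return A `QualityScaledDNAStringSet` of the same length with trimmed
#'   reads, plus attribute `nBasesTrimmed`.
#' @export
trimReadQuality <- function(reads, params = qcParams()) {
    stopifnot(is(params, "QcParams"))
    if (!is(reads, "QualityScaledDNAStringSet"))
        stop("quality trimming requires per-base qualities ",
             "(FASTA input has none)")
    if (!length(reads)) {
        attr(reads, "nBasesTrimmed") <- 0L
        return(reads)
    }
    quals <- as(quality(reads), "IntegerList")
    cutoff <- params@qualityCutoff
    keep <- vapply(quals, .trim_keep_length, integer(1L), cutoff = cutoff)
    trimmed <- sum(width(reads) - keep)
    out <- narrow(reads, start = 1L, end = keep)
    attr(out, "nBasesTrimmed") <- as.integer(trimmed)
    out
}

#' Drop short reads
#'
#' Removes reads strictly shorter than `minLength` (the cutoff itself is
#' kept: a 40-base read passes the default).
#'
#' @param reads a `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @param params a [QcParams-class] object.
#' @return The filtered read set with attributes `nKept` and `nDropped`.
#' @export
filterReadLength <- function(reads, params = qcParams()) {
    stopifnot(is(params, "QcParams"))
    keep <- width(reads) >= params@minLength
    out <- reads[keep]
    attr(out, "nKept") <- sum(keep)
    attr(out, "nDropped") <- sum(!keep)
    out
}

#' Full read quality-control pipeline
#'
#' De-duplicate, 3'-quality-trim, then length-filter, in that fixed order.
#' FASTA input (no qualities) skips the trimming stage.
#'
#' @param reads a `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @param params a [QcParams-class] object.
#' @return The cleaned read set; attribute `qcSummary` holds a named vector
#'   with `nIn`, `nDuplicates`, `nBasesTrimmed`, `nShort`, `nOut`.
#' @examples
#' r <- Biostrings::DNAStringSet(c(a = paste(rep("A", 50), collapse = ""),
#'                                 b = "ACGT"))
#' attr(qcReads(r), "qcSummary")
#' @export
qcReads <- function(reads, params = qcParams()) {
    n_in <- length(reads)
    reads <- dedupReads(reads)
    n_dup <- attr(reads, "nDropped")
    trimmed <- 0L
    if (is(reads, "QualityScaledDNAStringSet")) {
        reads <- trimReadQuality(reads, params)
        trimmed <- attr(reads, "nBasesTrimmed")
    }
    reads <- filterReadLength(reads, params)
    n_short <- attr(reads, "nDropped")
    attr(reads, "qcSummary") <- c(nIn = n_in, nDuplicates = n_dup,
                                  nBasesTrimmed = trimmed, nShort = n_short,
                                  nOut = length(reads))
    reads
}
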