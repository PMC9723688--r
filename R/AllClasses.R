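#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Read preprocessing parameters
#'
#' Container for the read quality-control settings: the Phred cutoff used by
#' the 3' quality trimmer and the minimum read length retained after trimming.
#'
#' @slot qualityCutoff Phred quality cutoff; bases scoring below it at the
#'   3' end are trimmed. Default 20.
#' @slot minLength minimum read length in bases kept after trimming;
#'   strictly shorter reads are dropped. Default 40.
#'
#' @seealso [qcReads()], [trimReadQuality()], [filterReadLength()]
#' @export
setClass("QcParams", representation(
    qualityCutoff = "integer",
    minLength     = "integer"
))

setValidity("QcParams", function(object) {
    msg <- character()
    if (length(object@qualityCutoff) != 1L || is.na(object@qualityCutoff) ||
        object@qualityCutoff < 0L)
        msg <- c(msg, "qualityCutoff must be a single non-negative integer")
    if (length(object@minLength) != 1L || is.na(object@minLength) ||
        object@minLength < 1L)
        msg <- c(msg, "minLength must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' @param qualityCutoff Phred cutoff for 3' trimming (default 20).
#' @param minLength minimum retained read length in bases (default 40).
#' @return A `QcParams` object.
#' @rdname QcParams-class
#' @examples
#' qcParams()
#' qcParams(qualityCutoff = 25, minLength = 50)
#' @export
qcParams <- function(qualityCutoff = 20L, minLength = 40L) {
    new("QcParams",
        qualityCutoff = as.integer(qualityCutoff),
        minLength     = as.integer(minLength))
}

#' Variant-calling thresholds
#'
#' Thresholds applied when candidate variant sites are called from a pileup
#' and when RNA calls are compared with the genomic DNA pileup. A site/allele
#' is called only when total depth is at least `minDepth`, the alternate
#' allele is seen in at least `minAltReads` reads and in at least a
#' `minAltFrac` fraction of the depth. An RNA call is considered matched by
#' genomic DNA when the identical alternate allele exceeds (strictly) a
#' `dnaPresenceFrac` fraction of the mapped DNA reads at the site. Reads
#' whose SAM flag intersects `excludedFlagMask` (default 1024, the PCR/optical
#' duplicate bit) or whose mapping quality is below `minMapq` never enter a
#' pileup.
#'
#' @slot minDepth minimum total mapped reads at a site (default 20).
#' @slot minAltReads minimum variant-supporting reads (default 5).
#' @slot minAltFrac minimum variant allele fraction (default 0.10).
#' @slot dnaPresenceFrac DNA variant fraction above which an RNA call is
#'   matched; the comparison is strict (default 0.05).
#' @slot excludedFlagMask SAM flag bits that exclude a read (default 1024).
#' @slot minMapq minimum mapping quality (default 0).
#'
#' @seealso [callCandidates()], [filterDnaMatch()]
#' @export
setClass("CallerThresholds", representation(
    minDepth         = "integer",
    minAltReads      = "integer",
    minAltFrac       = "numeric",
    dnaPresenceFrac  = "numeric",
    excludedFlagMask = "integer",
    minMapq          = "integer"
))

setValidity("CallerThresholds", function(object) {
    msg <- character()
    if (object@minDepth < 1L)
        msg <- c(msg, "minDepth must be >= 1")
    if (object@minAltReads < 0L)
        msg <- c(msg, "minAltReads must be >= 0")
    if (object@minAltFrac < 0 || object@minAltFrac > 1)
        msg <- c(msg, "minAltFrac must lie in [0, 1]")
    if (object@dnaPresenceFrac < 0 || object@dnaPresenceFrac > 1)
        msg <- c(msg, "dnaPresenceFrac must lie in [0, 1]")
    if (object@excludedFlagMask < 0L)
        msg <- c(msg, "excludedFlagMask must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @param minDepth,minAltReads,minAltFrac,dnaPresenceFrac,excludedFlagMask,minMapq
#'   see slot documentation.
#' @return A `CallerThresholds` object.
#' @rdname CallerThresholds-class
#' @examples
#' callerThresholds()
#' callerThresholds(minDepth = 10, minAltFrac = 0.2)
#' @export
callerThresholds <- function(minDepth = 20L, minAltReads = 5L,
                             minAltFrac = 0.10, dnaPresenceFrac = 0.05,
                             excludedFlagMask = 1024L, minMapq = 0L) {
    new("CallerThresholds",
        minDepth         = as.integer(minDepth),
        minAltReads      = as.integer(minAltReads),
        minAltFrac       = as.numeric(minAltFrac),
        dnaPresenceFrac  = as.numeric(dnaPresenceFrac),
        excludedFlagMask = as.integer(excludedFlagMask),
        minMapq          = as.integer(minMapq))
}

#' Pooled raw-read search parameters
#'
#' Settings for the search of variant-supporting RNA reads against the pool
#' of raw (unaligned) genomic DNA reads. A candidate site is explained by the
#' genome when at least `minHits` pooled gDNA reads contain a
#' variant-supporting RNA read at 100% identity over the full length of the
#' shorter of the two sequences, with the match covering the variant base.
#' The search uses a k-mer index prefilter followed by exact verification.
#'
#' @slot kmerSize k-mer length of the pool index (default 31).
#' @slot minHits minimum number of matching pooled gDNA reads (default 1).
#' @slot searchRevcomp also search reverse complements (default TRUE).
#'
#' @seealso [pooledGenomicSearch()]
#' @export
setClass("PooledSearchParams", representation(
    kmerSize      = "integer",
    minHits       = "integer",
    searchRevcomp = "logical"
))

setValidity("PooledSearchParams", function(object) {
    msg <- character()
    if (object@kmerSize < 11L)
        msg <- c(msg, "kmerSize must be >= 11")
    if (object@minHits < 1L)
        msg <- c(msg, "minHits must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param kmerSize,minHits,searchRevcomp see slot documentation.
#' @return A `PooledSearchParams` object.
#' @rdname PooledSearchParams-class
#' @export
pooledSearchParams <- function(kmerSize = 31L, minHits = 1L,
                               searchRevcomp = TRUE) {
    new("PooledSearchParams",
        kmerSize      = as.integer(kmerSize),
        minHits       = as.integer(minHits),
        searchRevcomp = isTRUE(searchRevcomp))
}

#' Cross-assembly liftover parameters
#'
#' @slot window bases flanking a site on each side when collecting overlapping
#'   genome-to-genome alignment blocks (default 75, about one short-read
#'   insert half-width).
#' @slot splitGap minimum separation, in bases on the target assembly, for two
#'   mapped hits to count as separate regions; hits on different contigs are
#'   always separate (default 10000).
#'
#' @seealso [mapSite()], [diffVariantSets()]
#' @export
setClass("LiftoverParams", representation(
    window   = "integer",
    splitGap = "integer"
))

setValidity("LiftoverParams", function(object) {
    msg <- character()
    if (object@window < 1L)   msg <- c(msg, "window must be >= 1")
    if (object@splitGap < 1L) msg <- c(msg, "splitGap must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param window,splitGap see slot documentation.
#' @return A `LiftoverParams` object.
#' @rdname LiftoverParams-class
#' @export
liftoverParams <- function(window = 75L, splitGap = 10000L) {
    new("LiftoverParams",
        window   = as.integer(window),
        splitGap = as.integer(splitGap))
}

#' Per-position base counts from one alignment set
#'
#' A `Pileup` tallies, for every covered reference position, how many aligned
#' reads place each of the four bases there. Ambiguous bases (N) and gaps are
#' never counted, so depth is always the sum of the four base counts.
#' Zero-depth positions are absent from the table.
#'
#' @slot sampleId sample identifier.
#' @slot source `"RNA"` or `"DNA"`.
#' @slot counts a `data.frame` with columns `contig`, `pos` (1-based),
#'   `A`, `C`, `G`, `T`, sorted by (contig, pos).
#' @slot nSkipped number of alignment records excluded by flag/mapq filters.
#'
#' @seealso [buildPileup()], [callCandidates()], [siteFraction()]
#' @export
setClass("Pileup", representation(
    sampleId = "character",
    source   = "character",
    counts   = "data.frame",
    nSkipped = "integer"
))

setValidity("Pileup", function(object) {
    msg <- character()
    if (!object@source %in% c("RNA", "DNA"))
        msg <- c(msg, "source must be 'RNA' or 'DNA'")
    need <- c("contig", "pos", "A", "C", "G", "T")
    if (!all(need %in% names(object@counts)))
        msg <- c(msg, sprintf("counts must have columns %s",
                              paste(need, collapse = ", ")))
    else {
        cnt <- as.matrix(object@counts[, c("A", "C", "G", "T")])
        if (nrow(cnt) && (any(cnt < 0) || any(cnt != round(cnt))))
            msg <- c(msg, "base counts must be non-negative integers")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn Pileup-class sample identifier.
#' @param x,object a `Pileup`.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname Pileup-class
#' @export
setMethod("sampleId", "Pileup", function(x) x@sampleId)

#' @describeIn Pileup-class `"RNA"` or `"DNA"`.
#' @export
setGeneric("pileupSource", function(x) standardGeneric("pileupSource"))

#' @rdname Pileup-class
#' @export
setMethod("pileupSource", "Pileup", function(x) x@source)

#' @describeIn Pileup-class the per-position count table (with a `depth`
#'   column added).
#' @export
setGeneric("siteCounts", function(x) standardGeneric("siteCounts"))

#' @rdname Pileup-class
#' @export
setMethod("siteCounts", "Pileup", function(x) {
    df <- x@counts
    df$depth <- df$A + df$C + df$G + df$T
    df
})

setMethod("show", "Pileup", function(object) {
    cat(sprintf("Pileup [%s] sample '%s': %d covered position%s",
                object@source, object@sampleId, nrow(object@counts),
                if (nrow(object@counts) == 1L) "" else "s"))
    if (object@nSkipped > 0L)
        cat(sprintf(" (%d records skipped by filters)", object@nSkipped))
    cat("\n")
    if (nrow(object@counts)) {
        cat(sprintf("  contigs: %s\n",
                    paste(unique(object@counts$contig), collapse = ", ")))
    }
})

setMethod("show", "QcParams", function(object) {
    cat(sprintf("QcParams: 3' quality cutoff Q%d, minimum length %d bp\n",
                object@qualityCutoff, object@minLength))
})

setMethod("show", "CallerThresholds", function(object) {
    cat(sprintf(paste0(
        "CallerThresholds: depth >= %d, alt reads >= %d, alt fraction >= ",
        "%.3g;\n  DNA match when alt fraction > %.3g; flag mask %d; ",
        "mapq >= %d\n"),
        object@minDepth, object@minAltReads, object@minAltFrac,
        object@dnaPresenceFrac, object@excludedFlagMask, object@minMapq))
})

setMethod("show", "PooledSearchParams", function(object) {
    cat(sprintf(
        "PooledSearchParams: k = %d, min hits = %d, reverse complement %s\n",
        object@kmerSize, object@minHits,
        if (object@searchRevcomp) "on" else "off"))
})

setMethod("show", "LiftoverParams", function(object) {
    cat(sprintf("LiftoverParams: window +/-%d bp, split gap %d bp\n",
                object@window, object@splitGap))
})
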