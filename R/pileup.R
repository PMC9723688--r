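#' @importFrom data.table as.data.table dcast melt
NULL

## Expand filtered alignments into one row per aligned base:
## (read index, contig, 1-based reference position, base character).
## M/=/X blocks contribute one observation per reference position; I and S
## consume query only, D and N reference only, H nothing. Coordinates refer
## to SEQ as stored in the SAM record (soft clips included in query space).
.alignedBaseTable <- function(aln) {
    empty <- data.frame(read = integer(), contig = character(),
                        pos = integer(), qpos = integer(),
                        base = character(), stringsAsFactors = FALSE)
    if (!length(aln)) return(empty)
    cig <- GenomicAlignments::cigar(aln)
    qr <- cigarRangesAlongQuerySpace(cig, ops = c("M", "=", "X"))
    rr <- cigarRangesAlongReferenceSpace(cig,
                                         pos = GenomicAlignments::start(aln),
                                         ops = c("M", "=", "X"))
    nblk <- S4Vectors::elementNROWS(qr)
    read_of_block <- rep(seq_along(aln), nblk)
    qs <- unlist(IRanges::start(qr), use.names = FALSE)
    w  <- unlist(IRanges::width(qr), use.names = FALSE)
    rs <- unlist(IRanges::start(rr), use.names = FALSE)
    if (!length(w) || sum(w) == 0L) return(empty)
    blk <- rep(seq_along(w), w)
    off <- sequence(w) - 1L
    read_idx <- read_of_block[blk]
    ref_pos <- rs[blk] + off
    q_pos <- qs[blk] + off
    seq_str <- as.character(mcols(aln)$seq)
    chars <- strsplit(paste(seq_str, collapse = ""), "", fixed = TRUE)[[1L]]
    seq_off <- cumsum(c(0L, nchar(seq_str)))[read_idx]
    base <- chars[seq_off + q_pos]
    data.frame(
        read = read_idx,
        contig = as.character(GenomicAlignments::seqnames(aln))[read_idx],
        pos = ref_pos, qpos = q_pos, base = base, stringsAsFactors = FALSE)
}

## Apply flag-mask and mapq read filters; returns the kept subset with
## attribute nSkipped.
.filterAlignments <- function(aln, thresholds) {
    flag <- mcols(aln)$flag
    mapq <- mcols(aln)$mapq
    keep <- bitwAnd(flag, thresholds@excludedFlagMask) == 0L &
        mapq >= thresholds@minMapq
    out <- aln[keep]
    attr(out, "nSkipped") <- sum(!keep)
    out
}

#' Build a per-position base-count pileup
#'
#' Walks every retained alignment's CIGAR and tallies the four bases at each
#' covered reference position. Reads whose SAM flag intersects
#' `excludedFlagMask` (default 1024, duplicates) or whose mapping quality is
#' below `minMapq` are skipped; `N` base observations are discarded. Base
#' qualities are not used.
#'
#' @param aln a `GAlignments` from [readSamAlignments()] or
#'   [placeAlignments()].
#' @param reference named `DNAStringSet`; every alignment contig must be
#'   present and no alignment may extend past a contig end.
#' @param thresholds a [CallerThresholds-class] (only the read-level filters
#'   are used here).
#' @param sampleId sample identifier stored in the pileup.
#' @param source `"RNA"` or `"DNA"`.
#' @return A [Pileup-class] object.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr = "ACGTACGT"))
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr\tLN:8",
#'              "r1\t0\tchr\t1\t60\t4M\t*\t0\t0\tACGT\t*"), sam)
#' buildPileup(readSamAlignments(sam), ref)
#' @export
buildPileup <- function(aln, reference, thresholds = callerThresholds(),
                        sampleId = "sample", source = c("RNA", "DNA")) {
    source <- match.arg(source)
    stopifnot(is(thresholds, "CallerThresholds"))
    contigs <- unique(as.character(GenomicAlignments::seqnames(aln)))
    unknown <- setdiff(contigs, names(reference))
    if (length(unknown))
        stop("alignments reference unknown contig(s): ",
             paste(unknown, collapse = ", "))
    aln <- .filterAlignments(aln, thresholds)
    n_skipped <- attr(aln, "nSkipped")
    tab <- .alignedBaseTable(aln)
    tab <- tab[tab$base %in% c("A", "C", "G", "T"), , drop = FALSE]
    if (nrow(tab)) {
        clen <- stats::setNames(width(reference), names(reference))
        over <- tab$pos > clen[tab$contig] | tab$pos < 1L
        if (any(over))
            stop("alignment extends outside contig ",
                 tab$contig[over][1L], " (position ", tab$pos[over][1L], ")")
        dt <- as.data.table(tab)
        counts <- as.data.frame(dcast(dt[, list(N = .N),
                                         by = c("contig", "pos", "base")],
                                      contig + pos ~ base,
                                      value.var = "N", fill = 0L))
        for (b in c("A", "C", "G", "T"))
            if (!b %in% names(counts)) counts[[b]] <- 0L
        counts <- counts[, c("contig", "pos", "A", "C", "G", "T")]
        counts$contig <- as.character(counts$contig)
        cf <- factor(counts$contig, levels = names(reference))
        counts <- counts[order(cf, counts$pos), , drop = FALSE]
        rownames(counts) <- NULL
    } else {
        counts <- data.frame(contig = character(), pos = integer(),
                             A = integer(), C = integer(), G = integer(),
                             T = integer(), stringsAsFactors = FALSE)
    }
    new("Pileup", sampleId = sampleId, source = source, counts = counts,
        nSkipped = as.integer(n_skipped))
}

## Vectorized lookup of (depth, alt_count) in a pileup for site/allele
## vectors; absent sites report depth 0. Returns rows in query order.
.pileupLookup <- function(pileup, contig, pos, alt) {
    q <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                    alt = as.character(alt), stringsAsFactors = FALSE)
    p <- pileup@counts
    if (!nrow(p) || !nrow(q)) {
        q$depth <- 0L
        q$alt_count <- 0L
        return(q)
    }
    key_q <- paste(q$contig, q$pos)
    key_p <- paste(p$contig, p$pos)
    hit <- match(key_q, key_p)
    depth <- p$A[hit] + p$C[hit] + p$G[hit] + p$T[hit]
    depth[is.na(hit)] <- 0L
    cnt <- as.matrix(p[, c("A", "C", "G", "T")])
    col <- match(q$alt, c("A", "C", "G", "T"))
    alt_count <- integer(nrow(q))
    ok <- !is.na(hit) & !is.na(col)
    alt_count[ok] <- cnt[cbind(hit[ok], col[ok])]
    q$depth <- as.integer(depth)
    q$alt_count <- alt_count
    q
}

#' Variant allele fraction at one site
#'
#' Returns the fraction of mapped reads carrying `alt` at the given
#' position, together with the depth. A site absent from the pileup (zero
#' coverage) reports fraction 0, depth 0 and `zeroCoverage = TRUE` so that
#' callers can distinguish "no variant" from "no data".
#'
#' @param pileup a [Pileup-class].
#' @param contig,pos site (1-based).
#' @param alt queried alternate base.
#' @return A list with elements `frac`, `depth`, `zeroCoverage`.
#' @export
siteFraction <- function(pileup, contig, pos, alt) {
    r <- .pileupLookup(pileup, contig, pos, alt)
    if (r$depth == 0L)
        return(list(frac = 0, depth = 0L, zeroCoverage = TRUE))
    list(frac = r$alt_count / r$depth, depth = r$depth, zeroCoverage = FALSE)
}

#' Call candidate variant sites from a pileup
#'
#' Applies the depth/support thresholds: a site enters consideration only
#' with total depth `>= minDepth`; every non-reference base seen in
#' `>= minAltReads` reads and `>= minAltFrac` of the depth yields one call
#' (multiple qualifying alternate bases at one site yield multiple calls,
#' matched per allele downstream). Sites whose reference base is `N` are
#' never called. Only single-nucleotide substitutions are considered, in
#' reference-forward orientation.
#'
#' @param pileup a [Pileup-class].
#' @param reference the `DNAStringSet` the pileup was built against.
#' @param thresholds a [CallerThresholds-class].
#' @return A `data.frame` of calls with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`, `depth`, `alt_count`, `alt_frac`, `sample_id`, `source`,
#'   ordered by (contig, pos, alt).
#' @export
callCandidates <- function(pileup, reference,
                           thresholds = callerThresholds()) {
    stopifnot(is(pileup, "Pileup"), is(thresholds, "CallerThresholds"))
    empty <- data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character(),
                        depth = integer(), alt_count = integer(),
                        alt_frac = numeric(), sample_id = character(),
                        source = character(), stringsAsFactors = FALSE)
    cnt <- pileup@counts
    if (!nrow(cnt)) return(empty)
    unknown <- setdiff(unique(cnt$contig), names(reference))
    if (length(unknown))
        stop("pileup references contig(s) absent from reference: ",
             paste(unknown, collapse = ", "))
    cnt$depth <- cnt$A + cnt$C + cnt$G + cnt$T
    cnt <- cnt[cnt$depth >= thresholds@minDepth, , drop = FALSE]
    if (!nrow(cnt)) return(empty)
    cnt$ref <- .refBaseAt(reference, cnt$contig, cnt$pos)
    cnt <- cnt[cnt$ref %in% c("A", "C", "G", "T"), , drop = FALSE]
    if (!nrow(cnt)) return(empty)
    long <- as.data.frame(melt(as.data.table(cnt),
                               id.vars = c("contig", "pos", "ref", "depth"),
                               measure.vars = c("A", "C", "G", "T"),
                               variable.name = "alt",
                               value.name = "alt_count",
                               variable.factor = FALSE))
    long <- long[long$alt != long$ref &
                 long$alt_count >= thresholds@minAltReads &
                 long$alt_count / long$depth >= thresholds@minAltFrac, ,
                 drop = FALSE]
    if (!nrow(long)) return(empty)
    long$alt_frac <- long$alt_count / long$depth
    cf <- factor(long$contig, levels = names(reference))
    long <- long[order(cf, long$pos, long$alt), , drop = FALSE]
    out <- long[, c("contig", "pos", "ref", "alt", "depth", "alt_count",
                    "alt_frac")]
    out$sample_id <- pileup@sampleId
    out$source <- pileup@source
    rownames(out) <- NULL
    out
}

## Reference base at 1-based positions, vectorized per contig.
.refBaseAt <- function(reference, contig, pos) {
    out <- character(length(pos))
    for (ctg in unique(contig)) {
        i <- contig == ctg
        hits <- Biostrings::extractAt(reference[[ctg]],
                                      IRanges(pos[i], pos[i]))
        out[i] <- as.character(hits)
    }
    out
}
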