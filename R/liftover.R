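## Cross-assembly site liftover. A candidate site whose neighbourhood maps
## to two or more well-separated regions of an independent assembly of the
## same reads sits in a collapsed duplication: the "polymorphism" is the
## divergence between the copies, not an RNA/DNA difference.

#' Map one site through genome-to-genome alignment blocks
#'
#' Every alignment block overlapping the window `[pos - window, pos +
#' window]` on the source assembly contributes one hit; the site position is
#' interpolated linearly within the block (mirrored for reverse-oriented
#' blocks). Hits are then clustered into regions: two hits belong to
#' separate regions when they fall on different target contigs or are at
#' least `splitGap` bases apart.
#'
#' @param blocks a block table from [readCoordsBlocks()].
#' @param contig,pos site on the source ("old") assembly, 1-based.
#' @param params a [LiftoverParams-class].
#' @return A list with elements `contig`, `pos`, `status` (`"UNIQUE"`,
#'   `"SPLIT_MULTI"` or `"UNMAPPED"`), `nRegions`, and `hits` (a
#'   `data.frame` with `new_contig`, `new_pos`, `pct_identity`).
#' @examples
#' blocks <- data.frame(old_contig = "c1", old_start = 1, old_end = 100,
#'                      new_contig = "n1", new_start = 1, new_end = 100,
#'                      pct_identity = 99, reverse = FALSE)
#' mapSite(blocks, "c1", 40)$status
#' @export
mapSite <- function(blocks, contig, pos, params = liftoverParams()) {
    stopifnot(is(params, "LiftoverParams"))
    w <- params@window
    ov <- blocks[blocks$old_contig == contig &
                 blocks$old_start <= pos + w &
                 blocks$old_end >= pos - w, , drop = FALSE]
    if (!nrow(ov)) {
        return(list(contig = contig, pos = pos, status = "UNMAPPED",
                    nRegions = 0L,
                    hits = data.frame(new_contig = character(),
                                      new_pos = numeric(),
                                      pct_identity = numeric())))
    }
    new_pos <- ifelse(ov$reverse,
                      ov$new_start - (pos - ov$old_start),
                      ov$new_start + (pos - ov$old_start))
    hits <- data.frame(new_contig = ov$new_contig, new_pos = new_pos,
                       pct_identity = ov$pct_identity,
                       stringsAsFactors = FALSE)
    o <- order(hits$new_contig, hits$new_pos)
    h <- hits[o, , drop = FALSE]
    brk <- c(TRUE, h$new_contig[-1L] != h$new_contig[-nrow(h)] |
                 diff(h$new_pos) >= params@splitGap)
    n_regions <- sum(brk)
    status <- if (n_regions >= 2L) "SPLIT_MULTI" else "UNIQUE"
    rownames(hits) <- NULL
    list(contig = contig, pos = pos, status = status,
         nRegions = as.integer(n_regions), hits = hits)
}

#' Lift a set of sites to another assembly
#'
#' Vectorised wrapper around [mapSite()]: one row per input site with its
#' status and, for sites hitting a single region, the coordinates of the
#' best (highest-identity) hit.
#'
#' @param blocks a block table from [readCoordsBlocks()].
#' @param sites a `data.frame` with columns `contig` and `pos`.
#' @param params a [LiftoverParams-class].
#' @return A `data.frame` with columns `contig`, `pos`, `status`,
#'   `n_regions`, `new_contig`, `new_pos` (the latter two `NA` unless status
#'   is `UNIQUE`).
#' @export
liftSites <- function(blocks, sites, params = liftoverParams()) {
    n <- nrow(sites)
    out <- data.frame(contig = as.character(sites$contig),
                      pos = as.integer(sites$pos),
                      status = character(n), n_regions = integer(n),
                      new_contig = NA_character_, new_pos = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        r <- mapSite(blocks, out$contig[i], out$pos[i], params)
        out$status[i] <- r$status
        out$n_regions[i] <- r$nRegions
        if (r$status == "UNIQUE") {
            best <- which.max(r$hits$pct_identity)
            out$new_contig[i] <- r$hits$new_contig[best]
            out$new_pos[i] <- r$hits$new_pos[best]
        }
    }
    out
}

#' Compare variant sets across two assemblies of the same reads
#'
#' Partitions the old-assembly calls by what the reassembly did to them and
#' reports the calls the new assembly introduced: (a) `eliminated` -- old
#' calls whose unique image carries no matching new call (the reassembly
#' dissolved the variant); (b) `collapse_explained` -- old calls whose
#' neighbourhood maps to two or more separate regions (`SPLIT_MULTI`), the
#' collapsed-duplication signature; (c) `assembly_introduced` -- new calls
#' at positions that are not the image of any old call. Also returned:
#' `preserved` (unique image with a matching new call) and `unmapped`.
#' Matching means identical target position and alternate allele.
#'
#' @param oldCalls calls on the old assembly (needs `contig`, `pos`, `alt`).
#' @param newCalls calls on the new assembly.
#' @param blocks genome-to-genome blocks, old vs new.
#' @param params a [LiftoverParams-class].
#' @return A list of data.frames: `eliminated`, `collapse_explained`,
#'   `assembly_introduced`, `preserved`, `unmapped`, plus `lift` (the
#'   per-old-call liftover table).
#' @export
diffVariantSets <- function(oldCalls, newCalls, blocks,
                            params = liftoverParams()) {
    lift <- liftSites(blocks, oldCalls, params)
    stopifnot(nrow(lift) == nrow(oldCalls))
    new_key <- paste(newCalls$contig, newCalls$pos, newCalls$alt)
    img_key <- ifelse(lift$status == "UNIQUE",
                      paste(lift$new_contig, lift$new_pos, oldCalls$alt),
                      NA_character_)
    has_match <- !is.na(img_key) & img_key %in% new_key

    split_multi <- lift$status == "SPLIT_MULTI"
    unmapped <- lift$status == "UNMAPPED"
    eliminated <- lift$status == "UNIQUE" & !has_match
    preserved <- lift$status == "UNIQUE" & has_match

    ## images of *all* old-call hits (any status), to decide which new calls
    ## are genuinely introduced by the reassembly
    img_pos <- character(0)
    for (i in seq_len(nrow(oldCalls))) {
        r <- mapSite(blocks, oldCalls$contig[i], oldCalls$pos[i], params)
        if (nrow(r$hits))
            img_pos <- c(img_pos, paste(r$hits$new_contig, r$hits$new_pos))
    }
    introduced <- !(paste(newCalls$contig, newCalls$pos) %in% img_pos)

    list(eliminated = oldCalls[eliminated, , drop = FALSE],
         collapse_explained = oldCalls[split_multi, , drop = FALSE],
         assembly_introduced = newCalls[introduced, , drop = FALSE],
         preserved = oldCalls[preserved, , drop = FALSE],
         unmapped = oldCalls[unmapped, , drop = FALSE],
         lift = lift)
}
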