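fwd_block <- function(old_contig = "c1", old_start = 1, old_end = 100,
                      new_contig = "n1", new_start = 1, new_end = 100,
                      pct = 99, reverse = FALSE) {
    data.frame(old_contig = old_contig, old_start = old_start,
               old_end = old_end, new_contig = new_contig,
               new_start = new_start, new_end = new_end,
               pct_identity = pct, reverse = reverse,
               stringsAsFactors = FALSE)
}

test_that("single-block sites lift uniquely with offset arithmetic", {
    blk <- fwd_block(old_start = 11, old_end = 110, new_start = 501,
                     new_end = 600)
    r <- mapSite(blk, "c1", 40)
    expect_equal(r$status, "UNIQUE")
    expect_equal(r$hits$new_pos, 501 + (40 - 11))

    # reverse-oriented blocks mirror the offset
    rev <- fwd_block(old_start = 11, old_end = 110, new_start = 600,
                     new_end = 501, reverse = TRUE)
    r <- mapSite(rev, "c1", 40)
    expect_equal(r$hits$new_pos, 600 - (40 - 11))

    # no overlapping block
    expect_equal(mapSite(blk, "c1", 5000)$status, "UNMAPPED")
    expect_equal(mapSite(blk, "other", 40)$status, "UNMAPPED")
})

test_that("split detection follows the contig / distance clustering rule", {
    two_contigs <- rbind(fwd_block(new_contig = "n1"),
                         fwd_block(new_contig = "n2", new_start = 1,
                                   new_end = 100))
    r <- mapSite(two_contigs, "c1", 50)
    expect_equal(r$status, "SPLIT_MULTI")
    expect_equal(r$nRegions, 2L)

    # two hits on one contig, closer than splitGap: a single region
    near <- rbind(fwd_block(), fwd_block(new_start = 2001, new_end = 2100))
    expect_equal(mapSite(near, "c1", 50)$status, "UNIQUE")
    # beyond splitGap: separate regions
    far <- rbind(fwd_block(), fwd_block(new_start = 50001, new_end = 50100))
    expect_equal(mapSite(far, "c1", 50)$status, "SPLIT_MULTI")
    # the split threshold is configurable
    expect_equal(mapSite(near, "c1", 50,
                         liftoverParams(splitGap = 100))$status,
                 "SPLIT_MULTI")
})

test_that("mapSite is independent of block input order", {
    set.seed(8)
    blocks <- do.call(rbind, lapply(1:6, function(i)
        fwd_block(old_start = i * 30, old_end = i * 30 + 99,
                  new_contig = sample(c("n1", "n2"), 1),
                  new_start = i * 5000, new_end = i * 5000 + 99)))
    for (pos in c(40, 95, 150)) {
        a <- mapSite(blocks, "c1", pos)
        b <- mapSite(blocks[sample(nrow(blocks)), ], "c1", pos)
        expect_equal(a$status, b$status)
        expect_equal(a$nRegions, b$nRegions)
        o1 <- a$hits[order(a$hits$new_contig, a$hits$new_pos), ]
        o2 <- b$hits[order(b$hits$new_contig, b$hits$new_pos), ]
        rownames(o1) <- rownames(o2) <- NULL
        expect_equal(o1, o2)
    }
})

test_that("self-alignment lifts every in-bounds site onto itself", {
    blocks <- rbind(
        fwd_block("c1", 1, 5000, "c1", 1, 5000, pct = 100),
        fwd_block("c2", 1, 3000, "c2", 1, 3000, pct = 100))
    set.seed(19)
    sites <- data.frame(contig = sample(c("c1", "c2"), 20, replace = TRUE),
                        pos = sample(200:2800, 20))
    lifted <- liftSites(blocks, sites)
    expect_true(all(lifted$status == "UNIQUE"))
    expect_equal(lifted$new_contig, sites$contig)
    expect_equal(lifted$new_pos, as.numeric(sites$pos))
})

test_that("variant-set diff partitions old calls and spots introductions", {
    calls <- function(contig, pos, alt) {
        data.frame(contig = contig, pos = pos, ref = "A", alt = alt,
                   stringsAsFactors = FALSE)
    }
    self <- fwd_block("c1", 1, 1000, "c1", 1, 1000, pct = 100)
    old <- calls("c1", c(100L, 300L), c("G", "T"))

    # identical assemblies, identical calls: nothing changes
    d <- diffVariantSets(old, old, self)
    expect_equal(nrow(d$eliminated), 0L)
    expect_equal(nrow(d$collapse_explained), 0L)
    expect_equal(nrow(d$assembly_introduced), 0L)
    expect_equal(nrow(d$preserved), 2L)

    # a split region explains its call; a dissolved call is eliminated
    blocks <- rbind(self,
                    fwd_block("c1", 250, 350, "n_extra", 1, 101, pct = 98))
    new <- calls("c1", 100L, "G")   # the 300/T call is gone
    d <- diffVariantSets(old, new, blocks)
    expect_equal(d$collapse_explained$pos, 300L)
    expect_equal(nrow(d$eliminated), 0L)   # 300 is split, not eliminated
    expect_equal(nrow(d$assembly_introduced), 0L)

    # a brand-new call away from any image is introduced
    new2 <- rbind(new, calls("c1", 900L, "C"))
    d2 <- diffVariantSets(old, new2, blocks)
    expect_equal(d2$assembly_introduced$pos, 900L)

    # partition: no old call lands in two categories
    ids <- c(paste(d2$eliminated$pos), paste(d2$collapse_explained$pos),
             paste(d2$preserved$pos), paste(d2$unmapped$pos))
    expect_equal(anyDuplicated(ids), 0L)
    expect_equal(length(ids), nrow(old))
})

test_that("a simulated reassembly explains collapsed-paralog artifacts", {
    s <- small_sim()
    th <- callerThresholds()
    ref <- s$sim$collapsedRef
    rp <- buildPileup(s$aln$rna, ref, th, "sim", "RNA")
    calls <- callCandidates(rp, ref, th)
    truth <- s$sim$truth
    art_key <- paste(truth$contig[truth$truth_class == "PARALOG_ARTIFACT"],
                     truth$pos[truth$truth_class == "PARALOG_ARTIFACT"])
    art_calls <- calls[paste(calls$contig, calls$pos) %in% art_key, ]
    expect_gt(nrow(art_calls), 0L)
    blocks <- collapsedCoordsBlocks(s$sim)
    d <- diffVariantSets(art_calls, art_calls[0, ], blocks)
    # every artifact call sits in a region that splits in two, and the
    # resolved assembly offers no replacement call
    expect_equal(nrow(d$collapse_explained), nrow(art_calls))
    expect_equal(nrow(d$assembly_introduced), 0L)
})
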