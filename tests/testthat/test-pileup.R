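test_that("CIGAR walking covers the expected reference positions", {
    ref <- Biostrings::DNAStringSet(c(chr = "TTTTTTTTTT"))
    recs <- data.frame(qname = "r1", flag = 0L, contig = "chr", pos = 1L,
                       mapq = 60L, cigar = "4M", seq = "ACGT",
                       stringsAsFactors = FALSE)
    p <- buildPileup(readSamAlignments(write_sam(recs, ref), ref), ref)
    sc <- siteCounts(p)
    expect_equal(sc$pos, 1:4)
    expect_equal(sc$depth, rep(1L, 4))
    expect_equal(sc$A, c(1L, 0L, 0L, 0L))

    # duplicate flag 1024 excluded entirely
    recs$flag <- 1024L
    p <- buildPileup(readSamAlignments(write_sam(recs, ref), ref), ref)
    expect_equal(nrow(siteCounts(p)), 0L)
    expect_equal(p@nSkipped, 1L)

    # skipped region: 2M3N2M covers positions 1,2 then 6,7
    recs <- data.frame(qname = "r1", flag = 0L, contig = "chr", pos = 1L,
                       mapq = 60L, cigar = "2M3N2M", seq = "ACGT",
                       stringsAsFactors = FALSE)
    p <- buildPileup(readSamAlignments(write_sam(recs, ref), ref), ref)
    expect_equal(siteCounts(p)$pos, c(1L, 2L, 6L, 7L))

    # N bases in the read are never counted
    recs$cigar <- "4M"; recs$seq <- "ANGT"
    p <- buildPileup(readSamAlignments(write_sam(recs, ref), ref), ref)
    expect_equal(siteCounts(p)$pos, c(1L, 3L, 4L))
})

test_that("mapq filter and unknown contigs are enforced", {
    ref <- Biostrings::DNAStringSet(c(chr = "ACGTACGT"))
    recs <- data.frame(qname = c("hi", "lo"), flag = 0L, contig = "chr",
                       pos = 1L, mapq = c(30L, 3L), cigar = "4M",
                       seq = "ACGT", stringsAsFactors = FALSE)
    aln <- readSamAlignments(write_sam(recs, ref), ref)
    p <- buildPileup(aln, ref, callerThresholds(minMapq = 10L))
    expect_equal(max(siteCounts(p)$depth), 1L)
    expect_equal(p@nSkipped, 1L)
    expect_error(
        buildPileup(aln, Biostrings::DNAStringSet(c(other = "ACGT"))),
        "unknown contig")
})

test_that("pileup agrees with the naive per-base oracle on random inputs", {
    set.seed(101)
    for (case in 1:25) {
        ref <- Biostrings::DNAStringSet(
            c(cA = random_seq(sample(150:250, 1)),
              cB = random_seq(sample(150:250, 1))))
        recs <- random_records(sample(5:50, 1), ref)
        aln <- readSamAlignments(write_sam(recs, ref), ref)
        p <- buildPileup(aln, ref)
        got <- pileup_long(p)
        want <- naive_pileup(recs)
        want <- want[order(want$contig, want$pos, want$base), , drop = FALSE]
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want)
    }
})

test_that("per-site counts conserve the bases placed by the CIGAR walk", {
    set.seed(77)
    ref <- Biostrings::DNAStringSet(c(chr = random_seq(300)))
    recs <- random_records(40, ref)
    aln <- readSamAlignments(write_sam(recs, ref), ref)
    p <- buildPileup(aln, ref)
    placed <- sum(naive_pileup(recs)$count)
    expect_equal(sum(siteCounts(p)$depth), placed)
})

test_that("calling thresholds follow the strict published inequalities", {
    mk <- function(A, G) {
        counts <- data.frame(contig = "chr", pos = 5L, A = A, C = 0L,
                             G = G, T = 0L, stringsAsFactors = FALSE)
        new("Pileup", sampleId = "s", source = "RNA", counts = counts,
            nSkipped = 0L)
    }
    ref <- Biostrings::DNAStringSet(
        c(chr = paste(rep("A", 10), collapse = "")))
    th <- callerThresholds()
    # depth 19 is ignored even at 100% variant reads
    expect_equal(nrow(callCandidates(mk(0L, 19L), ref, th)), 0L)
    # depth 50, alt 5 (10.0%): both boundaries inclusive -> called
    calls <- callCandidates(mk(45L, 5L), ref, th)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$alt, "G")
    expect_equal(calls$alt_frac, 0.1)
    # depth 100, alt 9 (9%) fails the fraction bound
    expect_equal(nrow(callCandidates(mk(91L, 9L), ref, th)), 0L)
    # alt 4 fails the count bound whatever the fraction
    expect_equal(nrow(callCandidates(mk(16L, 4L), ref, th)), 0L)
})

test_that("multiple qualifying alternate alleles give one call each", {
    counts <- data.frame(contig = "chr", pos = 2L, A = 40L, C = 10L,
                         G = 10L, T = 0L, stringsAsFactors = FALSE)
    p <- new("Pileup", sampleId = "s", source = "RNA", counts = counts,
             nSkipped = 0L)
    ref <- Biostrings::DNAStringSet(c(chr = "AAAA"))
    calls <- callCandidates(p, ref)
    expect_equal(calls$alt, c("C", "G"))
    # N reference sites are never called
    refN <- Biostrings::DNAStringSet(c(chr = "ANAA"))
    expect_equal(nrow(callCandidates(p, refN)), 0L)
})

test_that("siteFraction reports zero-coverage explicitly", {
    counts <- data.frame(contig = "chr", pos = 7L, A = 95L, C = 0L,
                         G = 5L, T = 0L, stringsAsFactors = FALSE)
    p <- new("Pileup", sampleId = "s", source = "DNA", counts = counts,
             nSkipped = 0L)
    absent <- siteFraction(p, "chr", 99L, "G")
    expect_true(absent$zeroCoverage)
    expect_equal(absent$frac, 0)
    expect_equal(absent$depth, 0L)
    expect_equal(siteFraction(p, "chr", 7L, "G")$frac, 0.05)
    counts$G <- 6L; counts$A <- 94L
    p2 <- new("Pileup", sampleId = "s", source = "DNA", counts = counts,
              nSkipped = 0L)
    expect_equal(siteFraction(p2, "chr", 7L, "G")$frac, 0.06)
})

test_that("raising any calling threshold never increases the call count", {
    set.seed(202)
    ref <- Biostrings::DNAStringSet(c(chr = random_seq(120)))
    recs <- random_records(120, ref)
    aln <- readSamAlignments(write_sam(recs, ref), ref)
    base <- callerThresholds(minDepth = 2L, minAltReads = 1L,
                             minAltFrac = 0.02)
    p <- buildPileup(aln, ref, base)
    n0 <- nrow(callCandidates(p, ref, base))
    for (i in 1:12) {
        th <- callerThresholds(
            minDepth = sample(2:12, 1), minAltReads = sample(1:4, 1),
            minAltFrac = stats::runif(1, 0.02, 0.4))
        n1 <- nrow(callCandidates(p, ref, th))
        th_up <- callerThresholds(minDepth = th@minDepth + sample(0:5, 1),
                                  minAltReads = th@minAltReads +
                                      sample(0:3, 1),
                                  minAltFrac = min(1, th@minAltFrac +
                                      stats::runif(1, 0, 0.3)))
        n2 <- nrow(callCandidates(p, ref, th_up))
        expect_lte(n2, n1)
        expect_lte(n1, n0)
    }
})

test_that("identical inputs give identical ordered call lists", {
    set.seed(55)
    ref <- Biostrings::DNAStringSet(c(chr = random_seq(150)))
    recs <- random_records(60, ref)
    aln <- readSamAlignments(write_sam(recs, ref), ref)
    th <- callerThresholds(minDepth = 2L, minAltReads = 1L,
                           minAltFrac = 0.05)
    c1 <- callCandidates(buildPileup(aln, ref, th), ref, th)
    c2 <- callCandidates(buildPileup(aln, ref, th), ref, th)
    expect_identical(c1, c2)
})
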