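test_that("gDNA-alignment match requires the identical substitution > 5%", {
    call <- one_call()
    dna20 <- mk_pileup(data.frame(contig = "chr", pos = 10L, A = 80L,
                                  C = 0L, G = 20L, T = 0L))
    out <- filterDnaMatch(call, dna20)
    expect_equal(nrow(out$matched), 1L)
    expect_equal(out$matched$dna_frac, 0.2)

    # 4% is at or below the strict 5% bound: not matched
    dna4 <- mk_pileup(data.frame(contig = "chr", pos = 10L, A = 96L,
                                 C = 0L, G = 4L, T = 0L))
    expect_equal(nrow(filterDnaMatch(call, dna4)$matched), 0L)
    # exactly 5% is not matched either (strict inequality)
    dna5 <- mk_pileup(data.frame(contig = "chr", pos = 10L, A = 95L,
                                 C = 0L, G = 5L, T = 0L))
    expect_equal(nrow(filterDnaMatch(call, dna5)$matched), 0L)

    # a different substitution type at the same site never matches
    dnaC <- mk_pileup(data.frame(contig = "chr", pos = 10L, A = 80L,
                                 C = 20L, G = 0L, T = 0L))
    expect_equal(nrow(filterDnaMatch(call, dnaC)$matched), 0L)

    # zero DNA coverage passes the call onward instead of matching it
    empty <- mk_pileup(data.frame(contig = character(), pos = integer(),
                                  A = integer(), C = integer(),
                                  G = integer(), T = integer()))
    out <- filterDnaMatch(call, empty)
    expect_equal(nrow(out$passed), 1L)
    expect_equal(out$passed$dna_depth, 0L)
})

test_that("re-alignment absence applies the full calling thresholds", {
    call <- one_call()
    # zero coverage in the re-alignment
    empty <- mk_pileup(data.frame(contig = character(), pos = integer(),
                                  A = integer(), C = integer(),
                                  G = integer(), T = integer()), "RNA")
    expect_equal(nrow(filterAbsentInRealignment(call, empty)$absent), 1L)

    # identical support in both alignments passes
    same <- mk_pileup(data.frame(contig = "chr", pos = 10L, A = 25L,
                                 C = 0L, G = 25L, T = 0L), "RNA")
    expect_equal(nrow(filterAbsentInRealignment(call, same)$passed), 1L)

    # depth 25 but only 3 variant reads: below the 5-read bound -> absent
    weak <- mk_pileup(data.frame(contig = "chr", pos = 10L, A = 22L,
                                 C = 0L, G = 3L, T = 0L), "RNA")
    out <- filterAbsentInRealignment(call, weak)
    expect_equal(nrow(out$absent), 1L)
    expect_equal(out$absent$realn_alt_count, 3L)

    # no second alignment: filter skipped, calls pass through
    expect_warning(out <- filterAbsentInRealignment(call, NULL), "skipped")
    expect_equal(nrow(out$passed), 1L)
})

test_that("pooled search finds full-length exact containments only", {
    set.seed(12)
    ref <- Biostrings::DNAStringSet(c(chr = random_seq(200)))
    pos <- 100L
    aln <- support_aln(ref, pos, n_sup = 2, n_ref = 2)
    call <- one_call(pos = pos, depth = 4L, alt_count = 2L)
    sup_seq <- as.character(S4Vectors::mcols(aln)$seq[1])

    params <- pooledSearchParams(kmerSize = 11)
    # pool read containing a supporting read verbatim -> matched
    pool <- Biostrings::DNAStringSet(
        c(paste0(random_seq(10), sup_seq, random_seq(10)), random_seq(60)))
    out <- pooledGenomicSearch(call, aln, pool, params)
    expect_equal(nrow(out$matched), 1L)
    expect_equal(out$matched$pool_hits, 1L)

    # reverse complement only matches when enabled
    pool_rc <- Biostrings::DNAStringSet(rc(sup_seq))
    expect_equal(nrow(pooledGenomicSearch(call, aln, pool_rc,
                                          params)$matched), 1L)
    norc <- pooledSearchParams(kmerSize = 11, searchRevcomp = FALSE)
    expect_equal(nrow(pooledGenomicSearch(call, aln, pool_rc,
                                          norc)$matched), 0L)

    # one mismatch breaks the 100% identity requirement
    mut <- sup_seq
    substr(mut, 15, 15) <- if (substr(mut, 15, 15) == "A") "C" else "A"
    pool_mut <- Biostrings::DNAStringSet(paste0("TTTT", mut, "TTTT"))
    expect_equal(nrow(pooledGenomicSearch(call, aln, pool_mut,
                                          params)$matched), 0L)

    # a shorter pool read must cover the variant position
    off <- pos - GenomicAlignments::start(aln)[1] + 1L  # variant offset
    covering <- substr(sup_seq, off - 5L, off + 5L)
    not_covering <- substr(sup_seq, 1L, off - 1L)
    expect_equal(nrow(pooledGenomicSearch(
        call, aln, Biostrings::DNAStringSet(covering), params)$matched), 1L)
    expect_equal(nrow(pooledGenomicSearch(
        call, aln, Biostrings::DNAStringSet(not_covering),
        params)$matched), 0L)

    # empty pool skips the filter with a warning
    expect_warning(out <- pooledGenomicSearch(call, aln, NULL, params),
                   "skipped")
    expect_equal(nrow(out$passed), 1L)
})

test_that("k-mer-indexed pooled search equals the brute-force scan", {
    set.seed(31)
    ref <- Biostrings::DNAStringSet(c(chr = random_seq(400)))
    for (case in 1:8) {
        pos <- sample(60:340, 1)
        aln <- support_aln(ref, pos, n_sup = 3, n_ref = 2,
                           read_len = sample(c(25L, 40L, 61L), 1))
        call <- one_call(pos = pos, depth = 5L, alt_count = 3L)
        # pool: background reads + planted exact/near matches of varied size
        sup <- as.character(S4Vectors::mcols(aln)$seq)[1:3]
        pool <- c(replicate(300, random_seq(sample(20:80, 1))),
                  paste0(random_seq(5), sup[1], random_seq(3)),
                  rc(sup[2]),
                  substr(sup[3], 2, nchar(sup[3]) - 1),
                  vapply(sup, function(s) {
                      substr(s, 10, 10) <- "N"; s
                  }, character(1)))
        pool <- Biostrings::DNAStringSet(unname(pool))
        for (k in c(11L, 31L)) {
            params <- pooledSearchParams(kmerSize = k)
            got <- pooledGenomicSearch(call, aln, pool, params)
            tab <- editcheck:::.alignedBaseTable(aln)
            supr <- tab[tab$pos == pos & tab$base == "G", ]
            queries <- as.character(S4Vectors::mcols(aln)$seq)[supr$read]
            want <- brute_pool_search(queries, supr$qpos,
                                      as.character(pool))
            expect_equal(got$matched$pool_hits,
                         if (length(want)) length(want) else integer(0))
            expect_equal(nrow(got$matched) == 1L, length(want) >= 1L)
        }
    }
})

test_that("classification applies the fixed precedence order", {
    set.seed(64)
    ref <- Biostrings::DNAStringSet(c(chr = random_seq(200)))
    pos <- 90L
    aln <- support_aln(ref, pos, n_sup = 3, n_ref = 3)
    call <- one_call(pos = pos, depth = 6L, alt_count = 3L)
    dna <- mk_pileup(data.frame(contig = "chr", pos = pos, A = 70L,
                                C = 0L, G = 30L, T = 0L))
    # matched by DNA alignment AND pooled reads -> DNA_MATCH wins
    pool <- Biostrings::DNAStringSet(
        as.character(S4Vectors::mcols(aln)$seq[1]))
    v <- suppressWarnings(classifySites(
        call, dna, aln, gdnaPool = pool,
        searchParams = pooledSearchParams(kmerSize = 11)))
    expect_equal(v$category, "DNA_MATCH")

    # without optional inputs every non-DNA-matched call is retained
    far_dna <- mk_pileup(data.frame(contig = "chr", pos = 1L, A = 50L,
                                    C = 0L, G = 0L, T = 0L))
    v <- suppressWarnings(classifySites(call, far_dna))
    expect_equal(v$category, "RETAINED")

    # with no DNA pileup at all, calls are still classified
    v <- suppressWarnings(classifySites(call))
    expect_equal(v$category, "RETAINED")
})

test_that("every call gets exactly one category (conservation identity)", {
    s <- small_sim()
    th <- callerThresholds()
    ref <- s$sim$collapsedRef
    rp <- buildPileup(s$aln$rna, ref, th, "sim", "RNA")
    dp <- buildPileup(s$aln$dna, ref, th, "sim", "DNA")
    calls <- callCandidates(rp, ref, th)
    expect_gt(nrow(calls), 0L)
    v <- suppressWarnings(classifySites(calls, dp, s$aln$rna,
                                        gdnaPool = s$reads$dna))
    expect_equal(nrow(v), nrow(calls))
    expect_true(all(v$category %in% c("DNA_MATCH", "ABSENT_IN_REALIGNMENT",
                                      "POOLED_GENOMIC_MATCH", "RETAINED")))
    counts <- table(factor(v$category,
                           c("DNA_MATCH", "ABSENT_IN_REALIGNMENT",
                             "POOLED_GENOMIC_MATCH", "RETAINED")))
    expect_equal(sum(counts), nrow(calls))
    # same sites in, same sites out
    expect_setequal(paste(v$contig, v$pos, v$alt),
                    paste(calls$contig, calls$pos, calls$alt))
})
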