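# editcheck

Misassembly-aware verification of candidate RNA-editing sites.

## The problem

RNA-editing sites in fungi (and elsewhere) are commonly predicted by
aligning transcriptome reads to a reference assembly and calling positions
where the RNA disagrees with the reference. That inference silently assumes
the assembly is complete. It rarely is: near-identical regions — transposon
copies, tandem and segmental duplications — get *collapsed* into a single
reference locus. Reads from both genomic copies then stack on one position
with perfect identity, and the copies' divergent bases masquerade as RNA
variants at ~50% allele fraction. A second confounder is biological rather
than technical: when the RNA and the DNA libraries come from different
isolates, genuine strain SNPs look like editing.

`editcheck` re-calls RNA variant sites from alignments and then tries to
*eliminate* every candidate by a non-editing explanation, in a fixed
precedence order:

1. **`DNA_MATCH`** — the genomic DNA alignment shows the identical
   substitution at the site. With depth *d* and variant count *v* in the
   DNA pileup, the site is removed when *v/d* > 0.05 (strict).
2. **`ABSENT_IN_REALIGNMENT`** — an independent re-alignment of the same
   RNA reads (e.g. a newer spliced aligner with a restricted intron
   length) no longer supports the variant at calling thresholds.
3. **`POOLED_GENOMIC_MATCH`** — the raw, *unaligned* gDNA read pool
   contains a variant-supporting RNA read at 100% identity over the full
   length of the shorter sequence, covering the variant base. This catches
   genomic copies that never made it into the assembly at all, so no
   alignment can reveal them.
4. **`RETAINED`** — everything else: credible editing, or strain variation
   when the isolates differ (then flagged `possible_strain_variant`).

Candidate calling follows explicit thresholds: a site needs total depth
≥ 20, variant reads ≥ 5 and variant allele fraction ≥ 10%; reads flagged
as duplicates (SAM flag 1024) are excluded and mapping quality is not
otherwise restricted. Cross-assembly liftover (`mapSite`, `diffVariantSets`)
additionally flags sites whose neighbourhood corresponds to two or more
separate regions of an independent assembly of the same reads — the
collapsed-duplication signature.

A deterministic simulator generates all three phenomena (collapsed
paralogs, genuine A→G editing at a configurable per-molecule rate, strain
SNPs) together with alignments, raw reads and a ground-truth table, so the
whole pipeline is testable at desk scale without downloads.

## Worked example

Simulate a 30 kb haploid genome with two collapsed 5 kb duplications (1%
copy divergence), 20 genuine edit sites at 30% editing rate, 60× DNA and
RNA coverage — and withhold the DNA *alignments* of the second duplication,
leaving its reads only in the raw pool:

```r
library(editcheck)

cfg <- simConfig(seed = 1, withholdDnaFor = 2)
d   <- simulateEditingData(cfg, outdir = "demo")   # FASTA/FASTQ/SAM/truth

th   <- callerThresholds()
ref  <- d$sim$collapsedRef
rna  <- buildPileup(d$aln$rna, ref, th, "demo", "RNA")
dna  <- buildPileup(d$aln$dna, ref, th, "demo", "DNA")
calls <- callCandidates(rna, ref, th)
head(calls, 3)
#>   contig  pos ref alt depth alt_count  alt_frac sample_id source
#> 1   chr1 2041   C   T    45        21 0.4666667      demo    RNA
#> 2   chr1 2154   T   C   130        65 0.5000000      demo    RNA
#> 3   chr1 2220   T   C   138        62 0.4492754      demo    RNA

v <- classifySites(calls, dna, d$aln$rna, gdnaPool = d$reads$dna)
summarizeVerdicts(v, "demo")
#>   sample_id n_reported n_dna_match n_absent_realignment n_pooled_match n_retained
#> 1      demo        110          46                    0             44         20
```

110 candidate sites were called; 46 were removed because the DNA alignment
shows the same substitution, 44 (the withheld duplication) were removed
because raw gDNA reads match the variant-supporting RNA reads at full
length, and the 20 retained sites are exactly the engineered edits:

```r
scoreVerdicts(v, d$sim$truth, th, withheldPairs = 2)$stats
#>     n_artifact_candidates    artifact_dna_match_pct artifact_pooled_match_pct
#>                        90                       100                       100
#>    true_edit_retained_pct   strain_snp_retained_pct
#>                       100                       NaN
```

Multi-sample runs are driven by a TSV manifest (`runPipeline`), which also
ingests externally published candidate-site lists and re-evaluates them
against the current alignments instead of trusting them. A thin CLI wraps
the same functions (`exec/editcheck qc|call|filter|liftover|simulate|run`).

For full-scale reanalysis of published data, point the manifest at your
own alignments (the package consumes SAM, FASTA/FASTQ, show-coords blocks
and TSV site lists; producing alignments and assemblies is out of scope)
and supply the prior study's site list per sample via `sites_tsv`.

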