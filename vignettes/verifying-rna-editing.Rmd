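---
title: "Verifying candidate RNA-editing sites against misassembly and strain artifacts"
author: "editcheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying candidate RNA-editing sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editcheck)
```

## The model

An RNA-editing candidate is a reference position where aligned RNA reads
show a non-reference base at appreciable frequency. Three generative
processes produce the same signal:

* **genuine editing** — a fraction $e$ of RNA molecules carries the edited
  base (canonically A→G for A-to-I editing read as cDNA); the genomic DNA
  is homogeneous for the reference base;
* **a collapsed duplication** — two near-identical genomic copies were
  assembled as one locus. Reads from both copies align there perfectly, so
  at each inter-copy divergent position both RNA *and* DNA show the second
  copy's base at roughly 50% (for a balanced two-copy collapse);
* **strain difference** — the RNA-source isolate carries a true SNP the
  DNA-source isolate lacks; RNA shows the variant near 100%, DNA not at
  all.

Only the first is editing. The package separates the three by asking, for
every candidate with alternate allele $b$ at site $s$: does the DNA
alignment show $b$ at $s$ in more than 5% of mapped reads (strict)? If
yes, the site is explained by the genome (`DNA_MATCH`). Does an
independent re-alignment of the same RNA reads still support the call at
the calling thresholds? If not, the original support was an alignment
artifact (`ABSENT_IN_REALIGNMENT`). Do raw, unaligned gDNA reads contain a
variant-supporting RNA read at 100% identity over the full length of the
shorter sequence, covering the variant base? If yes, the allele exists in
the genome even though no alignment shows it — the locus was dropped or
collapsed beyond recognition during assembly (`POOLED_GENOMIC_MATCH`).
Survivors are `RETAINED`, and flagged `possible_strain_variant` when the
manifest declares different DNA and RNA source isolates.

The precedence order is fixed (DNA match, then re-alignment absence, then
pooled match, then retained), mirroring the narrative order in which the
filters are naturally applied: cheap alignment-level evidence first, the
pooled-read search as the remedy for sites the alignments cannot
adjudicate. Every input call receives exactly one category, so the
per-category counts always sum to the number of candidates — an identity
the pipeline asserts on every run.

## Calling thresholds and their meaning

Candidate calling uses pileups of the four bases (N and gaps never count,
so depth is always the sum of the four base counts):

| parameter | default | meaning |
|---|---|---|
| `minDepth` | 20 reads | sites with fewer total mapped reads are ignored |
| `minAltReads` | 5 reads | minimum variant-supporting reads |
| `minAltFrac` | 0.10 | minimum variant allele fraction |
| `dnaPresenceFrac` | 0.05 (strict >) | DNA fraction above which an RNA call is genome-matched |
| `excludedFlagMask` | 1024 | SAM flag bits excluding a read (duplicates) |
| `minMapq` | 0 | no mapping-quality restriction |

Boundaries are taken literally from the inequalities they encode: a site
is ignored when depth < 20, variant reads < 5 or fraction < 10% — so depth
20, 5 reads and exactly 10% all pass — and DNA-matched only when the DNA
fraction strictly exceeds 5%. Several qualifying alternate alleles at one
site yield one call each, and the DNA comparison is per allele: an RNA A→G
call is *not* matched by DNA showing A→C, only by the identical
substitution type. Calls are reported in reference-forward orientation;
no transcript-strand inference is attempted, and insertions/deletions are
out of scope (substitution editing only).

A site with *zero* DNA coverage is deliberately **not** DNA-matched: a
missing locus is precisely the situation the pooled search addresses, so
such calls pass onward rather than being discarded or matched.

## The pooled raw-read search

For each surviving call the variant-supporting RNA reads are collected
(the reads whose aligned base at the site equals the alternate allele,
taken as stored in the alignment, reference-forward). A call is eliminated
when at least `minHits` (default 1) distinct gDNA reads contain such an
RNA read at 100% identity over the full length of the shorter of the two
sequences — reverse complements included — with the containment covering
the variant base. "Full length of the shorter" is the only well-defined
reading when library read lengths differ; when they are equal it reduces
to exact sequence identity.

The implementation indexes the pool with anchor k-mers at stride *k*
(default *k* = 31): any containment of a query of length ≥ 2*k* − 1 must
share an anchor, so candidate retrieval is lossless for such queries;
shorter queries and pool reads shorter than *k* fall back to a direct
scan. Candidates are then verified by exact string containment. The test
suite checks this machinery against a brute-force full scan on randomized
pools.

`minHits = 1` is a deliberate, permissive default: one full-length exact
genomic match already demonstrates the allele exists in the genome. Its
known cost is sensitivity to sequencing error in the pool: a single gDNA
read carrying an error at exactly the candidate site, colocated with an
error-free variant-supporting RNA read, produces a spurious match and
eliminates a genuine site. At a per-base error rate of 0.005 and 60×
depth this is a percent-level risk per near-fixed variant site; analyses
of different-isolate samples, where retained sites are the object of
interest, should either raise `minHits` or omit the pool when the DNA
alignment is complete (the pooled search adds information only where DNA
alignments are missing). The bundled strain-difference demonstration does
the latter.

## Re-evaluating external candidate lists

Previously published site lists are ingested per sample and re-evaluated
rather than trusted: positions and alleles are kept, while depth and
support are recomputed from the supplied alignments. When no independent
re-alignment is given, the primary RNA pileup itself is the re-evaluation
target, so published sites with no current RNA support are classed
`ABSENT_IN_REALIGNMENT`. This mirrors the intended full-scale use: take a
prior study's predictions, align that study's reads plus matching gDNA
reads, and let the filters decide.

## Cross-assembly liftover

Independent assemblies of the same reads make different collapse errors.
`mapSite` lifts a site through genome-to-genome alignment blocks
(show-coords layout): every block overlapping a ±75 bp window contributes
a hit, positions are interpolated linearly within a block (mirrored for
reverse-oriented blocks), and hits are clustered into regions — different
target contigs, or ≥ 10 kb apart, count as separate. A site whose
neighbourhood maps to two or more regions (`SPLIT_MULTI`) sits in a
collapsed duplication that the other assembly resolved.
`diffVariantSets` partitions old-assembly calls into reassembly-dissolved,
collapse-explained and preserved, and reports new-assembly calls at
positions that are no old call's image (misassemblies freshly introduced
by the other assembler).

The window (±75 bp, about a short-read insert half-width) and the split
gap (10 kb, beyond tandem-repeat scale) are package choices, configurable
via `liftoverParams()`. Linear interpolation assumes collinearity within a
block — acceptable at the ≥98%-identity granularity of whole-genome
aligner blocks, and a documented approximation: indel-aware offsetting
inside blocks is not attempted.

## Read preprocessing

Raw pools are cleaned in a fixed order: exact full-sequence
de-duplication (PCR-duplicate removal; no reverse-complement collapsing,
no pair awareness), 3' quality trimming, minimum-length filtering
(< 40 bp dropped; 40 bp kept). Trimming uses the standard partial-sums
rule of cutadapt-family trimmers at Q20: walking from the 3' end,
accumulate (cutoff − q) and cut where the running sum is maximal and
positive. Among tied maxima the smaller trim is taken; the suite verifies
the rule against a brute-force enumeration of every cut point. Only the
3' end is trimmed, and adapters are out of scope (synthetic reads carry
none).

## What the simulator emulates — and what it does not

`simConfig()` defaults define the synthetic study conditions used
throughout the tests and the acceptance script: a 30 kb haploid contig
with two 5 kb duplication pairs at 1% copy divergence collapsed to single
loci; 20 A→G edit sites at per-molecule rate 0.3 on a single-copy
transcript; 60× DNA and RNA coverage with 100 bp single-end reads at
per-base error 0.005; constant Phred qualities consistent with the error
rate; seed-determined everything (identical seeds give byte-identical
files). Divergent paralog positions use transition substitutions,
matching the transition-dominated substitution spectra reported for
fungal RNA-variant sets. Strain mode (`nStrainSnps > 0`, default off)
places transition SNPs on a second single-copy transcript carried only by
the RNA-source isolate; the bundled demonstration uses 8 such SNPs.
Editing is applied per read (read ≈ molecule at these depths); an
optional 300 bp intron exercises spliced M,N,M alignments.

Reads are *placed*, not aligned: the simulator emits SAM directly from
known provenance, with duplicate-copy origins mapped onto the collapsed
locus. This removes any aligner dependency and makes artifacts
deterministic; externally produced SAM can be substituted wherever the
pipeline takes alignments. `withholdDnaFor` omits a duplication's DNA
alignments (keeping its raw reads) to exercise the pooled search — the
"second copy never assembled" scenario.

Consequences for interpretation: passing tests show the filters recover
engineered truth under uniform coverage, uniform error, single-end
placement-perfect alignments and balanced two-copy collapses. They do not
probe GC/coverage bias, indels, paired-end artifacts, alignment errors,
multi-copy (>2) collapses or polyploid genotypes — real data can be
harder in all these ways.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere: internally (the
  R/Bioconductor convention shared with IRanges) and in every table read
  or written, so no shift exists to get wrong at module boundaries.
* SAM text is consumed directly (header required, `@SQ` names checked
  against the reference); records are treated independently — no mate
  rescue. Hard clips consume nothing; soft clips consume query only; `N`
  read bases never support variants nor reference.
* Stable orderings throughout — calls and verdicts by (contig, position,
  alternate allele), summary rows by manifest order — make re-runs
  byte-identical.
* Percentages in summary reports are rounded half-up to two decimals, the
  printed precision of the bookkeeping they reproduce.
* Per-sample failures in a manifest run are isolated and reported while
  the remaining samples complete; the CLI exits non-zero if any sample
  failed.
* Problem sizes in the test suite and acceptance script: pileup oracle
  agreement on 100 randomized alignment sets (≤ 50 reads, mixed CIGARs);
  pooled-search oracle agreement on ~1000-read pools; end-to-end recovery
  on the default 30 kb / 60× configuration (three runs: plain, DNA
  alignments withheld for one duplication, strain mode). These sizes keep
  a full run in minutes on one CPU while every engineered site class is
  represented dozens of times.

## Known limitations

* The DNA-match threshold (> 5%) is a point rule; no binomial or quality
  model backs it, by design — the goal is a transparent reimplementation
  of a published filtering rule, not probabilistic genotyping.
* `minHits = 1` pooled matching is error-sensitive (see above).
* Heterokaryotic/dikaryotic genomes need haplotype-resolved analysis the
  package does not attempt; the liftover module flags collapses but does
  not phase.
* Published count tables with range-valued cells are preserved as text
  and excluded from identities that need single values.
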