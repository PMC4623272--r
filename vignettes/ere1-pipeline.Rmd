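---
title: "Detecting SINE insertion polymorphism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting SINE insertion polymorphism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ereScout)
```

## The problem

Short interspersed elements (SINEs) spread through a genome by
retrotransposition. A young insertion segregates in the population: some
chromosomes carry the element (the filled, "+" allele), others retain the
ancestral empty site ("-"). Over time the insertion either fixes or is
lost, and the element's sequence diverges from the subfamily consensus by
neutral substitution. Two consequences follow that this package is built
around:

* per-locus **percent identity to the consensus** is a molecular clock
  proxying insertion age;
* the **fraction of polymorphic loci** within an identity class decays
  with that age, so young classes are rich in segregating insertions.

The concrete system is the equine ERE1 family, a ~225 bp tRNA-derived
SINE, and the reference individual is the horse whose genome assembly and
unassembled trace reads are available: an empty allele shows up as a trace
that aligns to the locus with a ~225 bp deletion, proving the individual
heterozygous there. The best-known ERE1 insertion sits in the myostatin
promoter, where it weakens the core promoter and is associated with
sprinting aptitude; its population genetics (allele frequencies across
breeds, association with a linked SNP) motivates the statistics module.

## Pipeline stages

1. **Discovery** (`scan_genome()`, `filter_hits()`, `lift_to_genome()`,
   `exclude_repeat_embedded()`): a k-mer seeded scan (word size 11, both
   strands) clusters exact seed matches on diagonals and realigns each
   candidate globally on the consensus, locally on the genome. Identity is
   matches over alignment columns, gap columns counting as mismatches —
   the convention of BLAST-style hit tables. Hits are kept when their
   aligned length is within 225 ± 10 bp and identity is at least 84%
   (inclusive; `strict_gt` switches to a strict inequality — the
   inclusive reading was chosen because the published filter is phrased
   as a *minimum* identity). Hits on contigs missing from the placement
   table are dropped as unplaced; loci overlapping another repeat by at
   least 1 bp (configurable) are dropped as repeat-embedded, since a SINE
   nested in an older transposon cannot be genotyped by flank alignment.
   Overlapping hits are resolved by score, then leftmost position. Kept
   loci are binned into eight 2-point identity classes, 84–86 up to the
   closed top bin 98–100.

2. **Polymorphism** (`extract_window()`, `match_trace()`,
   `detect_empty_allele()`, `check_locus_uniqueness()`,
   `call_polymorphic_loci()`): each kept locus contributes a ~2.2 kb
   window (element plus 1 kb flanks, truncated and flagged at contig
   ends). Trace reads from the reference sequencing project are aligned
   semi-globally to the window with an affine gap model whose high
   opening (40) and low extension (0.1) penalty make a single large
   deletion affordable. A read is evidence for an empty allele when it
   shows a deletion whose **TSD-corrected** length is within ±10 bp of
   the element length, both flanking segments are at least 98% identical,
   both anchors are at least 50 bp, and the deletion overlaps the element
   interval. A locus is called heterozygous when it lies in single-copy
   sequence and at least one read supports the empty allele.

3. **Gene context and TPRT annotation**
   (`classify_relative_to_genes()`, `detect_tsd()`,
   `find_integration_microhomology()`): loci are classified with the
   precedence exon > intron > distance bins (≤1 kb, 1–5 kb, 5–10 kb,
   >10 kb) from the strand-aware transcription start site of the nearest
   gene; intronic status requires full containment in one intron (mere
   overlap with a gene body is not enough), and distance is the gap in
   bases between the locus and the TSS (0 when the locus covers it), with
   ties broken by the lexicographically smaller gene id. `detect_tsd()`
   decomposes a filled/empty allele pair as `L·r·X·r·R` versus `L·r·R`,
   reporting the longest exact direct repeat `r` (the target-site
   duplication left by target-primed reverse transcription), ties broken
   by the leftmost nick. Microhomology is the A-run shared between the
   element's poly-A tail and the empty allele at the left nick — the
   T-run on the minus strand that anneals the element RNA's tail during
   integration.

4. **Population statistics** (`genotype_from_pcr()`,
   `allele_genotype_frequencies()`, `chisq_goodness_of_fit()`,
   `chisq_independence()`, `pearson_identity_logfreq()`,
   `classify_insertion_age()`, `two_locus_concordance_and_r2()`,
   `fold_change_ddcq()`): frequencies and chi-square statistics are
   computed from their defining formulas with **no continuity
   correction** — with Yates' correction the goodness-of-fit p on the
   elite-versus-unselected allele counts would be ~1.3e-5 rather than the
   published ~9.3e-6, so the uncorrected statistic is clearly what the
   original analysis used. Percentages are rounded half away from zero to
   one decimal, matching printed-table formatting. The identity-class
   correlation takes class midpoints as the identity covariate (the lower
   bound is available via `covariate = "lower"`) and drops classes with
   zero polymorphic loci before taking logs, since ln 0 is undefined;
   whether the original analysis used all eight classes is not stated,
   and the choice is exposed. Two-locus linkage disequilibrium is
   estimated by expectation–maximisation on unphased genotypes,
   `r² = D²/(pA·pa·pB·pb)`; when no double heterozygotes are present the
   EM solution coincides with the closed-form count, which the tests
   assert.

## The target-site-duplication correction of trace gaps

A filled reference locus reads `L·r·E·r·R` (element `E` flanked by the
duplicated target `r`); the empty chromosome reads `L·r·R`. An
empty-allele trace therefore aligns to the reference with a deletion of
`E` **plus one copy of `r`** — up to 20 bp more than the element. The
classic ±10 bp gap filter, applied to the raw deletion, would silently
miss loci whose duplication exceeds 10 bp. `match_trace()` therefore
canonicalises every large deletion: the longest common suffix (prefix)
between the deleted sequence and the retained sequence immediately left
(right) of it, capped at 30 bp, measures the duplicated target, and the
corrected length estimates the inserted element alone. Evidence rows
carry both `gap_raw` (exactly element + TSD on clean data) and
`gap_length` (corrected; the ±10 bp rule is applied to it). The
correction can overshoot by a base or two when the flank continues the
element's terminal run by chance; the ±10 tolerance absorbs this.

## The synthetic-data generator

Real inputs for this analysis are a reference assembly, a trace archive
and curated annotation tracks. The generator builds statistically
matched stand-ins with complete ground truth:

* **Consensus and divergence**: a random 225-mer ending in a poly-A tail
  (8 bp by default; the tail drives microhomology simulation). Copies are
  diverged by substitutions only — indels would move loci out of the
  225 ± 10 length filter, which is exactly how the real filter treats
  them, so indel-bearing copies are deliberate out-of-filter cases.
* **Identity clock**: insertion ages are uniform on 0–16 My and identity
  is `100·(1 − 0.01·T)`, mapping the age range onto the 84–100% identity
  window. The rate is a modelling device, not an estimate of the equine
  neutral rate.
* **Polymorphism decay**: a locus is still polymorphic with probability
  `p0·exp(−T/τ)`, `p0 = 0.166`, `τ = 3.656` My, and polymorphic loci get
  an insertion frequency uniform on 0.05–0.95. The two parameters are
  calibrated in closed form so that the *observed heterozygous* fraction
  of the reference individual (polymorphism times the Hardy–Weinberg
  heterozygosity, mean 0.365) is ~4.6% in the youngest identity class and
  ~0.1% in the oldest — the two endpoints the genome-wide survey reports.
* **Tree structure**: loci older than the 3.8 My radiation of the genus
  are fixed in all seven species; loci younger than the radiation but
  older than the horse split (0.72 My, a free parameter — only the
  radiation age is documented) are confined to the two horse species;
  younger loci are private to the domestic horse.
* **Planting**: `plant_insertions()` duplicates the `tsd_len` bases 5' of
  each cut so every copy is flanked by identical direct repeats
  (5–20 bp), on a random strand. Designated loci are nested inside a
  simulated older repeat, have their whole window duplicated elsewhere
  (segmental-duplication analogues; these are also made heterozygous so
  that the uniqueness veto, not missing evidence, is what excludes them),
  or are made heterozygous in the reference individual.
* **Traces**: per locus and haplotype, reads of 700 bp (traces are short,
  sub-kilobase reads) spanning the insertion point with at least 60 bp
  anchors, half reverse-complemented, tagged with the reference project
  id; decoy reads with a different project id replicate the evidence and
  must never be counted. Trace depth per haplotype is a free parameter
  (the real per-locus coverage is not documented); the default is 3.
* **Genotypes**: per species group, Hardy–Weinberg draws from the locus'
  allele frequency; species outside the lineage are homozygous empty.
  Default panel sizes mirror the published survey (30 domestic horses,
  20 Przewalski's horses, 3 donkeys, one individual from each of four
  further species).

What the generator does **not** emulate: sequencing error, quality
values, paired ends, indel divergence (off by default), CpG rate
heterogeneity, demography and drift. Passing recovery tests on this data
therefore demonstrates the correctness of the algorithms — coordinates,
filters, gap calling, veto logic — not robustness to noisy reads; the
flank-identity and anchor thresholds are the knobs a noisy-data user
would loosen.

## Problem sizes and numerical choices

The end-to-end recovery test plants 200 loci in a 2 Mb two-contig genome
(30 heterozygous, 10 repeat-embedded, 5 window-duplicated) and demands
recall = precision = 1.0 for kept loci and heterozygous calls; the
statistical-law test simulates 2000 loci. These sizes keep the full suite
within a few minutes while leaving every per-class expectation well above
one locus.

Alignment scoring is match +1 / mismatch −1 with gap opening 5 and
extension 2 for the scanner (gaps expensive, so substitution-diverged
copies align gaplessly and coordinates are exact), and opening 40 /
extension 0.1 for trace matching (one large deletion affordable,
scattered small gaps discouraged). Seed clustering uses a ±25 diagonal
band. The duplication screen requires a second flank match at ≥95%
identity over ≥80% of the flank. All randomness flows from a single seed
through fixed per-stage offsets, so a configuration is bit-reproducible.

Known limitations: the scanner is not a drop-in replacement for megablast
scoring (scores differ; coordinates and identities are what the filters
consume); novel insertions absent from the reference assembly are out of
scope (they are found by PCR, not by reference-anchored traces); TSD
detection is exact-match only, as is appropriate for the clean allele
pairs it is given; and the identity threshold treats the published
"minimum identity of 84%" as inclusive.
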