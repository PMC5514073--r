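---
title: "Monitoring mutant DNA in plasma and urine during neoadjuvant chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring mutant DNA in plasma and urine during neoadjuvant chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urotrace)
```

## The problem

Muscle-invasive bladder cancer (MIBC) is treated with cisplatin-based
neoadjuvant chemotherapy (NAC) followed by radical cystectomy, but many
patients do not respond, and no validated biomarker indicates failure early
enough to change course. Tumour-derived mutant DNA (mutDNA) shed into body
fluids offers a minimally invasive readout: in bladder cancer the tumour sits
directly in the urinary reservoir, so urine — both the cell pellet (UCP) and
supernatant (USN) of centrifuged urine — tends to carry far more tumour DNA
than plasma. `urotrace` implements the analysis layer for such a monitoring
study: per-patient panels of single-nucleotide variants (SNVs) assayed by
deep amplicon sequencing across serial plasma/UCP/USN samples, shallow
whole-genome sequencing (sWGS) copy-number profiles of the same fluids, and
an outcome layer linking on-treatment mutDNA presence to recurrence.

The pipeline starts downstream of alignment: its inputs are per-bin read
counts (BED-style TSV), per-variant read counts with the per-reaction
amplifiable input (genomic equivalents, GE, as quantified by dPCR), and a
cohort sample sheet. A synthetic cohort generator produces all three, with
ground truth, so every stage is testable without any external data.

## SNV detection: the dual-threshold rule

A variant observation is called detected when its allele fraction (AF,
`alt_reads / depth`) strictly exceeds

$$\max\left(0.005,\ \frac{1}{\mathrm{GE}}\right).$$

The 0.5% technical floor guards against background substitution noise (at
this working point germline samples produce no calls — see the
false-positive property below); the 1/GE sampling floor recognises that a
reaction seeded with GE amplifiable molecules cannot reliably witness an
allele rarer than one molecule. Sub-threshold AFs are retained for
interpreting kinetics, they just never count as detections. The rule is
applied per variant per sample (the simplest reading; nothing in the package
pools replicates before thresholding).

Patient-level *presence* at a visit is detection of any panel variant in any
*available* peripheral sample type. Missing samples are never counted as
negative: a visit with no assayable fluid is unevaluable (`NA`), and a
patient with no panel SNV observed anywhere (tumour or fluids) forms an
unevaluable stratum excluded from presence classification.

## Copy-number profiling

`correct_counts()` reproduces the standard binned-count correction chain:

1. bins that are blacklisted or have mappability < 0.5 are invalidated;
2. counts (plus a 0.5 pseudocount, so zero-count bins stay finite) are
   divided by a smoothed GC-bias estimate — the local median of count versus
   GC in 20 equal-frequency GC strata, linearly interpolated — then by
   mappability;
3. the result is expressed as log2 ratio to the sample median over valid
   bins, making the valid-bin median exactly 0 and the profile invariant to
   sequencing depth.

The local-median fit is deliberately assumption-light: it removes any smooth
unimodal bias without trusting a parametric form. Its one failure mode is
worth knowing: when a single CNA covers a large fraction of all bins in some
GC stratum (tiny genomes, huge events), part of the event is absorbed into
the bias estimate. On genome frames of a few hundred bins with events below
~10% of the genome the absorption is a few hundredths of a log2 unit.

`segment_profile()` is a from-scratch circular binary segmentation: per
chromosome, the circular arc \((i, j]\) maximising
\(|S_j - S_i - k\bar{x}|/\sqrt{k(n-k)}\) is found exhaustively, accepted if
its within-region permutation p-value is below `alpha`, and the algorithm
recurses. Defaults: `alpha = 0.01`, `n_perm = 1000`, `min_width = 2`, a
fixed permutation seed (so segmentation is deterministic), and no
pruning/undo pass — the profiles here are short (tens to ~130 bins per
chromosome), where the plain recursion is exact enough that on noiseless
instances it provably picks the same split as an exhaustive
best-RSS-reduction oracle (the two criteria are monotone transforms of each
other for a two-mean circular split). The permutation loop is vectorised
and stops early once enough exceedances guarantee non-significance.

Gain/loss calling replaces a mixture-model caller with robust thresholding:
a segment is aberrant when its mean exceeds `max(0.10, 3 * MAD)` in absolute
value, where the MAD is taken over bin-level residuals around segment means.
A six-state mixture is not identifiable on a single shallow profile, and the
pipeline only ever uses calls as binary presence evidence, so the simpler
caller is the honest one. The absolute 0.10 floor dominates at default noise
(bin-level MAD ≈ 0.03) and sets the detection limit: a single-copy gain
(log2 factor \(\log_2(1 + tf/2)\)) crosses 0.10 near tumour fraction
\(tf \approx 0.15\), consistent with the common observation that sWGS
copy-number analysis resolves tumour content only in the several-percent
regime and above. A sample is *CNA-detectable* when it carries at least one
non-neutral segment spanning ≥ 3 bins — an objective replacement for by-eye
profile matching.

## Genome-wide imbalance score and profile concordance

Both bespoke sWGS statistics are affine-regression based. Test and control
profiles are compared on their shared valid autosomal bins by ordinary least
squares of test on control; the control is the correction of the *summed*
raw counts of the germline (buffy coat) samples, which makes pooling
order-free. The **imbalance score** is the sum of squared residuals over the
5% of bins with the largest squared residuals (`ceiling` for fractional
counts; ties broken by bin order). Reading "most extreme residuals" as
largest *squared* residuals reconciles the two natural phrasings — the sum
of squared residuals, restricted to the extreme 5% — and is equivalent to
absolute-value ranking for selection. Restricting to the tail makes the
score insensitive to baseline noise; it is zero exactly when the test is an
affine function of the control, and it grows monotonically with tumour
fraction on a fixed aberrant profile (a property asserted in the test
suite). No published positivity threshold exists for this score, so the
package exposes a leave-one-out control calibration
(`imbalance_threshold()`: the maximum score of each control against the pool
of the others) and labels it an artifact of this implementation.

**Concordance** between two profiles is the adjusted
\(R^2 = 1 - (1 - R^2)(n-1)/(n-2)\) of the same regression; it may dip
slightly below zero for null comparisons. In the clonal-switch scenario the
early-urine profile is discordant with the eventual cystectomy-truth profile
while the late-urine profile is concordant, reproducing the qualitative
pattern the assay is designed to reveal.

## Outcome layer

All proportions carry exact Clopper–Pearson intervals from Beta quantiles
(lower \(q_{\beta}(\alpha/2; k, n-k+1)\), upper
\(q_{\beta}(1-\alpha/2; k+1, n-k)\)); a zero denominator flags the metric
undefined rather than silently zero. Kaplan–Meier curves and the two-group
log-rank test delegate to the `survival` package (the field standard), with
an independent hand-computed risk-table oracle in the tests. Group
comparisons: two-sample Kolmogorov–Smirnov on AF distributions by outcome;
per-timepoint 2×2 chi-squared on detection counts, *without* continuity
correction (the convention is configurable via `correct =`), Bonferroni
adjusted over timepoints; Kruskal–Wallis across PLS/UCP/USN with a
hand-written Dunn post-hoc (tie-corrected rank variance, Bonferroni over the
three pairs — the family-wise method is a package choice, stated here
because conventions differ). Report formatting follows clinical convention:
percentages to one decimal, CI bounds as integer percent, medians rounded
half-up to whole days.

## The synthetic cohort: what it emulates, and what it does not

The generator's defaults encode the study conditions the package models:

* **Design** — 17 patients, 8 recurrers; five on-treatment visits at days
  30, 51, 72, 93, 114 after the initial resection (TUR, day 0); three fluids
  per visit; a TUR tumour sample (tumour content 0.7) and a germline buffy
  coat per patient; 8 germline sWGS controls for the pooled reference.
* **Sequencing** — 13.6 million sWGS reads/sample over an 8-chromosome,
  40 × 1 Mb-bin frame; 7600× amplicon depth; symmetric substitution error
  10⁻⁴; negative-binomial bin counts with overdispersion 4 × 10⁻⁴ (≈ 2%
  coefficient of variation — a clean 1 Mb-bin profile at this depth).
  The compact genome keeps segmentation fast while leaving 16 bins in the
  imbalance score's 5% tail; detection-limit properties use a larger
  10 × 60-bin frame so a 30-bin event stays below 10% of the genome.
* **Molecular input** — GE per reaction log-uniform on [100, 10⁵], spanning
  the observed range of amplifiable copies in such cohorts. The variant
  simulator draws mutant molecules Binomial(GE, AF) *first*, then resamples
  reads from that finite pool: low-GE reactions genuinely lose rare alleles,
  which is precisely what the 1/GE floor exists for. A corollary worth
  noting: a reaction containing a single true mutant molecule produces reads
  that straddle 1/GE, so occasional legitimate single-molecule detections
  occur in low-burden samples; they are true detections of real mutant DNA,
  not assay error.
* **Trajectories** — persistent shedders (pre-NAC tumour fractions
  USN 0.18 / UCP 0.12 / PLS 0.02, mild lognormal wobble over visits),
  responders decaying below the detection floor by cycle 2 (× 0.05 at visit
  2, × 0.001 by the last visit), a clonal switch (dominant sensitive clone
  with its own CNA/SNV profile receding as a resistant clone rises, clone
  fractions crossing once), and mutDNA-absent patients — one evaluable
  low-shedder among the recurrers (the archetypal false negative) and four
  patients with no panel SNVs at all (the unevaluable stratum). Urine
  exceeds plasma in every archetype, reflecting direct shedding from the
  bladder; the urine-to-plasma ratio is a free scenario parameter, not an
  estimate — no shedding model is available to calibrate it. The urinary
  levels were chosen so that pre-NAC urine sits above the CNA detectability
  limit while plasma sits below it, matching the reported pattern that
  copy-number signal is found in roughly half of pre-treatment urine samples
  but a quarter of plasma.
* **AF model** — a variant's true AF is `tf × clone_fraction / 2`: clonal,
  heterozygous, copy-neutral. Copy-number-aware AF adjustment is
  deliberately omitted; it would couple the two arms of the simulator
  without changing what the detection rule is tested on.

What passing tests on this cohort do *not* show: the generator has no
fragment-size structure, no FFPE artefacts, no sample cross-contamination,
no within-patient correlation of GE across visits, and clean clonal
structure; real cohorts are messier in all five ways. Conclusions supported
are about the pipeline's arithmetic and its operating characteristics under
the stated noise model, not about clinical performance.

## Problem sizes and determinism

Everything is seeded: the genome, the scenario, every count and read draw,
and the CBS permutation stream (restored afterwards, so library calls never
disturb the caller's RNG). The test suite and the acceptance script run the
default cohort (255 fluid samples assayed for SNVs; sWGS on the first and
last visits plus TUR/BUF/controls, 136 segmented profiles), 20-seed
detection-frequency sweeps at tumour fractions 0.20 and 0.01, and a
10⁴-locus germline error sweep — a few minutes end to end on one CPU. The
synthetic log-rank comparison has only 13 evaluable patients; its p-value is
significant at the default seed but, as in any cohort this size, hovers
around the 0.05 boundary across seeds. The published cohort's contingency
table, by contrast, is recomputed exactly from its stated counts.

## Known limitations

* CBS here has no pruning/undo pass and an \(O(n^2)\) split search; both are
  fine to a few hundred bins per chromosome but would need attention for
  50 kb bins genome-wide.
* The GC correction can absorb very large events on very small bin frames
  (see above).
* The imbalance-score positivity threshold is a pipeline artifact, not a
  published calibration.
* Absolute copy number, ploidy and sex chromosomes are out of scope; the
  profiles are autosomal log2 ratios only.
* The tumour-fraction estimator (`2 × mean panel AF`) assumes clonal
  heterozygous variants; it under-estimates in samples dominated by a
  subclone, which is visible in the clonal-switch patient.
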