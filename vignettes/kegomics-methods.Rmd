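---
title: "Harmonizing knock-out multi-omics: methods and design notes"
author: "kegomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing knock-out multi-omics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kegomics)
```

## The problem

A knock-out (KO) series — here wild-type Arabidopsis plus eight arogenate
dehydratase (ADT) KO genotypes of increasing order, in leaf and stem — is
profiled on three platforms at once: 8-plex iTRAQ proteomics,
RNA-Seq transcript counts, and GC/LC-MS metabolite abundances. The three
layers arrive on incommensurable scales with platform-specific noise, so the
package's job is to place every layer on one comparable scale (z-scores of
log2 KO/WT ratios), collapse genes and proteins into KEGG Orthology enzyme
families (KEGOs), join the layers through substrate/product reactions, and
finally mine the protein layer for candidates whose abundance tracks a
phenotype — stem lignin G+S monomer content — across the KO series.

## iTRAQ rollup

Each identified MS/MS spectrum carries a base-peak intensity and eight
reporter-ion intensities. The pipeline:

1. distributes the base-peak intensity over channels proportionally to each
   reporter's share of the summed reporter signal, so channel intensities
   sum to the base peak and reproduce the reporter ratios exactly;
2. sums multiple spectra of a peptide within a plex channel-wise (linear
   scale), then log2-transforms;
3. shifts each peptide row per plex so its pooled-reference channel equals
   the peptide's cross-plex mean reference value. Any common anchor yields
   identical contrasts; the mean is used because it needs no arbitrary
   choice of a "master" plex. Plex rows lacking a reference value cannot be
   anchored and are dropped with a warning;
4. mean-centers every sample column (idempotent; removes channel loading);
5. un-logs, sums peptides per protein separately within the unique-peptide
   and shared-peptide sets, prefers the unique-peptide rollup when it is
   identified in all channels, and re-logs. Proteins with identical peptide
   sets are indistinguishable and reported as one `;`-joined group.

Column centering deliberately destroys the absolute abundance scale, which
the MA plot's A axis and the noise floor need. `shiftToAbundanceScale()`
restores each protein row's anchor from the aligned (uncentered)
unique-peptide linear table; within-row contrasts are untouched. Log2
values strictly below the noise floor (default 2.0) are then treated as
noise and removed; cells exactly at the floor are retained.

## Abundance-localized z-scores

For each KO line and tissue, replicates are averaged per side and each
entity gets M = mean(KO) − mean(WT) and A = (mean(KO) + mean(WT))/2. The
variance of M shrinks as A grows (counting noise, detector floor), so a
single global standard deviation misstates significance at both abundance
extremes. Records are therefore ranked by A and each record is standardized
against its window of w = max(3, round(0.10·n)) rank-nearest neighbours:

z = (M − median(window M)) / sd(window M)

with two-sided normal p = 2(1 − Φ(|z|)). Design choices:

* **Median center, sd spread.** The centering statistic is the window
  median (robust to the minority of true signals inside a window); the
  spread is the conventional n−1 sample standard deviation. A MAD spread is
  available (`spread = "mad"`) but off by default.
* **Clamped windows.** Edge windows are clamped to full width rather than
  truncated, so tail variance estimates use as much data as interior ones.
* **Determinism.** Ties in A are broken by entity id.
* **Zero-spread guard.** A window whose variance is indistinguishable from
  numerical cancellation noise yields missing z rather than ±Inf.
* **Per-contrast ranking.** Each KO-vs-WT contrast is ranked and windowed
  on its own (a config switch pools all contrasts into one ranked set). Per
  contrast keeps calibration intact when contrasts differ in depth.
* **Pseudocount.** Transcript counts get +1 before log2.
* **No multiple-testing correction** is applied to the primary outputs; a
  Benjamini–Hochberg column is emitted alongside for convenience.

The module's core property is calibration: on a true-null set with
abundance-dependent noise spanning a 4-fold sd range, the fraction of
|z| ≥ 1.96 must sit near 0.05 globally *and within every abundance decile*,
which a global z cannot do. The test suite and `scripts/acceptance.R`
measure exactly this on 10,000 generated null pairs.

## KEGO collapse

Protein KEGOs sum the unique-peptide linear values of member proteins;
transcript KEGOs sum member counts; results are then log2-transformed. An
entity mapping to several KEGOs contributes its full value to each (the
summation rule has no fractional reading; multiplicity is checked by the
mass-conservation test). Collapsing averages out entity-level noise and
within-family regulation, so transcript–protein correlation at KEGO level
should match or exceed the entity level — asserted on synthetic data with
family-level effects, and reported by the acceptance script as the mean
entity-level and KEGO-level correlations.

## Reaction triads and clusters

Each detected metabolite is paired with every KEGO that uses it as
substrate or product in a reaction table, provided the KEGO was detected in
*both* the transcript and protein layers. Triads carry z-profiles across
the KO contrasts per layer; signs of the per-layer mean z classify them:

| cluster | transcript | metabolite | protein |
|---------|-----------|------------|---------|
| 1 | together | together | together |
| 2 | opposed  | together | together |
| 3 | together | together | opposed |
| 4 | together | opposed  | together |

Both sign polarities of each pattern belong to the same cluster; any
exactly-zero mean is `unclassified` (zeros have measure zero on real data).
Pearson correlations r_tm, r_pm, r_tp are computed across pairwise-complete
contrasts (≥ 3 required). Per metabolite, flags mark the most abundant KEGO
(protein-layer mean abundance by default; the layer is an argument), the
best transcript- and protein-correlated KEGOs (ties broken by KEGO id), and
single-reaction metabolites. Rows are ordered by cluster, then role
(substrate, product, reversible), then descending mean metabolite z.

## Phenotype network

Per-protein stem log2-ratio profiles across the eight KO lines are
rank-correlated (Spearman, average ranks) against the per-line lignin G+S
vector. A candidate passes when |rho| ≥ 0.85 — both signs retained, and the
boundary inclusive by default since either convention is defensible — *and*
its z in the adt1-vs-WT stem contrast lies within ±0.5: adt1 retains
near-wild-type lignin, so a genuinely lignin-tracking protein should be
essentially unchanged there. The band also works as a false-positive
filter: a null protein can only reach high |rho| when its adt1 ratio is
extreme among its eight line values, which pushes its |z| out of the band.
Edges between passing candidates are kept at combined score ≥ 0.4, isolated
candidates are dropped, and the network is exported as SIF plus a node
attribute table (z per contrast for red/blue coloring, functional
category).

## The synthetic-data generator

`generateStudy()` emulates the study design so every stage is testable
without any download. Its defaults are the study conditions:

* 9 lines (WT + 8 ADT KOs) × 2 tissues; proteome/transcriptome n = 3
  replicates, metabolome n = 9 (replicate counts per layer are not uniform
  in this kind of design; both are configurable);
* 500 proteins × 3 peptides (20% shared between two proteins), 2000
  transcripts, 100 metabolites, KEGO families of 3 genes;
* lignin G+S vector (relative units): WT 100, adt1 99 (near wild type),
  single KOs 76–85, double 60, triples 45/32, quadruple 30 — monotone in
  mutation order with the deep multiples at ~30% of wild type;
* effects are planted at KEGO level and shared between a family's
  transcript and protein members (entity noise sd 0.25 on top of family
  effects sd 0.5), which is what makes KEGO collapse informative;
* 20 planted lignin-tracking proteins whose per-line log2 effects are an
  affine function of the lignin vector (slope magnitude 1.5–2.5, alternating
  sign) plus Gaussian noise of sd 0.05;
* measurement noise sd σ(A) = 0.5·2^(−(A−4)/4) clamped to [0.125, 0.5] — a
  4-fold monotone non-increasing span. Proteome base abundances are drawn
  at log2 ~ N(12, 2), a reporter-intensity scale at which the σ(A) floor
  keeps measurement noise subordinate to the planted 0.05 profile noise;
* every peptide is quantified in every plex by default (one digest mixture
  distributed across plexes); a `pepObsProb` parameter introduces dropout
  when the missing-reference code paths are the object of study. With
  dropout, a missing peptide shifts a 3-peptide protein sum by ~0.58 log2 —
  a bias, not noise — so it is not part of the default conditions;
* the reference-pool channel is generated as the mean of all line channel
  values per peptide plus noise (sd 0.05), mirroring a pooled reference;
* transcripts are negative binomial (size 10), metabolites log-normal with
  internal-standard and tissue-weight factors multiplied in (the pipeline
  divides them back out);
* the interaction table contains a ring plus random pairs among the planted
  set at score 0.7–0.95 and 800 random decoy edges at 0.05–0.9.

What the generator does **not** emulate: peptide identification errors and
FDR, reporter-ion isotope impurity, chromatographic batch effects,
metabolite annotation ambiguity, and correlated biological replicates.
Passing tests therefore demonstrate that the procedures are implemented
correctly and behave as designed under the stated noise model — not that
the thresholds are optimal for any particular real instrument.

## Problem sizes and seeds

The test suite runs the full default study (500 proteins, 54 proteome
samples over 8 plexes) for the recovery and determinism checks, a 2-plex
variant for rollup conservation, 10,000 null pairs for calibration, and
reduced studies (30–150 proteins) for orchestration tests. All stochastic
checks fix their seeds; `scripts/acceptance.R` takes `--seed` and threads
it through every generator call. The recovery bounds (sensitivity ≥ 0.90,
FDP ≤ 0.10 among ~20 passing candidates) are statements about the seeded
default study; across arbitrary seeds the false-positive count is
approximately Poisson with mean near 1, so occasional seeds exceed an FDP
of 0.10 with a handful of false positives.

## Known limitations

* The exact arithmetic behind distributing base-peak intensity over
  reporter channels admits more than one reading; the proportional-share
  form is implemented because literal division by a relative ratio inverts
  abundance ordering.
* Whether column centering in the original procedure acted per plex channel
  or per final sample column is not fully determinate; it is applied per
  sample column here.
* Indistinguishable-protein grouping is parsimony-style only; no
  probabilistic peptide assignment is attempted.
* The real-data mode ingests tabular exports (spectrum reports, counts,
  STRING tables); vendor formats and live database queries are out of
  scope.
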