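# kegomics

Multi-omics harmonization for knock-out series: iTRAQ peptide-to-protein
rollup, abundance-localized MA-plot z-scores, KEGG-Orthology (KEGO)
collapsing, transcript–metabolite–protein reaction triads, and
phenotype-correlated protein networks.

## The problem

Comparing a panel of knock-out (KO) genotypes against wild type across
proteome (8-plex iTRAQ), transcriptome (RNA-Seq counts) and metabolome
(internal-standard-normalized abundances) requires putting three platforms
on one scale. `kegomics` does this with the sliding-window z-score: for each
KO-vs-WT contrast, every entity gets

- **M** = mean(KO) − mean(WT) (log2 fold change),
- **A** = (mean(KO) + mean(WT)) / 2 (average log2 abundance),
- **z** = (M − median(window M)) / sd(window M), where the window is the
  10% of entities rank-nearest in A,
- **p** = 2(1 − Φ(|z|)).

Because measurement variance shrinks with abundance, standardizing against
abundance-local windows keeps z calibrated at every abundance — which is
what lets z-scores from sequencing and mass spectrometry be compared
directly, collapsed into KEGO enzyme families, joined through
substrate/product reactions into Cluster 1–4 triads, and correlated
(Spearman |rho| ≥ 0.85, with an adt1 z-band filter of ±0.5) against the
per-line stem lignin G+S phenotype to seed a STRING-style interaction
network (combined score ≥ 0.4, degree ≥ 1, SIF export).

A seeded synthetic-study generator reproduces the study design — WT + 8 ADT
KO lines × 2 tissues, pooled-reference iTRAQ plexes, unique/shared
peptides, negative-binomial counts, log-normal metabolites, heteroscedastic
noise, and a planted set of lignin-tracking proteins — so the whole
pipeline is testable end to end with known ground truth.

## Worked example

```r
library(kegomics)

s <- generateStudy(seed = 1)
s
#> SyntheticStudy
#> StudyDesign: 9 lines (WT = WT), 2 tissue(s), 3 replicate(s)
#>   54 samples over 8 iTRAQ plex(es), one reference channel each
#>   12000 spectra | 2000 transcripts | 100 metabolites | 20 planted lignin-tracking proteins

runPipeline(defaultConfig(), seed = 1, outDir = "results")
```

The run writes every intermediate table plus a deterministic
`manifest.yaml` of md5 checksums. Key numbers from this run:

```r
cc <- read.delim("results/fig2_correlations.tsv")
mean(cc$r_entity)   # 0.572  transcript-protein correlation, gene level
mean(cc$r_kego)     # 0.723  after KEGO collapse: family-level effects emerge

cand <- read.delim("results/candidates.tsv")
sum(cand$passes)    # 20 proteins pass |rho| >= 0.85 and |z_adt1| <= 0.5
head(cand[cand$passes, c("protein", "rho", "adt1_z")], 3)
#>    protein    rho  adt1_z
#> 11   G0011  1.000  0.0923
#> 41   G0041 -0.976  0.2545
#> 55   G0055  1.000 -0.2539

length(readLines("results/network.sif"))   # 84 candidate-candidate edges

tri <- read.delim("results/triads.tsv")
table(tri$cluster)  # reaction triads per sign-concordance cluster
#>  1  2  3  4
#> 93 58 56 85
```

The 20 passing candidates are exactly the planted lignin-tracking set for
this seed; the rise from 0.57 to 0.72 in transcript–protein correlation
after KEGO collapse is the family-level signal the collapse is designed to
expose. A thin CLI lives in `inst/scripts/multiomics-run.R`
(`run` and `simulate` subcommands).

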