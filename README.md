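# npxspectrum

Serum-proteomics analysis of inflammatory bowel disease (IBD) heterogeneity:
from Olink-style NPX matrices through differential screening and a
from-scratch **SCAD + ridge penalized logistic regression** to CD-vs-UC
probability scores that place disease subgroups along an ileal–colonic
continuum.

## Who this is for

IBD is conventionally split into Crohn's disease (CD) and ulcerative colitis
(UC), but subgroups defined by the Montreal location of inflammation behave
like points on a spectrum: purely colonic disease (UC, colonic CD) at one
end, ileal CD at the other, ileocolonic CD between. This package is for
researchers who want to quantify that spectrum from targeted serum protein
panels (NPX units: relative protein levels on the log2 scale, with per-assay
limits of detection, plate/batch labels and QC flags), or to prototype such
analyses on synthetic cohorts when patient-level data cannot be shared.

## What it computes

For CD (y = 1) vs UC (y = 0) on standardized protein levels *x*, the core
model minimizes

```
(1/n) Σ log(1 + exp(-(2y-1)(β₀ + xᵀβ)))  +  Σⱼ [ p_SCAD(|βⱼ|; αλ, a) + ((1-α)λ/2) βⱼ² ]
```

with α = 0.1 (mostly ridge, mild sparsity), SCAD shape a = 3.7, at most 28
proteins in the model (path cap), λ chosen by stratified inner 5-fold CV.
Nested cross-validation (outer leave-one-out, or k-fold at desk scale) with
10-model averaging yields an out-of-sample **probability score in [0, 1]**
per sample; per-subgroup medians, one-way ANOVA + Tukey HSD, coefficient
stability over repeated refits, restricted AUCs and a down-sampled
repeated-CV benchmark of four classifier families complete the pipeline.
Preprocessing (QC exclusion, assay exclusion, the strict ">90% below LOD"
protein filter, batch adjustment) and the univariate screen (Welch t-tests,
Benjamini–Hochberg FDR < 0.05, |fold-change| > 1.2 i.e. |log2FC| > ~0.26)
follow the conventions described in the methods vignette.

## Worked example

```r
library(npxspectrum)

cfg <- synthetic_config(
  group_sizes = c(UC = 150, CD_L2 = 150, CD_L3 = 150, CD_L1 = 150, HC = 100),
  n_proteins = 86, seed = 42)
cohort <- generate_cohort(cfg)

ds     <- adjust_batches(exclude_below_lod(apply_qc(cohort$dataset)))
groups <- assign_groups(cohort$meta)
ds
#> npx_dataset: 689 samples x 86 proteins, 4 batch(es), 0 QC fail
#>   below-LOD values: 1186 (2.00%)

screen <- pairwise_screen(ds, groups, list(c("CD_L1", "UC")))
sum(screen$significant)       # proteins with q < 0.05 and |log2FC| > log2(1.2)
#> [1] 21

scores <- nested_cv_scores(ds, groups, outer = 10, repeats = 10, seed = 42)
group_medians(scores[scores$in_training, ])
#>   group   n    median        q1        q3
#> 1    UC 149 0.5327183 0.4074809 0.6554738
#> 2 CD_L2 146 0.7324531 0.6213334 0.7942480
#> 3 CD_L3 147 0.8714703 0.8256843 0.9190865
#> 4 CD_L1 149 0.9130625 0.8792259 0.9368124

anova_tukey(scores)$tukey[, c("pair", "diff", "p_adj")]
#>            pair        diff        p_adj
#> 1 CD_L2 - CD_L1 -0.20180052 5.001028e-10
#> 2 CD_L3 - CD_L1 -0.04450985 7.145407e-03
#> 3    UC - CD_L1 -0.37208519 5.001028e-10
#> 4 CD_L3 - CD_L2  0.15729067 5.001122e-10
#> 5    UC - CD_L2 -0.17028466 5.001028e-10
#> 6    UC - CD_L3 -0.32757534 5.001028e-10

score_auc(scores$score, as.numeric(scores$group == "CD_L1"),
          scores$group, c("UC", "CD_L1"))   # UC vs ileal CD
#> [1] 0.98
score_auc(scores$score, as.numeric(scores$group == "CD_L2"),
          scores$group, c("UC", "CD_L2"))   # UC vs colonic CD
#> [1] 0.78
```

Reading the output: the median probability scores order the subgroups along
the planted continuum — UC (0.53) < colonic CD (0.73) < ileocolonic CD
(0.87) < ileal CD (0.91) — with every Tukey pair significant; the score
separates UC from ileal CD far better (AUC 0.98) than from colonic CD
(AUC 0.78), the characteristic asymmetry of the IBD spectrum. (Numbers are
from this synthetic cohort; on real serum panels effects are weaker.)

## Command line

```sh
Rscript inst/cli/npxspectrum.R simulate --seed 1 --outdir out/
Rscript inst/cli/npxspectrum.R run --stage all --seed 1 --outdir out/ \
    --npx out/npx_long.csv --metadata out/sample_meta.csv
```

Stages (`preprocess`, `screen`, `spectrum`, `benchmark`, `all`) write TSV/JSON
outputs plus a JSON-lines log with sample/protein counts after every filter.
A YAML config (`--config`) can override any default; see `?pipeline_config`.

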