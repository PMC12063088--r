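---
title: "Methods: serum-protein scoring of the IBD spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum-protein scoring of the IBD spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Crohn's disease (CD) and ulcerative colitis (UC) are conventionally treated as
two diagnoses, but clinically and biologically the subgroups of inflammatory
bowel disease (IBD) behave more like points on a continuum ordered by the
location of inflammation: purely colonic disease (UC, colonic CD) at one end,
purely ileal CD at the other, ileocolonic CD in between. `npxspectrum`
implements a serum-proteomics pipeline that makes this continuum measurable
from targeted protein panels (Olink-style NPX data, i.e. relative protein
levels on the log2 scale):

1. **Preprocessing** — QC exclusion, removal of assays unavailable across
   batches, removal of proteins mostly below the limit of detection (LOD),
   batch adjustment.
2. **Univariate screening** — Welch t-tests per protein and group pair,
   Benjamini–Hochberg FDR, and a fold-change gate; a covariate-adjusted
   linear-model screen as robustness companion; a PCA overview with
   Kruskal–Wallis/Dunn group tests.
3. **Probability scores** — a from-scratch SCAD+ridge penalized logistic
   regression distinguishing CD from UC, used in nested cross-validation so
   that every sample gets an out-of-sample predicted probability of CD in
   [0, 1]. The per-subgroup distribution of these scores *is* the spectrum:
   medians ordered UC < colonic CD < ileocolonic CD ≈ ileal CD.
4. **Benchmarking** — a down-sampled, repeated 5-fold CV comparison of four
   classifier families on subgroup pairs, summarized by median AUC.

Because the patient-level data behind the original analysis cannot be shared,
the package ships a **synthetic cohort generator** whose draws have the
statistical structure the analysis assumes, plus ground truth, so that every
stage is testable end to end.

## The model behind the scores

For binary outcome $y_i \in \{0,1\}$ (CD = 1, UC = 0) and standardized
protein levels $x_i$, the solver minimizes

$$\frac{1}{n}\sum_i \log\!\left(1 + e^{-(2y_i-1)(\beta_0 + x_i^\top\beta)}\right)
  + \sum_j \left[ p_{\text{SCAD}}(|\beta_j|;\lambda_1, a)
  + \frac{\lambda_2}{2}\beta_j^2 \right],$$

with $\lambda_1 = \alpha\lambda$ and $\lambda_2 = (1-\alpha)\lambda$.
$p_{\text{SCAD}}$ is the standard three-zone smoothly clipped absolute
deviation penalty: its derivative is $\lambda_1$ up to $\lambda_1$, decays
linearly to zero at $a\lambda_1$, and is zero beyond — so small coefficients
are soft-thresholded while large ones are left unbiased.

Parameters that matter:

* `alpha` (default **0.1**) — the SCAD share of the penalty. At 0.1 the fit
  is mostly ridge with mild sparsity: coefficients are stabilized against the
  strong correlations typical of inflammation panels, yet a limited subset is
  driven exactly to zero.
* `a` (default **3.7**) — the canonical SCAD shape value; the reference
  analysis does not state one, and results are insensitive within 3–5.
* `df_max` (default **28**) — the cap on the number of proteins in the
  model, enforced as a *path cap*: the descending $\lambda$ path stops at the
  first fit whose active set exceeds the cap and that fit is discarded.
* `lambda` — never set by hand; selected per fit by stratified inner 5-fold
  cross-validation minimizing the out-of-fold binomial deviance (the loss is
  not stated in the reference; deviance is the standard choice, AUC is
  available via `criterion = "auc"`). Ties break toward the larger
  (more regularized) $\lambda$.

### Optimization and numerical choices

The solver is IRLS-MM: the logistic loss is majorized by a quadratic with
fixed curvature $w = 1/4$ (a true global bound on the logistic Hessian), and
the quadratic-plus-penalty problem is solved by cyclic coordinate descent.
Each scalar subproblem is minimized *exactly* by evaluating the stationary
candidates of the three SCAD zones together with the zone boundaries — not by
applying the textbook zone formula blindly, which can fail to be the argmin
when $w + \lambda_2 < 1/(a-1)$ makes the middle zone non-convex. Exact scalar
minimization of a true majorizer guarantees the penalized objective is
non-increasing across outer iterations and that first-order (KKT) residuals
vanish at convergence; both are tested. Because SCAD is nonconvex, the
solution is a stationary point, not a certified global optimum — acceptance
is through oracle agreement in the convex limits ($\lambda \to 0$ against the
unpenalized MLE, $\alpha = 0$ against a BFGS ridge solution, $\alpha = 1$
with $a \to \infty$ against `glmnet`'s lasso), not through global claims.

Convergence: largest coordinate update below `tol` (default 1e-8); the
intercept is never penalized; predictors are z-standardized internally
(1/n variance convention) and coefficients are reported on both scales.
$\lambda_{\max} = \max_j |x_j^\top(y-\bar y)| / (n\max(\alpha, 0.001))$ makes
the first path fit empty; the grid is log-spaced down to
`lambda_min_ratio * lambda_max`.

### Nested cross-validation and the repeat mechanism

The outer loop is leave-one-out by definition (`outer = "loo"`); k-fold
(`outer = 10`) estimates the same quantity at desk scale and is what the
tests use. For each held-out sample, `repeats` (default 10) models are
trained on the remainder; the repeats differ *only* in the inner-CV fold
assignment, hence in the selected $\lambda$ — this is the stated source of
model-to-model variability — and the held-out probabilities are averaged.
IBD-U and HC samples never enter training; they are scored by the same
repeated models refitted on all CD/UC data (`in_training = FALSE`). Whether
the original analysis scored them from full-data models or some CV scheme is
unstated; projection from full-data models is the choice here because it uses
every training sample and keeps the scored samples strictly out of training.

Group comparisons of scores use a from-scratch one-way ANOVA with Tukey's HSD
(Tukey–Kramer standard errors for unequal group sizes, studentized-range
p-values and simultaneous CIs, verified against `TukeyHSD`). Medians/IQRs are
reported descriptively while ANOVA/Tukey compare means, mirroring the mixed
convention of the reference analysis. HC is excluded from ANOVA/Tukey by
default. Note that for $k \ge 3$ groups Tukey controls the *familywise* error
at $\alpha$; individual pairs are rejected at a rate below $\alpha$ under the
complete null, which is what the calibration tests check.

Coefficient stability refits the full-data model (default 1000 times; tests
use 200) with fresh inner CV each time and summarizes each protein's
coefficient distribution and selection frequency; proteins are ranked by
median absolute standardized coefficient, the importance measure behind the
signature.

## What the synthetic cohort emulates — and what it does not

Each sample $i$ in group $g$ with batch $b$ is drawn as

$$\text{NPX}_{ij} = \mu_j + w_j\,\theta_g + \text{IBD}_i\,\delta_j + b_{bj}
 + \beta_{\text{age}}\,\text{age}_i + \beta_{\text{sex}}\,\text{sex}_i
 + \beta_{\text{dur}}\,\text{dur}_i + \varepsilon_{ij},
 \qquad \varepsilon_{ij} \sim N(0, \sigma^2).$$

* $\theta_g \in [0,1]$ is the latent ileal–colonic position (defaults:
  UC = 0, colonic CD = 0.35, ileocolonic CD = 0.8, ileal CD = 1.0); HC is
  pinned at $\theta = 0$ and receives **no** IBD offset, so the healthy-vs-IBD
  contrast ($\delta_j$, on its own protein subset, mostly positive — the
  inflammation direction) is separate from the location contrast, as in the
  reference analysis.
* $w_j$ loads `n_signal` (default 20) of `n_proteins` (default 86) proteins
  with magnitude `effect_scale` (default 0.8 NPX) and alternating sign, so
  both ends of the continuum have markers.
* Batch shifts are i.i.d. $N(0, \text{batch\_sd}^2)$ per batch and protein;
  the per-protein LOD sits at the `lod_quantile` (default 2%) quantile of
  realized values, and below-LOD values are *kept and flagged*, never
  imputed — the reference never states an imputation rule, and flags keep
  preprocessing reversible.
* Covariates: age ~ Uniform(18, 80), sex ~ Bernoulli(1/2), disease duration ~
  Exponential(mean 8 y) truncated at 40 y (0 for HC) — plausible adult-IBD
  ranges; the exact distributions are free parameters, stated rather than
  fitted, because the underlying data are unavailable. Default group sizes
  are the real subgroup counts (UC 639, ileal CD 275, colonic CD 188,
  ileocolonic CD 420, HC 312).

The generator does **not** emulate protein–protein correlation beyond what
the shared latent factor induces, assay-specific noise distributions,
longitudinal structure, or medication effects. A green continuum-recovery
test therefore establishes that the pipeline recovers the ordering *its own
generative assumptions encode* — it cannot certify performance on real serum
panels, whose correlation structure is richer. The default `residual_sd = 1`
with `effect_scale = 0.8` makes single-protein effects detectable but weak
(planted group differences of 0.3–0.8 NPX across 20 proteins), roughly the
regime in which the real analysis operates (overall CD-vs-UC AUC near 0.75,
not 0.99).

## Preprocessing conventions

* Below-LOD flags use strict `NPX < LOD`; the exclusion rule removes a
  protein only when its below-LOD fraction is strictly greater than 90%
  (exactly 90% is retained). Missing values never enter denominators.
* The batch-adjustment procedure of the reference analysis lives in an
  unavailable supplement; three standard location(/scale) methods are
  exposed, defaulting to per-protein median-centering, which is idempotent
  and preserves within-batch ranks. LODs are shifted with the same maps.
* Montreal mapping: CD is split by location L1/L2/L3 after stripping an L4
  modifier; CD with *isolated* L4 has no ileal/colonic location and is
  excluded from location groups with a warning; CD with missing location is
  an error rather than silent exclusion.
* Proteins are z-standardized only inside model fitting, never during
  preprocessing, so univariate log2 fold-changes stay on the NPX scale
  (NPX is already log2, so a mean difference *is* a log2 fold-change).
* BH correction is applied within each pairwise contrast across proteins,
  matching per-volcano FDR display; whether the original pooled across
  contrasts is unstated.

## Benchmark design

`downsample_groups()` equalizes group sizes before every CV repeat (with the
real subgroup counts every pair involving colonic CD lands at n = 188 per
arm); `repeated_cv_auc()` then runs stratified 5-fold CV with all tuning,
standardization and down-sampling inside training folds. Four families share
one adapter contract. The two penalized-logistic families use this package's
own solver. Because no random-forest or SVM package exists in the offline
runtime, the forest is a compact in-package CART ensemble (bootstrap + `mtry`
feature sampling, Gini splits, leaf-probability averaging, `mtry` tuned by
inner CV) and the radial-kernel family is a least-squares SVM (kernel ridge
on ±1 labels), whose decision values are used directly as AUC ranking
scores — for rank-based AUC the monotone link makes probability calibration
irrelevant. The number of CV repeats is unstated in the reference
("repeated"); the default is 20, tests use fewer.

## Known limitations

* SCAD is nonconvex: different warm starts can reach different stationary
  points. The path's warm-start continuity makes results deterministic given
  a seed, but a global optimum is not guaranteed.
* The LS-SVM stand-in differs from a hinge-loss SVM in its loss; at the
  benchmark's sample sizes its ranking behaviour is close, but margins are
  not sparse.
* Leave-one-out at the original cohort scale (1863 samples × 10 repeats ×
  inner CV) is computationally faithful but slow; the k-fold outer option is
  the intended desk-scale surrogate.
* The synthetic cohort's independence assumptions make screening power
  estimates optimistic relative to correlated real panels.

## Reproducibility

Every stochastic routine takes a seed and derives all internal stream seeds
from it; reruns are byte-identical. The command-line pipeline
(`inst/cli/npxspectrum.R`, or `cmd_simulate()` / `cmd_run()` from R) logs
sample and protein counts after every exclusion as JSON lines, reproducing
the audit trail a preprocessing section reports.
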