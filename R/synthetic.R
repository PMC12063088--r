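#' Configuration for the synthetic IBD serum-proteomics cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a latent ileal-colonic disease continuum theta in \[0,1\] loading a
#' sparse protein signature, an IBD-vs-healthy offset on a separate protein
#' subset, per-batch location shifts, left-censoring at a per-protein limit of
#' detection, covariate effects (age, sex, disease duration) and i.i.d.
#' Gaussian residual noise on the log2 NPX scale.
#'
#' Default group sizes are the real cohort's subgroup counts (UC 639, ileal CD
#' 275, colonic CD 188, ileocolonic CD 420, HC 312); default continuum
#' positions put UC and ileal CD at opposite ends with colonic CD closer to UC
#' and ileocolonic CD closer to ileal CD.
#'
#' @param group_sizes named integer vector of samples per analysis group.
#' @param group_positions named numeric vector theta_g in \[0,1\]; must cover
#'   every group in `group_sizes` (HC is pinned at 0 and additionally receives
#'   no IBD offset).
#' @param n_proteins panel size (default 86).
#' @param n_signal number of continuum-loaded signature proteins.
#' @param effect_scale magnitude of the signature loadings w_j, in NPX log2
#'   units per unit theta; signs alternate so both ends of the continuum have
#'   markers.
#' @param ibd_shift NPX offset added to all IBD groups (not HC) on
#'   `n_ibd_proteins` proteins; most are positive (inflammation up), a small
#'   fraction negative.
#' @param n_ibd_proteins size of the IBD-vs-HC offset subset (default 30).
#' @param n_batches,batch_sd number of batches and SD of the per-batch,
#'   per-protein location shift (NPX units).
#' @param residual_sd residual noise SD (NPX units), default 1.
#' @param lod_quantile per-protein LOD placed at this quantile of the
#'   protein's realized distribution; in \[0,1).
#' @param qc_fail_rate i.i.d. probability that a sample fails QC.
#' @param covariate_effects named numeric vector with elements `age`
#'   (NPX per year), `sex` (NPX for male vs female) and `duration`
#'   (NPX per year), applied to all proteins.
#' @param mu_mean,mu_sd mean and SD of per-protein baseline levels mu_j.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(group_sizes = c(HC = 312, UC = 639, CD_L2 = 188,
                                             CD_L3 = 420, CD_L1 = 275),
                             group_positions = c(HC = 0, UC = 0, CD_L2 = 0.35,
                                                 CD_L3 = 0.8, CD_L1 = 1.0),
                             n_proteins = 86,
                             n_signal = 20,
                             effect_scale = 0.8,
                             ibd_shift = 0.5,
                             n_ibd_proteins = 30,
                             n_batches = 4,
                             batch_sd = 0.3,
                             residual_sd = 1.0,
                             lod_quantile = 0.02,
                             qc_fail_rate = 0.02,
                             covariate_effects = c(age = 0.005, sex = 0.1,
                                                   duration = 0.01),
                             mu_mean = 3, mu_sd = 1.5,
                             seed = 1L) {
  cfg <- list(group_sizes = group_sizes, group_positions = group_positions,
              n_proteins = as.integer(n_proteins),
              n_signal = as.integer(n_signal),
              effect_scale = effect_scale, ibd_shift = ibd_shift,
              n_ibd_proteins = as.integer(n_ibd_proteins),
              n_batches = as.integer(n_batches), batch_sd = batch_sd,
              residual_sd = residual_sd, lod_quantile = lod_quantile,
              qc_fail_rate = qc_fail_rate,
              covariate_effects = covariate_effects,
              mu_mean = mu_mean, mu_sd = mu_sd, seed = as.integer(seed))
  stopifnot(all(cfg$group_sizes > 0), cfg$n_proteins > 0, cfg$n_signal >= 0,
            cfg$n_signal <= cfg$n_proteins, cfg$n_batches > 0,
            cfg$residual_sd > 0,
            cfg$lod_quantile >= 0, cfg$lod_quantile < 1,
            cfg$qc_fail_rate >= 0, cfg$qc_fail_rate < 1)
  missing_pos <- setdiff(names(cfg$group_sizes), names(cfg$group_positions))
  if (length(missing_pos)) {
    stop("group_positions missing group(s): ",
         paste(missing_pos, collapse = ", "))
  }
  if (any(cfg$group_positions < 0 | cfg$group_positions > 1)) {
    stop("group_positions must lie in [0, 1]")
  }
  if (!all(c("age", "sex", "duration") %in% names(cfg$covariate_effects))) {
    stop("covariate_effects needs elements age, sex, duration")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic NPX cohort with ground truth
#'
#' Draws a cohort from the generative model
#' \deqn{NPX_{ij} = \mu_j + w_j \theta_{g(i)} + IBD_i \delta_j +
#'   b_{batch(i),j} + \beta_{age} age_i + \beta_{sex} sex_i +
#'   \beta_{dur} dur_i + \epsilon_{ij}}
#' with Gaussian residuals. Values falling below the per-protein LOD (placed
#' at `lod_quantile` of each protein's realized values) are kept numerically
#' and flagged in the below-LOD mask — censoring decisions stay reversible.
#'
#' Covariates: age ~ Uniform(18, 80); sex ~ Bernoulli(1/2); disease duration
#' ~ Exponential(mean 8y) truncated at 40y for IBD, 0 for HC. Cohort labels
#' split samples into two historical cohorts plus an inception cohort
#' (`"SIC"`) whose members are mostly treatment-naive.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `dataset` ([npx_dataset()]), `meta` (metadata
#'   data.frame) and `truth` (signal proteins, effects, group positions,
#'   batch shifts, planted QC failures, realized censored fractions).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    groups <- rep(names(cfg$group_sizes), times = cfg$group_sizes)
    n <- length(groups)
    p <- cfg$n_proteins
    proteins <- sprintf("PROT_%02d", seq_len(p))
    ids <- sprintf("S%04d", seq_len(n))

    mu <- rnorm(p, cfg$mu_mean, cfg$mu_sd)
    w <- numeric(p)
    sig_idx <- seq_len(cfg$n_signal)
    if (cfg$n_signal > 0) {
      signs <- rep(c(1, -1), length.out = cfg$n_signal)
      w[sig_idx] <- signs * cfg$effect_scale
    }
    delta <- numeric(p)
    ibd_idx <- integer(0)
    if (cfg$n_ibd_proteins > 0) {
      ibd_idx <- p - seq_len(min(cfg$n_ibd_proteins, p)) + 1L
      dsign <- rep(c(rep(1, 9), -1), length.out = length(ibd_idx))
      delta[ibd_idx] <- dsign * cfg$ibd_shift
    }
    theta <- cfg$group_positions[groups]
    theta[groups == "HC"] <- 0
    is_ibd <- as.numeric(groups != "HC")

    batch <- sprintf("B%02d", sample.int(cfg$n_batches, n, replace = TRUE))
    batch_levels <- sprintf("B%02d", seq_len(cfg$n_batches))
    bshift <- matrix(rnorm(cfg$n_batches * p, 0, cfg$batch_sd),
                     cfg$n_batches, p,
                     dimnames = list(batch_levels, proteins))

    age <- runif(n, 18, 80)
    sex <- ifelse(runif(n) < 0.5, "M", "F")
    dur <- pmin(rexp(n, 1 / 8), 40)
    dur[groups == "HC"] <- 0
    ce <- cfg$covariate_effects

    vals <- matrix(rnorm(n * p, 0, cfg$residual_sd), n, p,
                   dimnames = list(ids, proteins))
    vals <- vals +
      matrix(mu, n, p, byrow = TRUE) +
      outer(theta, w) +
      outer(is_ibd, delta) +
      bshift[batch, , drop = FALSE] +
      (ce[["age"]] * age + ce[["sex"]] * (sex == "M") +
         ce[["duration"]] * dur)

    lod <- apply(vals, 2, quantile, probs = cfg$lod_quantile,
                 names = FALSE, type = 7)
    if (cfg$lod_quantile == 0) lod <- apply(vals, 2, min) - 1
    names(lod) <- proteins

    qc_fail <- runif(n) < cfg$qc_fail_rate

    cohort <- sample(c("COHORT_A", "COHORT_B", "SIC"), n, replace = TRUE,
                     prob = c(0.45, 0.35, 0.2))
    cohort[groups == "HC"] <- sample(c("COHORT_A", "COHORT_B"),
                                     sum(groups == "HC"), replace = TRUE)
    treatment_naive <- (cohort == "SIC" & runif(n) < 0.9) |
      (cohort != "SIC" & runif(n) < 0.05)
    treatment_naive[groups == "HC"] <- FALSE
    surgery <- runif(n) < ifelse(startsWith(groups, "CD"), 0.2,
                                 ifelse(groups == "HC", 0, 0.08))

    diagnosis <- ifelse(groups == "HC", "HC",
                        ifelse(groups == "UC", "UC",
                               ifelse(groups == "IBDU", "IBD-U", "CD")))
    location <- rep(NA_character_, n)
    location[groups == "CD_L1"] <- "L1"
    location[groups == "CD_L2"] <- "L2"
    location[groups == "CD_L3"] <- "L3"
    behavior <- rep(NA_character_, n)
    behavior[diagnosis == "CD"] <-
      sample(c("B1", "B2", "B3"), sum(diagnosis == "CD"),
             replace = TRUE, prob = c(0.6, 0.25, 0.15))
    extent <- rep(NA_character_, n)
    extent[diagnosis == "UC"] <-
      sample(c("E1", "E2", "E3"), sum(diagnosis == "UC"),
             replace = TRUE, prob = c(0.2, 0.35, 0.45))

    meta <- data.frame(
      SampleID = ids, Diagnosis = diagnosis, Location = location,
      Behavior = behavior, Extent = extent, Age = age, Sex = sex,
      DurationYears = dur, PriorSurgery = surgery,
      TreatmentNaive = treatment_naive, Cohort = cohort,
      stringsAsFactors = FALSE)

    ds <- npx_dataset(vals, lod = lod, batch = batch, qc_pass = !qc_fail)
    truth <- list(
      signal_proteins = proteins[sig_idx],
      effects = setNames(w, proteins),
      ibd_effects = setNames(delta, proteins),
      group_positions = cfg$group_positions,
      batch_shifts = bshift,
      qc_fail_ids = ids[qc_fail],
      censored_fraction = colMeans(ds$below_lod),
      mu = setNames(mu, proteins))
    list(dataset = ds, meta = meta, truth = truth)
  })
}

#' Force a fraction of values below the LOD for chosen proteins
#'
#' Fixture builder for the ">90% below LOD" exclusion rule: for each named
#' protein the `ceiling(fraction * n)` lowest values are pushed below that
#' protein's LOD (and flagged); all other proteins are untouched. The
#' operation is deterministic.
#'
#' @param ds an [npx_dataset()].
#' @param proteins protein names to censor.
#' @param fraction fraction in (0, 1\] of samples to push below LOD.
#' @return the modified dataset.
#' @export
plant_lod_violations <- function(ds, proteins, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  unknown <- setdiff(proteins, protein_names(ds))
  if (length(unknown)) {
    stop("unknown protein name(s): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(ds$values)
  m <- ceiling(fraction * n)
  lodm <- lod_per_sample(ds$lod, ds$batch, protein_names(ds))
  for (pr in proteins) {
    ord <- order(ds$values[, pr])[seq_len(m)]
    ds$values[ord, pr] <- lodm[ord, pr] - abs(ds$values[ord, pr] - lodm[ord, pr]) - 0.1
    ds$below_lod[ord, pr] <- TRUE
  }
  ds
}

#' Write a synthetic cohort to disk
#'
#' Long NPX CSV + metadata CSV + ground-truth JSON sidecar.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  npx_path <- file.path(dir, "npx_long.csv")
  meta_path <- file.path(dir, "sample_meta.csv")
  truth_path <- file.path(dir, "truth.json")
  write_npx_long(cohort$dataset, npx_path)
  write_sample_meta(cohort$meta, meta_path)
  truth <- cohort$truth
  truth$batch_shifts <- as.data.frame(truth$batch_shifts)
  jsonlite::write_json(truth, truth_path, digits = NA, auto_unbox = TRUE)
  c(npx = npx_path, meta = meta_path, truth = truth_path)
}
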