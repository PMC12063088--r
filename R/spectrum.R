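#' Rank-based AUC (Mann-Whitney concordance with half-credit ties)
#'
#' @param scores numeric ranking scores.
#' @param labels binary 0/1 labels (class 1 = positive).
#' @param groups optional group label per sample; with `subset_groups`,
#'   restricts the computation to those groups (composite names allowed,
#'   see [expand_group()]).
#' @param subset_groups optional character vector of group names.
#' @return the AUC in \[0, 1\].
#' @export
score_auc <- function(scores, labels, groups = NULL, subset_groups = NULL) {
  if (!is.null(subset_groups)) {
    stopifnot(!is.null(groups))
    keep <- groups %in% unlist(lapply(subset_groups, expand_group))
    scores <- scores[keep]; labels <- labels[keep]
  }
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes in the subset")
  r <- rank(scores)  # midranks give ties half credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Build the CD/UC design from a dataset + groups: X (original scale), y
# (CD = 1, UC = 0), plus the projection rows (IBD-U, HC, isolated-L4 CD).
spectrum_design <- function(ds, groups) {
  groups <- groups[sample_ids(ds)]
  cd <- groups %in% c("CD_L1", "CD_L2", "CD_L3")
  uc <- groups %in% "UC"
  train <- cd | uc
  if (!any(cd) || !any(uc)) stop("need both CD and UC samples")
  list(X = ds$values, y = as.numeric(cd), train = which(train),
       project = which(!train & !is.na(groups)), groups = groups)
}

# Mean predicted probability across a list of fitted models (order-invariant).
avg_predict <- function(models, X) {
  preds <- vapply(models, predict, numeric(nrow(X)), newdata = X)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  rowMeans(preds)
}

fit_repeat_models <- function(X, y, spec_template, repeats, inner_k, seed,
                              n_lambda, lambda_min_ratio) {
  lapply(seq_len(repeats), function(r) {
    sel <- cv_select_lambda(standardize_columns(X)$x, y, spec_template,
                            k = inner_k, seed = derive_seed(seed, r),
                            n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
    spec <- spec_template; spec$lambda <- sel$lambda
    scad_ridge(X, y, spec)
  })
}

#' Nested cross-validated CD-vs-UC probability scores
#'
#' The continuum machinery: every CD/UC sample receives an out-of-sample
#' predicted probability of CD, averaged over `repeats` models whose only
#' difference is a fresh inner 5-fold lambda selection (the source of
#' model-to-model variability). The outer loop is leave-one-out by definition
#' of the original analysis; k-fold (`outer = 10`) gives the same estimand at
#' desk scale. IBD-U and HC samples are scored by projection: the same
#' repeated models refitted on all CD/UC data.
#'
#' @param ds an [npx_dataset()].
#' @param groups named group vector from [assign_groups()].
#' @param outer `"loo"` or an integer number of outer folds.
#' @param inner_k inner CV folds for lambda (default 5).
#' @param repeats models averaged per sample (default 10).
#' @param spec_template a [penalty_spec()] (lambda ignored).
#' @param seed master seed; all repeat/fold seeds derive from it.
#' @param n_lambda,lambda_min_ratio lambda grid controls.
#' @param project score non-CD/UC samples with full-data repeated models.
#' @return data.frame: sample_id, group, score, n_repeats, in_training.
#' @export
nested_cv_scores <- function(ds, groups, outer = "loo", inner_k = 5L,
                             repeats = 10L, spec_template = penalty_spec(),
                             seed = 1L, n_lambda = 30L,
                             lambda_min_ratio = 0.05, project = TRUE) {
  des <- spectrum_design(ds, groups)
  Xt <- des$X[des$train, , drop = FALSE]
  yt <- des$y[des$train]
  n <- length(yt)
  folds <- if (identical(outer, "loo")) {
    seq_len(n)
  } else {
    with_seed(derive_seed(seed, 0L), stratified_folds(yt, as.integer(outer)))
  }
  scores <- rep(0, n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(yt[tr])) < 2) stop("a class is absent from an outer fold")
    models <- fit_repeat_models(Xt[tr, , drop = FALSE], yt[tr], spec_template,
                                repeats, inner_k, derive_seed(seed, 1000L + f),
                                n_lambda, lambda_min_ratio)
    scores[!tr] <- avg_predict(models, Xt[!tr, , drop = FALSE])
  }
  out <- data.frame(sample_id = rownames(Xt),
                    group = des$groups[des$train],
                    score = scores, n_repeats = repeats, in_training = TRUE,
                    stringsAsFactors = FALSE)
  if (project && length(des$project)) {
    full <- fit_repeat_models(Xt, yt, spec_template, repeats, inner_k,
                              derive_seed(seed, 999999L), n_lambda,
                              lambda_min_ratio)
    Xp <- des$X[des$project, , drop = FALSE]
    pp <- avg_predict(full, Xp)
    out <- rbind(out, data.frame(sample_id = rownames(Xp),
                                 group = des$groups[des$project],
                                 score = pp, n_repeats = repeats,
                                 in_training = FALSE,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Per-group score medians and IQRs
#'
#' @param scores data.frame from [nested_cv_scores()] (or any with `score`).
#' @param groups optional group vector overriding `scores$group`.
#' @return data.frame: group, n, median, q1, q3.
#' @export
group_medians <- function(scores, groups = NULL) {
  g <- groups %||% scores$group
  s <- if (is.data.frame(scores)) scores$score else scores
  lev <- unique(g[!is.na(g)])
  if (!length(lev)) stop("no non-missing groups to summarize")
  out <- do.call(rbind, lapply(lev, function(l) {
    x <- s[g %in% l]
    if (!length(x)) stop("empty group: ", l)
    data.frame(group = l, n = length(x), median = median(x),
               q1 = quantile(x, 0.25, names = FALSE),
               q3 = quantile(x, 0.75, names = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey's HSD post hoc comparisons
#'
#' From-scratch one-way ANOVA on group means followed by Tukey's Honestly
#' Significant Difference test with Tukey-Kramer standard errors for unequal
#' group sizes; adjusted p-values and simultaneous confidence intervals come
#' from the studentized range distribution.
#'
#' @param scores numeric vector (or data.frame with a `score` column).
#' @param groups group label per observation.
#' @param alpha simultaneous confidence level is `1 - alpha`.
#' @param exclude groups dropped before testing (default `"HC"`, which is
#'   projected onto the score scale but not part of the disease-spectrum
#'   comparison).
#' @return list with `anova` (F, df1, df2, p) and `tukey` (data.frame: pair,
#'   diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(scores, groups = NULL, alpha = 0.05,
                        exclude = "HC") {
  if (is.data.frame(scores)) {
    groups <- groups %||% scores$group
    scores <- scores$score
  }
  keep <- !is.na(scores) & !is.na(groups) & !(groups %in% exclude)
  x <- scores[keep]; g <- factor(groups[keep])
  lev <- levels(g)
  k <- length(lev)
  if (k < 2) stop("need >= 2 groups")
  ng <- tapply(x, g, length)
  if (any(ng < 2)) stop("each group needs >= 2 observations")
  m <- tapply(x, g, mean)
  N <- length(x)
  ss_between <- sum(ng * (m - mean(x))^2)
  ss_within <- sum((x - m[g])^2)
  df1 <- k - 1; df2 <- N - k
  if (ss_within <= 0) stop("zero within-group variance everywhere")
  mse <- ss_within / df2
  f_stat <- (ss_between / df1) / mse
  p_f <- pf(f_stat, df1, df2, lower.tail = FALSE)
  prs <- combn(lev, 2)
  qcrit <- qtukey(1 - alpha, k, df2)
  tukey <- do.call(rbind, apply(prs, 2, function(pr) {
    d <- m[[pr[2]]] - m[[pr[1]]]
    se <- sqrt(mse / 2 * (1 / ng[[pr[1]]] + 1 / ng[[pr[2]]]))
    data.frame(pair = paste(pr[2], "-", pr[1]), diff = d,
               lwr = d - qcrit * se, upr = d + qcrit * se,
               p_adj = ptukey(abs(d) / se, k, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(tukey) <- NULL
  list(anova = list(F = f_stat, df1 = df1, df2 = df2, p = p_f),
       tukey = tukey)
}

#' Coefficient stability over repeated full-data refits
#'
#' Refits the CD-vs-UC model `n_refits` times on all training data; the only
#' randomness is the inner-CV fold reassignment (hence lambda choice), so the
#' spread of each protein's coefficient across refits measures selection
#' stability. Proteins are ranked by median absolute coefficient
#' (standardized scale): the importance ordering behind the signature.
#'
#' @inheritParams nested_cv_scores
#' @param n_refits number of refits (1000 in the reference analysis).
#' @return data.frame: protein, median_coef, q1, q3, selection_freq, rank
#'   (by median |coef|), sorted by rank.
#' @export
coefficient_stability <- function(ds, groups, spec_template = penalty_spec(),
                                  n_refits = 1000L, inner_k = 5L, seed = 1L,
                                  n_lambda = 30L, lambda_min_ratio = 0.05) {
  des <- spectrum_design(ds, groups)
  Xt <- des$X[des$train, , drop = FALSE]
  yt <- des$y[des$train]
  Xs <- standardize_columns(Xt)$x
  coefs <- matrix(NA_real_, n_refits, ncol(Xt),
                  dimnames = list(NULL, colnames(Xt)))
  for (r in seq_len(n_refits)) {
    sel <- cv_select_lambda(Xs, yt, spec_template, k = inner_k,
                            seed = derive_seed(seed, r),
                            n_lambda = n_lambda,
                            lambda_min_ratio = lambda_min_ratio)
    coefs[r, ] <- sel$path$betas[, sel$index]
  }
  out <- data.frame(
    protein = colnames(Xt),
    median_coef = apply(coefs, 2, median),
    q1 = apply(coefs, 2, quantile, 0.25, names = FALSE),
    q3 = apply(coefs, 2, quantile, 0.75, names = FALSE),
    selection_freq = colMeans(coefs != 0),
    stringsAsFactors = FALSE)
  out$rank <- rank(-abs(out$median_coef), ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  out
}

#' Cohort-holdout robustness scores
#'
#' Trains the repeated CD-vs-UC models without one cohort, then scores the
#' held-out cohort's samples (optionally only treatment-naive ones) — the
#' treatment-effect control of the original analysis.
#'
#' @inheritParams nested_cv_scores
#' @param meta metadata data.frame (for Cohort / TreatmentNaive columns).
#' @param holdout_cohort cohort label to exclude from training.
#' @param treatment_naive_only restrict the scored holdout samples.
#' @return data.frame as in [nested_cv_scores()] (`in_training = FALSE`).
#' @export
cohort_holdout_scores <- function(ds, meta, groups, holdout_cohort,
                                  treatment_naive_only = TRUE,
                                  spec_template = penalty_spec(),
                                  repeats = 10L, inner_k = 5L, seed = 1L,
                                  n_lambda = 30L, lambda_min_ratio = 0.05) {
  meta <- validate_sample_meta(meta)
  meta <- meta[match(sample_ids(ds), meta$SampleID), ]
  if (!holdout_cohort %in% meta$Cohort) {
    stop("cohort label not present: ", holdout_cohort)
  }
  des <- spectrum_design(ds, groups)
  hold <- meta$Cohort == holdout_cohort
  tr_idx <- setdiff(des$train, which(hold))
  if (length(unique(des$y[tr_idx])) < 2) {
    stop("training data lack a class after excluding the holdout cohort")
  }
  score_idx <- which(hold)
  if (treatment_naive_only) score_idx <- score_idx[meta$TreatmentNaive[score_idx]]
  if (!length(score_idx)) stop("no holdout samples left after filtering")
  models <- fit_repeat_models(des$X[tr_idx, , drop = FALSE], des$y[tr_idx],
                              spec_template, repeats, inner_k,
                              derive_seed(seed, 7L), n_lambda,
                              lambda_min_ratio)
  Xh <- des$X[score_idx, , drop = FALSE]
  pp <- avg_predict(models, Xh)
  data.frame(sample_id = rownames(Xh), group = des$groups[score_idx],
             score = pp, n_repeats = repeats, in_training = FALSE,
             stringsAsFactors = FALSE)
}

#' Spectrum summary: medians + ANOVA/Tukey in one object
#'
#' @inheritParams anova_tukey
#' @return list with `medians`, `anova`, `tukey`.
#' @export
spectrum_summary <- function(scores, groups = NULL, alpha = 0.05,
                             exclude = "HC") {
  at <- anova_tukey(scores, groups, alpha = alpha, exclude = exclude)
  g <- groups %||% scores$group
  keep <- !(g %in% exclude)
  med <- group_medians(if (is.data.frame(scores)) scores[keep, ] else
    data.frame(score = scores[keep], group = g[keep]))
  list(medians = med, anova = at$anova, tukey = at$tukey)
}
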