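#' Screening configuration
#'
#' @param fdr_threshold BH-FDR significance boundary (default 0.05).
#' @param fc_threshold absolute fold-change boundary on the linear scale
#'   (default 1.2); applied as `|log2FC| > log2(fc_threshold)`, i.e. ~0.263.
#' @return a `screen_config` list.
#' @export
screen_config <- function(fdr_threshold = 0.05, fc_threshold = 1.2) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, fc_threshold > 1)
  structure(list(fdr_threshold = fdr_threshold, fc_threshold = fc_threshold),
            class = "screen_config")
}

#' Welch two-sample t-test (unequal variances)
#'
#' Direct implementation of the Welch statistic and Satterthwaite degrees of
#' freedom, returning a two-sided p-value.
#'
#' @param x,y numeric vectors (NAs dropped); each needs >= 2 values and
#'   positive variance in at least one group.
#' @param label optional name used in error messages.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y, label = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t needs >= 2 values per group", if (!is.null(label)) paste0(" (", label, ")"))
  }
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  if (vx + vy <= 0) {
    stop("degenerate (zero) variance in both groups",
         if (!is.null(label)) paste0(" for ", label))
  }
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' From-scratch step-up procedure: with ascending p-values p_(1..m),
#' q_(i) = min_{j >= i} p_(j) * m / j, clipped to \[0,1\] and returned in the
#' input order. Missing p-values propagate as `NA` and do not count toward m.
#'
#' @param pvals numeric vector of p-values in \[0,1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(pvals))
  if (m) {
    o <- order(p)
    qs <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    q[ok][o] <- qs
  }
  q
}

#' Pairwise univariate differential screen
#'
#' For every requested group pair and every protein: Welch t-test, log2
#' fold-change as the difference of group means (NPX is already log2, so the
#' mean difference is the log2 fold-change), BH-FDR across proteins within
#' each pair, and a significance flag requiring both `q < fdr_threshold` and
#' `|log2fc| > log2(fc_threshold)`.
#'
#' @param ds an [npx_dataset()].
#' @param groups named group vector from [assign_groups()] (names = sample id).
#' @param pairs list of length-2 character vectors `c(groupA, groupB)`;
#'   composite names (see [expand_group()]) allowed.
#' @param cfg a [screen_config()].
#' @return data.frame with one row per protein x pair: protein, contrast,
#'   log2fc, t, df, p, q, significant.
#' @export
pairwise_screen <- function(ds, groups, pairs, cfg = screen_config()) {
  groups <- groups[sample_ids(ds)]
  res <- list()
  for (pair in pairs) {
    ia <- group_index(groups, pair[1])
    ib <- group_index(groups, pair[2])
    if (length(ia) < 2 || length(ib) < 2) {
      stop("group with <2 samples in contrast ", pair[1], " vs ", pair[2])
    }
    pr <- protein_names(ds)
    rows <- lapply(pr, function(j) {
      wt <- welch_t(ds$values[ia, j], ds$values[ib, j], label = j)
      data.frame(protein = j,
                 contrast = paste(pair[1], "vs", pair[2]),
                 log2fc = mean(ds$values[ia, j], na.rm = TRUE) -
                   mean(ds$values[ib, j], na.rm = TRUE),
                 t = wt$t, df = wt$df, p = wt$p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- bh_fdr(tab$p)
    tab$significant <- tab$q < cfg$fdr_threshold &
      abs(tab$log2fc) > log2(cfg$fc_threshold)
    res[[paste(pair, collapse = "_vs_")]] <- tab
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted differential screen
#'
#' Robustness companion to [pairwise_screen()]: per protein, a linear model
#' `NPX ~ group + age + sex + duration` on the two groups of each pair; the
#' group coefficient is the adjusted log2 fold-change. Samples with prior
#' IBD-related surgery are excluded by default. BH across proteins per pair.
#'
#' @param ds an [npx_dataset()].
#' @param meta metadata data.frame.
#' @param groups named group vector.
#' @param pairs list of group pairs as in [pairwise_screen()].
#' @param cfg a [screen_config()].
#' @param covariates subset of `c("age", "sex", "duration")`.
#' @param exclude_prior_surgery drop `PriorSurgery == TRUE` samples first.
#' @return data.frame: protein, contrast, log2fc (adjusted), se, t, p, q,
#'   significant, n (samples in the model).
#' @export
adjusted_screen <- function(ds, meta, groups, pairs, cfg = screen_config(),
                            covariates = c("age", "sex", "duration"),
                            exclude_prior_surgery = TRUE) {
  meta <- validate_sample_meta(meta)
  meta <- meta[match(sample_ids(ds), meta$SampleID), ]
  groups <- groups[sample_ids(ds)]
  covmap <- c(age = "Age", sex = "Sex", duration = "DurationYears")
  covariates <- match.arg(covariates, several.ok = TRUE)
  res <- list()
  for (pair in pairs) {
    ia <- group_index(groups, pair[1]); ib <- group_index(groups, pair[2])
    idx <- c(ia, ib)
    if (exclude_prior_surgery) idx <- idx[!meta$PriorSurgery[idx]]
    sub <- meta[idx, ]
    gvec <- as.numeric(idx %in% ia)
    Xcov <- cbind(group = gvec)
    if ("age" %in% covariates) Xcov <- cbind(Xcov, age = sub$Age)
    if ("sex" %in% covariates) Xcov <- cbind(Xcov, sex = as.numeric(sub$Sex == "M"))
    if ("duration" %in% covariates) Xcov <- cbind(Xcov, duration = sub$DurationYears)
    if (anyNA(Xcov)) stop("missing covariate values in adjusted screen")
    const <- apply(Xcov, 2, function(z) var(z) == 0)
    if (any(const)) {
      stop("rank-deficient design: constant covariate(s) ",
           paste(colnames(Xcov)[const], collapse = ", "))
    }
    X <- cbind(`(Intercept)` = 1, Xcov)
    Y <- ds$values[idx, , drop = FALSE]
    fit <- lm.fit(X, Y)
    rdf <- nrow(X) - ncol(X)
    rss <- colSums(fit$residuals^2)
    xtxi <- chol2inv(chol(crossprod(X)))
    gi <- match("group", colnames(X))
    se_g <- sqrt(xtxi[gi, gi] * rss / rdf)
    est <- fit$coefficients["group", ]
    tstat <- est / se_g
    pv <- 2 * pt(-abs(tstat), rdf)
    tab <- data.frame(protein = protein_names(ds),
                      contrast = paste(pair[1], "vs", pair[2]),
                      log2fc = unname(est), se = unname(se_g),
                      t = unname(tstat), p = unname(pv), n = nrow(X),
                      stringsAsFactors = FALSE)
    tab$q <- bh_fdr(tab$p)
    tab$significant <- tab$q < cfg$fdr_threshold &
      abs(tab$log2fc) > log2(cfg$fc_threshold)
    res[[paste(pair, collapse = "_vs_")]] <- tab
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' PCA overview of the protein matrix
#'
#' Column-centered (optionally z-scaled) principal component analysis with a
#' deterministic sign convention: each component is flipped so that its
#' largest-magnitude loading is positive. Missing values are mean-imputed
#' with a warning before decomposition.
#'
#' @param ds an [npx_dataset()].
#' @param scale. z-scale columns before the decomposition (default `FALSE`).
#' @param n_components components to keep (default all).
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained_variance` (fractions).
#' @export
pca_overview <- function(ds, scale. = FALSE, n_components = NULL) {
  X <- ds$values
  if (nrow(X) < 3) stop("PCA needs at least 3 samples")
  if (ncol(X) < 2) stop("PCA needs at least 2 proteins")
  if (anyNA(X)) {
    warning("missing NPX values mean-imputed for PCA")
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j]); X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  k <- min(n_components %||% ncol(pc$x), ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Rank-based group test on a principal component
#'
#' Kruskal-Wallis test across groups on one component's scores, followed by
#' Dunn's post hoc pairwise z-tests (with tie correction) and BH adjustment
#' of the pairwise p-values.
#'
#' @param scores PCA score matrix (or vector of one component's scores).
#' @param groups group label per sample.
#' @param component column to test when `scores` is a matrix (default 1).
#' @return list with `kw_stat`, `kw_p`, and `dunn` (data.frame: pair, z, p,
#'   p_adj).
#' @export
component_group_test <- function(scores, groups, component = 1) {
  x <- if (is.matrix(scores)) scores[, component] else scores
  groups <- as.character(groups)
  keep <- !is.na(x) & !is.na(groups)
  x <- x[keep]; groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  kw <- kruskal.test(x, factor(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs_m <- combn(lev, 2)
  z <- apply(pairs_m, 2, function(pr) {
    sd_ij <- sqrt((N * (N + 1) / 12 - tie_term) *
                    (1 / ng[[pr[1]]] + 1 / ng[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / sd_ij
  })
  p <- 2 * pnorm(-abs(z))
  dunn <- data.frame(pair = apply(pairs_m, 2, paste, collapse = " vs "),
                     z = z, p = p, p_adj = bh_fdr(p),
                     stringsAsFactors = FALSE)
  list(kw_stat = unname(kw$statistic), kw_p = kw$p.value, dunn = dunn)
}

#' Write a differential screen result table as TSV
#'
#' @param tab result of [pairwise_screen()] or [adjusted_screen()].
#' @param path output path.
#' @export
write_screen_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
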