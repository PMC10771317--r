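#' Configuration for nested cross-validated elastic net
#'
#' @param outer_repeats Number of random outer train/test splits (default
#'   300).
#' @param outer_test_fraction Held-out fraction per split (default 0.25, the
#'   complement of a 75% train set).
#' @param inner_folds Folds of the inner CV on the train split (default 10).
#' @param alpha_grid Elastic-net mixing values searched (default the 11-point
#'   grid 0, 0.1, ..., 1).
#' @param lambda_rule `"one_se"` (most parsimonious model within one standard
#'   error of the best inner-CV error) or `"min"`.
#' @param seed Integer seed; split `r` uses `seed + r` so two feature sets
#'   run with the same config share outer splits exactly.
#' @return A list of class `nested_cv_config`.
#' @export
nested_cv_config <- function(outer_repeats = 300L, outer_test_fraction = 0.25,
                             inner_folds = 10L,
                             alpha_grid = seq(0, 1, by = 0.1),
                             lambda_rule = c("one_se", "min"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(outer_test_fraction > 0, outer_test_fraction < 1,
            all(alpha_grid >= 0 & alpha_grid <= 1), outer_repeats >= 1L,
            inner_folds >= 3L)
  structure(list(outer_repeats = as.integer(outer_repeats),
                 outer_test_fraction = outer_test_fraction,
                 inner_folds = as.integer(inner_folds),
                 alpha_grid = alpha_grid, lambda_rule = lambda_rule,
                 seed = as.integer(seed)),
            class = "nested_cv_config")
}

# Grid search over (alpha, lambda) by shared-fold CV; returns the fitted
# glmnet object plus the chosen point. The one-SE rule is applied globally:
# among all grid points whose CV error is within one SE of the best, the
# sparsest model wins (ties: larger lambda, then smaller alpha).
enet_grid_cv <- function(X, y, alpha_grid, nfolds, lambda_rule, foldid = NULL) {
  n <- nrow(X)
  if (is.null(foldid)) foldid <- sample(rep(seq_len(nfolds), length.out = n))
  fits <- lapply(alpha_grid, function(a)
    glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid, standardize = TRUE))
  tab <- do.call(rbind, lapply(seq_along(alpha_grid), function(i) {
    cv <- fits[[i]]
    data.frame(alpha_idx = i, lambda = cv$lambda, cvm = cv$cvm,
               cvsd = cv$cvsd, nzero = as.integer(cv$nzero))
  }))
  best <- which.min(tab$cvm)
  if (lambda_rule == "min") {
    pick <- best
  } else {
    threshold <- tab$cvm[best] + tab$cvsd[best]
    cand <- tab[tab$cvm <= threshold, , drop = FALSE]
    cand <- cand[order(cand$nzero, -cand$lambda, cand$alpha_idx), , drop = FALSE]
    pick <- as.integer(rownames(cand)[1L])
  }
  list(fit = fits[[tab$alpha_idx[pick]]]$glmnet.fit,
       alpha = alpha_grid[tab$alpha_idx[pick]],
       lambda = tab$lambda[pick], nzero = tab$nzero[pick],
       cvm = tab$cvm[pick], lambda_min_cvm = tab$lambda[best])
}

#' Nested cross-validated RMSE of an elastic-net model
#'
#' Per outer repeat: a random 75/25 train/test split, an inner `inner_folds`
#' cross-validated search over the `(alpha, lambda)` grid on the train split
#' only (features standardized within the train split), model selection by
#' the configured lambda rule, refit prediction on the held-out split, and
#' the root-mean-square error on that split.
#'
#' @param X Feature x sample matrix.
#' @param y Outcome vector, named by or ordered as the samples of `X`.
#' @param cfg A [nested_cv_config()].
#' @return List of class `rmse_distribution`: `rmse` (one value per repeat),
#'   `mean`, `se`, and a per-repeat `chosen` data.frame (alpha, lambda,
#'   model size).
#' @export
nested_cv_rmse <- function(X, y, cfg = nested_cv_config()) {
  stopifnot(is.matrix(X), inherits(cfg, "nested_cv_config"))
  y <- align_outcome(X, y)
  n <- ncol(X)
  if (n < 20L) stop("need >= 20 samples for nested cross-validation")
  Xt <- t(X)
  n_test <- max(1L, round(n * cfg$outer_test_fraction))
  rmse <- numeric(cfg$outer_repeats)
  chosen <- vector("list", cfg$outer_repeats)
  for (r in seq_len(cfg$outer_repeats)) {
    set.seed(cfg$seed + r)
    test_idx <- sample.int(n, n_test)
    X_train <- Xt[-test_idx, , drop = FALSE]
    y_train <- y[-test_idx]
    if (stats::sd(y_train) == 0) {
      pred <- rep(y_train[1L], n_test)
      chosen[[r]] <- data.frame(alpha = NA_real_, lambda = NA_real_, nzero = 0L)
    } else {
      sel <- enet_grid_cv(X_train, y_train, cfg$alpha_grid, cfg$inner_folds,
                          cfg$lambda_rule)
      pred <- as.vector(stats::predict(sel$fit, Xt[test_idx, , drop = FALSE],
                                       s = sel$lambda))
      chosen[[r]] <- data.frame(alpha = sel$alpha, lambda = sel$lambda,
                                nzero = sel$nzero)
    }
    rmse[r] <- sqrt(mean((y[test_idx] - pred)^2))
  }
  structure(list(rmse = rmse, mean = mean(rmse),
                 se = stats::sd(rmse) / sqrt(length(rmse)),
                 chosen = do.call(rbind, chosen)),
            class = "rmse_distribution")
}

#' Compare two feature sets on the same outcome with shared outer splits
#'
#' Runs [nested_cv_rmse()] on both feature matrices with identical outer
#' train/test splits (the per-repeat seed depends only on the config) and
#' reports the percent RMSE decrease of the first set relative to the
#' second: `100 * (mean_b - mean_a) / mean_b`. Positive values mean the
#' first (e.g. numTS) feature set predicts better.
#'
#' @param X_a,X_b Feature x sample matrices over identical samples (e.g.
#'   numTS and miRNA-expression features matched by family).
#' @param y Outcome vector.
#' @param cfg A [nested_cv_config()].
#' @return List with both `rmse_distribution`s, `percent_decrease`, and the
#'   per-repeat paired RMSE differences.
#' @export
compare_feature_sets <- function(X_a, X_b, y, cfg = nested_cv_config()) {
  if (!identical(colnames(X_a), colnames(X_b)))
    stop("feature matrices must cover identical samples in identical order")
  res_a <- nested_cv_rmse(X_a, y, cfg)
  res_b <- nested_cv_rmse(X_b, y, cfg)
  list(rmse_a = res_a, rmse_b = res_b,
       percent_decrease = 100 * (res_b$mean - res_a$mean) / res_b$mean,
       paired_diff = res_b$rmse - res_a$rmse)
}

#' Bootstrap stability selection with the elastic net
#'
#' Draws `B` bootstrap resamples of the samples, fits an elastic net on each
#' (lambda by `nfolds`-fold cross-validation at a fixed mixing `alpha`),
#' records the support (features with nonzero coefficients), and reports the
#' per-feature selection frequency over the `B` resamples. The predictive
#' set is derived from the frequencies by one of two rules:
#' * `list(top_fraction = 0.5)` — rank candidate features (selected at least
#'   once) by frequency and keep the top fraction, including all features
#'   tied at the cutoff frequency;
#' * `list(min_frequency = 0.7)` — keep features selected in at least that
#'   fraction of resamples.
#'
#' Bootstrap replicates with a constant outcome are skipped (and counted);
#' more than 10% skipped is an error.
#'
#' @param X Feature x sample matrix.
#' @param y Outcome vector.
#' @param B Number of bootstrap resamples (default 200).
#' @param rule Frequency rule, see above.
#' @param alpha Elastic-net mixing parameter for the per-resample fits
#'   (default 0.5).
#' @param nfolds Inner CV folds (default 10).
#' @param lambda_rule `"one_se"` or `"min"` for the per-resample lambda.
#' @param thresh Coordinate-descent convergence threshold for the
#'   per-resample fits (default 1e-5; selection frequencies are only
#'   resolved to 1/B, so the tighter glmnet default buys nothing here).
#' @param seed Integer seed.
#' @return List of class `stability_selection`: `frequency` (named, in
#'   `[0, 1]`), `predictive_set`, `B`, `n_skipped`, `rule`.
#' @export
bootstrap_stability_selection <- function(X, y, B = 200L,
                                          rule = list(top_fraction = 0.5),
                                          alpha = 0.5, nfolds = 10L,
                                          lambda_rule = c("one_se", "min"),
                                          thresh = 1e-5, seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.matrix(X))
  y <- align_outcome(X, y)
  n <- ncol(X)
  if (n < 20L) stop("need >= 20 samples for stability selection")
  Xt <- t(X)
  counts <- stats::setNames(numeric(nrow(X)), rownames(X))
  n_skipped <- 0L
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (stats::sd(yb) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    # fold hygiene on resampled data: all bootstrap copies of an original
    # sample share a CV fold, otherwise duplicates leak across folds and
    # the CV-chosen lambda is anti-conservative (stable false positives
    # under a pure-noise outcome)
    fold_of_sample <- sample(rep(seq_len(nfolds), length.out = n))
    cv <- glmnet::cv.glmnet(Xt[idx, , drop = FALSE], yb, alpha = alpha,
                            foldid = fold_of_sample[idx], standardize = TRUE,
                            thresh = thresh)
    s <- if (lambda_rule == "one_se") cv$lambda.1se else cv$lambda.min
    beta <- stats::coef(cv, s = s)[-1L, 1L]
    counts[beta != 0] <- counts[beta != 0] + 1
  }
  if (n_skipped > 0L)
    message(n_skipped, " degenerate bootstrap replicate(s) skipped")
  if (n_skipped > 0.1 * B)
    stop("more than 10% of bootstrap replicates were degenerate")
  frequency <- counts / B
  predictive_set <- apply_frequency_rule(frequency, rule)
  structure(list(frequency = frequency, predictive_set = predictive_set,
                 B = as.integer(B), n_skipped = n_skipped, rule = rule),
            class = "stability_selection")
}

apply_frequency_rule <- function(frequency, rule) {
  if (!is.null(rule$top_fraction)) {
    cand <- frequency[frequency > 0]
    if (length(cand) == 0L) return(character(0))
    k <- ceiling(length(cand) * rule$top_fraction)
    cutoff <- sort(cand, decreasing = TRUE)[k]
    names(cand)[cand >= cutoff]
  } else if (!is.null(rule$min_frequency)) {
    names(frequency)[frequency >= rule$min_frequency]
  } else {
    stop("rule must specify top_fraction or min_frequency")
  }
}

#' Hypergeometric test for the overlap of two feature sets
#'
#' Upper-tail probability that two subsets of a common universe share at
#' least the observed number of features: with `N = |universe|`,
#' `K = |set_a|` successes and `n = |set_b|` draws,
#' `p = P(X >= k)` for `k = |intersection|` under the hypergeometric law.
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all features eligible for selection.
#' @return List with `p`, `overlap` (k), and `expected` overlap under the
#'   null.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("set_a and set_b must be subsets of the universe")
  N <- length(unique(universe))
  K <- length(unique(set_a))
  n_draw <- length(unique(set_b))
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
  list(p = p, overlap = k, expected = K * n_draw / N)
}

align_outcome <- function(X, y) {
  if (!is.null(names(y)) && !is.null(colnames(X))) {
    if (!all(colnames(X) %in% names(y)))
      stop("outcome vector does not cover all samples of X")
    y <- y[colnames(X)]
  } else if (length(y) != ncol(X)) {
    stop("outcome length does not match the number of samples")
  }
  if (any(!is.finite(y))) stop("outcome must be finite")
  y
}
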