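#' Log-transform, center, and scale a feature matrix by rows
#'
#' The preprocessing used before clustering/PCA of heterogeneous molecular
#' features: per entry `log2(x + 1)`, then per-feature (row) mean-centering
#' and unit-variance scaling. Rows that are constant after the log transform
#' carry no information and are dropped with a warning.
#'
#' @param m Non-negative feature x sample matrix.
#' @param log2_transform Apply the `log2(x + 1)` step (set `FALSE` for
#'   features already on a bounded/log scale, e.g. PDUI).
#' @return Preprocessed matrix; every row has mean 0 and sd 1.
#' @export
preprocess_lcs <- function(m, log2_transform = TRUE) {
  stopifnot(is.matrix(m))
  if (log2_transform) {
    if (any(m < 0)) stop("log2(x+1) preprocessing requires non-negative values")
    m <- log2(m + 1)
  }
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant feature row(s)")
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (m - rowMeans(m)) / sds
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns on Euclidean distance,
#' cut into `k` clusters. Deterministic given the input column order.
#'
#' @param m Preprocessed feature x sample matrix.
#' @param k Number of clusters.
#' @param method Linkage: `"complete"` (default), `"average"`, or `"ward.D2"`.
#' @return List with `clusters` (named integer vector over samples) and
#'   `tree` (the `hclust` object).
#' @export
hierarchical_cluster <- function(m, k, method = c("complete", "average", "ward.D2")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m))
  if (k > ncol(m)) stop("k exceeds the number of samples")
  tree <- stats::hclust(stats::dist(t(m)), method = method)
  list(clusters = stats::cutree(tree, k = k), tree = tree)
}

#' PCA projection of samples
#'
#' Projects samples onto the top principal components of the feature
#' covariance (features centered; no rescaling beyond what preprocessing
#' already applied).
#'
#' @param m Feature x sample matrix.
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (samples x components), `explained` (fractions
#'   of total variance, non-increasing), and `rotation`.
#' @export
pca_project <- function(m, n_components = 2L) {
  stopifnot(is.matrix(m))
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds matrix rank (", rank, ")")
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = frac[seq_len(n_components)],
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE])
}

#' Percentage of feature variance explained by group (between-group rate)
#'
#' After scaling every feature to unit variance, computes
#' `100 * sum_f SS_between(f) / sum_f SS_total(f)` over features, the
#' one-way-ANOVA decomposition aggregated across all features. With
#' unit-variance features this equals the mean per-feature ratio.
#'
#' @param m Feature x sample matrix.
#' @param groups Per-sample group labels (length `ncol(m)`).
#' @return Percentage in `[0, 100]`.
#' @export
between_group_rate <- function(m, groups) {
  stopifnot(is.matrix(m), length(groups) == ncol(m))
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0L)) stop("a group has 0 samples")
  sds <- apply(m, 1L, stats::sd)
  m <- m[sds > 0, , drop = FALSE] / sds[sds > 0]
  grand <- rowMeans(m)
  centered <- m - grand
  ss_total <- sum(centered^2)
  group_means <- t(rowsum(t(centered), groups) / as.vector(table(groups)))
  n_g <- as.vector(table(groups))
  ss_between <- sum(sweep(group_means^2, 2L, n_g, `*`))
  100 * ss_between / ss_total
}

#' Pairwise Mahalanobis distances between groups
#'
#' For every pair of groups, the Mahalanobis distance between the group
#' centroids under the pooled within-group covariance of that pair:
#' `sqrt((mu1 - mu2)' S^-1 (mu1 - mu2))`.
#'
#' @param scores Samples x dimensions score matrix (e.g. PCA scores).
#' @param groups Per-sample group labels.
#' @return A `group x group` symmetric distance matrix with zero diagonal.
#' @export
mahalanobis_group_distance <- function(scores, groups) {
  stopifnot(is.matrix(scores), length(groups) == nrow(scores))
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  d <- ncol(scores)
  sizes <- table(groups)
  if (any(sizes <= d))
    stop("every group needs more samples than score dimensions")
  out <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)) for (j in seq_len(i - 1L)) {
    xi <- scores[groups == lev[i], , drop = FALSE]
    xj <- scores[groups == lev[j], , drop = FALSE]
    pooled <- ((nrow(xi) - 1) * stats::cov(xi) + (nrow(xj) - 1) * stats::cov(xj)) /
      (nrow(xi) + nrow(xj) - 2)
    delta <- colMeans(xi) - colMeans(xj)
    q <- tryCatch(drop(crossprod(delta, solve(pooled, delta))),
                  error = function(e)
                    stop("singular pooled covariance for pair (", lev[i],
                         ", ", lev[j], ")"))
    out[i, j] <- out[j, i] <- sqrt(q)
  }
  out
}
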