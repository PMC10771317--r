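#' Per-family correlation between numTS and miRNA expression
#'
#' For each miRNA family present in both matrices, computes the Spearman
#' correlation across samples between its numTS and its expression, the
#' squared coefficient, a two-sided p-value (exact permutation distribution
#' for n <= 10, t approximation above), and Benjamini-Hochberg adjusted
#' q-values over the non-degenerate families. Families with a constant
#' vector in either matrix get `NA` and are excluded from the BH adjustment.
#'
#' @param numts Family x sample numTS matrix.
#' @param expr Family x sample miRNA TPM matrix, sample-aligned with `numts`.
#' @param family_map Optional named character vector mapping miRNA IDs
#'   (rownames of `expr`) to family IDs (rownames of `numts`); rows of `expr`
#'   sharing a family are averaged before correlating.
#' @return A data.frame of class `correlation_profile`: `mirna_family, rho,
#'   rho_sq, p, q, n`.
#' @export
correlation_profile <- function(numts, expr, family_map = NULL) {
  stopifnot(is.matrix(numts), is.matrix(expr))
  if (!identical(colnames(numts), colnames(expr)))
    stop("numts and expr are not sample-aligned; run align_samples()")
  if (ncol(numts) < 3L) stop("need >= 3 common samples for correlation")
  if (!is.null(family_map)) {
    if (anyDuplicated(names(family_map)))
      stop("family_map must assign each miRNA to exactly one family")
    fam <- family_map[rownames(expr)]
    keep <- !is.na(fam)
    expr <- rowsum(expr[keep, , drop = FALSE], fam[keep]) /
      as.vector(table(fam[keep])[sort(unique(fam[keep]))])
  }
  families <- intersect(rownames(numts), rownames(expr))
  dropped <- setdiff(union(rownames(numts), rownames(expr)), families)
  if (length(dropped) > 0L)
    warning(length(dropped), " families present in only one matrix were dropped")
  if (length(families) == 0L) stop("no families shared between numts and expr")
  n <- ncol(numts)
  res <- lapply(families, function(f) {
    x <- numts[f, ]
    y <- expr[f, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = n <= 10))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  rho <- vapply(res, `[[`, 0, "rho")
  p <- vapply(res, `[[`, 0, "p")
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  out <- data.frame(mirna_family = families, rho = rho, rho_sq = rho^2,
                    p = p, q = q, n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Test for disruption of the numTS-expression coupling
#'
#' Compares the distributions of squared Spearman correlations between two
#' correlation profiles (typically normal vs. tumor samples of the same
#' patients) with a two-sided Wilcoxon test on the rho-squared values:
#' rank-sum (unpaired) by default, signed-rank on per-family differences
#' with `paired = TRUE`.
#'
#' @param profile_a,profile_b `correlation_profile` objects over the same
#'   family universe (e.g. normal and tumor).
#' @param paired Use the paired signed-rank variant (families matched by ID).
#' @return List with `statistic`, `p`, `direction` (which profile has the
#'   larger median rho-squared), and the two medians.
#' @export
disruption_test <- function(profile_a, profile_b, paired = FALSE) {
  a <- profile_a$rho_sq[!is.na(profile_a$rho_sq)]
  b <- profile_b$rho_sq[!is.na(profile_b$rho_sq)]
  if (paired) {
    shared <- intersect(profile_a$mirna_family[!is.na(profile_a$rho_sq)],
                        profile_b$mirna_family[!is.na(profile_b$rho_sq)])
    if (length(shared) < 2L) stop("need >= 2 shared non-missing families")
    a <- profile_a$rho_sq[match(shared, profile_a$mirna_family)]
    b <- profile_b$rho_sq[match(shared, profile_b$mirna_family)]
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  } else {
    if (length(a) < 2L || length(b) < 2L)
      stop("need >= 2 non-missing rho_sq values per group")
    wt <- suppressWarnings(stats::wilcox.test(a, b))
  }
  med_a <- stats::median(a)
  med_b <- stats::median(b)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       direction = if (med_a > med_b) "a > b" else if (med_a < med_b) "a < b" else "a = b",
       median_a = med_a, median_b = med_b)
}

#' Families with BH-significant numTS-expression correlation
#'
#' Applies Benjamini-Hochberg over the non-missing raw p-values of a
#' correlation profile and returns the families whose adjusted p-value falls
#' below the cutoff, together with the complementary fraction of
#' non-significant families.
#'
#' @param profile A `correlation_profile`.
#' @param q_cutoff BH-adjusted significance cutoff (default 0.05).
#' @return List with `significant` (character vector of family IDs),
#'   `fraction_nonsignificant` (percentage, over families with a defined
#'   p-value), and `n_tested`.
#' @export
significant_correlated_set <- function(profile, q_cutoff = 0.05) {
  tested <- profile[!is.na(profile$p), , drop = FALSE]
  q <- stats::p.adjust(tested$p, method = "BH")
  sig <- tested$mirna_family[q < q_cutoff]
  list(significant = sig,
       fraction_nonsignificant = 100 * (1 - length(sig) / max(nrow(tested), 1L)),
       n_tested = nrow(tested))
}
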