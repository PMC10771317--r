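#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper over [survival::coxph()] (Efron tie handling) that validates
#' inputs and returns the quantities the downstream model comparison needs:
#' coefficients, the log partial likelihood at the fit, and the fitted
#' object for prediction.
#'
#' @param covariates Data.frame of covariates (one row per subject; all
#'   columns entered untransformed).
#' @param time Follow-up durations (>= 0).
#' @param event Event indicators in \{0, 1\}.
#' @return List of class `cox_fit`: `coefficients`, `loglik` (at the fitted
#'   coefficients), `loglik_null`, `n`, `events`, `covariate_names`, `fit`.
#' @export
fit_cox <- function(covariates, time, event) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(time), length(time) == length(event))
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1) stop("need at least one event")
  if (anyNA(covariates)) stop("missing covariate values")
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    if (ncol(covariates) > 0L)
      paste(sprintf("`%s`", colnames(covariates)), collapse = " + ")
    else "1"))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (ncol(covariates) > 0L && anyNA(stats::coef(fit)))
    stop("Cox model failed to converge (NA coefficients); check for ",
         "collinear or degenerate covariates")
  ll <- if (ncol(covariates) > 0L) fit$loglik[2L] else fit$loglik[1L]
  structure(list(coefficients = stats::coef(fit), loglik = ll,
                 loglik_null = fit$loglik[1L], n = fit$n,
                 events = fit$nevent,
                 covariate_names = colnames(covariates), fit = fit,
                 data = df),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model:", length(x$coefficients), "covariates,", x$n, "subjects,",
      x$events, "events; log partial likelihood", format(x$loglik), "\n")
  invisible(x)
}

#' LASSO-Cox selection of numTS-change features with unpenalized clinical
#' covariates
#'
#' Fits a penalized Cox model on clinical covariates plus per-patient numTS
#' changes, with the penalty applied only to the numTS-change columns (the
#' clinical covariates are never shrunk and are always retained). Lambda is
#' chosen by `folds`-fold cross-validation; the selected families are the
#' penalized columns with nonzero coefficients at the chosen lambda. The
#' returned model is an unpenalized Cox refit on clinical + selected
#' features, so that likelihood-ratio comparisons against the clinical-only
#' model are well-defined.
#'
#' @param clinical Data.frame of clinical covariates (one row per patient).
#' @param features Family x patient matrix of numTS changes (tumor minus
#'   normal), patients matching `clinical` rows.
#' @param time,event Survival outcome per patient.
#' @param folds CV folds (default 10).
#' @param lambda_rule `"min"` (default) or `"one_se"`.
#' @param seed Integer seed for the CV fold assignment.
#' @return List with `selected_families`, `model` (a `cox_fit` on clinical +
#'   selected features), and `clinical_only` (a `cox_fit`).
#' @export
lasso_cox_select <- function(clinical, features, time, event, folds = 10L,
                             lambda_rule = c("min", "one_se"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  clinical <- as.data.frame(clinical)
  stopifnot(is.matrix(features), ncol(features) == nrow(clinical))
  X <- cbind(as.matrix(clinical), t(features))
  penalty <- c(rep(0, ncol(clinical)), rep(1, nrow(features)))
  set.seed(seed)
  clinical_only <- fit_cox(clinical, time, event)
  cv <- tryCatch(
    glmnet::cv.glmnet(X, survival::Surv(time, event), family = "cox",
                      penalty.factor = penalty, nfolds = folds,
                      standardize = TRUE),
    error = function(e) NULL)
  selected <- character(0)
  if (!is.null(cv)) {
    s <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    beta <- stats::coef(cv, s = s)[, 1L]
    pen_beta <- beta[seq_len(nrow(features)) + ncol(clinical)]
    selected <- rownames(features)[pen_beta != 0]
  }
  if (length(selected) == 0L) {
    model <- clinical_only
  } else {
    covs <- cbind(clinical,
                  as.data.frame(t(features[selected, , drop = FALSE])))
    model <- fit_cox(covs, time, event)
  }
  list(selected_families = selected, model = model,
       clinical_only = clinical_only)
}

#' Augment the clinical-only model with expression changes of selected
#' families
#'
#' Builds the expression counterpart of the numTS-clinical model: an
#' unpenalized Cox fit on the clinical covariates plus the per-patient
#' expression changes of exactly the families that the numTS-based selection
#' chose.
#'
#' @param clinical Data.frame of clinical covariates.
#' @param selected_families Families chosen by [lasso_cox_select()].
#' @param delta_expr Family x patient matrix of expression changes.
#' @param time,event Survival outcome per patient.
#' @return A `cox_fit`.
#' @export
augment_with_expression <- function(clinical, selected_families, delta_expr,
                                    time, event) {
  if (!all(selected_families %in% rownames(delta_expr)))
    stop("missing family in delta_expr: ",
         paste(setdiff(selected_families, rownames(delta_expr)), collapse = ", "))
  covs <- as.data.frame(clinical)
  if (length(selected_families) > 0L)
    covs <- cbind(covs, as.data.frame(
      t(delta_expr[selected_families, , drop = FALSE])))
  fit_cox(covs, time, event)
}

#' Median-split risk stratification with Kaplan-Meier and log-rank test
#'
#' Computes each subject's linear predictor (log relative hazard) under a
#' fitted Cox model, dichotomizes at the median (below or equal: low risk),
#' and compares the two groups' survival with the two-sided log-rank test.
#'
#' @param model A `cox_fit`.
#' @param covariates Data.frame with the model's covariate schema; defaults
#'   to the data the model was fitted on.
#' @param time,event Survival outcome; default to the fitting data.
#' @return List with `risk_group` (factor `high`/`low`), `logrank_p`,
#'   `logrank_chisq`, and `km` (a [survival::survfit] object by group).
#' @export
risk_stratify <- function(model, covariates = NULL, time = NULL, event = NULL) {
  stopifnot(inherits(model, "cox_fit"))
  if (is.null(covariates)) {
    df <- model$data
  } else {
    covariates <- as.data.frame(covariates)
    if (!all(model$covariate_names %in% colnames(covariates)))
      stop("covariates do not match the model schema")
    df <- cbind(data.frame(.time = time, .event = event), covariates)
  }
  lp <- as.vector(stats::predict(model$fit, newdata = df, type = "lp"))
  if (stats::sd(lp) == 0) stop("constant linear predictor: cannot stratify")
  group <- factor(ifelse(lp > stats::median(lp), "high", "low"),
                  levels = c("low", "high"))
  sd_test <- survival::survdiff(survival::Surv(.time, .event) ~ group,
                                data = cbind(df, group = group))
  p <- stats::pchisq(sd_test$chisq, df = 1L, lower.tail = FALSE)
  km <- survival::survfit(survival::Surv(.time, .event) ~ group,
                          data = cbind(df, group = group))
  list(risk_group = group, logrank_p = p, logrank_chisq = unname(sd_test$chisq),
       km = km)
}

#' Likelihood-ratio test between nested Cox models
#'
#' `statistic = 2 * (loglik_full - loglik_nested)`, degrees of freedom equal
#' to the number of added covariates, chi-square upper-tail p-value. Both
#' models must be unpenalized fits on the same subjects with the nested
#' model's covariates a subset of the full model's.
#'
#' @param nested,full `cox_fit` objects.
#' @return List with `statistic`, `df`, `p`.
#' @export
lrt_compare <- function(nested, full) {
  stopifnot(inherits(nested, "cox_fit"), inherits(full, "cox_fit"))
  if (nested$n != full$n)
    stop("models fitted on different numbers of subjects")
  if (!all(nested$covariate_names %in% full$covariate_names))
    stop("models are not nested")
  df <- length(full$covariate_names) - length(nested$covariate_names)
  statistic <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0L) 1 else stats::pchisq(statistic, df = df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p = p)
}

#' Fit and compare the clinical-only, numTS-clinical, and expr-clinical
#' survival models
#'
#' The full survival workflow: LASSO-Cox selection of numTS-change features
#' with unpenalized clinical covariates, an expression-augmented counterpart
#' on the same selected families, median-split risk groups with log-rank
#' tests for each model, and likelihood-ratio tests of both augmented models
#' against the clinical-only baseline.
#'
#' @param clinical Data.frame of clinical covariates (per patient).
#' @param delta_numts Family x patient numTS-change matrix.
#' @param delta_expr Family x patient expression-change matrix.
#' @param time,event Survival outcome per patient.
#' @param folds,lambda_rule,seed Passed to [lasso_cox_select()].
#' @return List of class `survival_model_set` with the three `cox_fit`s,
#'   `selected_families`, `lrt_numts`, `lrt_expr`, `risk` (per-model
#'   [risk_stratify()] results), and `logrank_p` per model.
#' @export
survival_model_set <- function(clinical, delta_numts, delta_expr, time, event,
                               folds = 10L, lambda_rule = "min", seed = 1L) {
  sel <- lasso_cox_select(clinical, delta_numts, time, event, folds = folds,
                          lambda_rule = lambda_rule, seed = seed)
  expr_model <- augment_with_expression(clinical, sel$selected_families,
                                        delta_expr, time, event)
  models <- list(clinical_only = sel$clinical_only,
                 numts_clinical = sel$model,
                 expr_clinical = expr_model)
  risk <- lapply(models, function(m)
    tryCatch(risk_stratify(m), error = function(e) NULL))
  structure(list(
    clinical_only = models$clinical_only,
    numts_clinical = models$numts_clinical,
    expr_clinical = models$expr_clinical,
    selected_families = sel$selected_families,
    lrt_numts = lrt_compare(sel$clinical_only, sel$model),
    lrt_expr = lrt_compare(sel$clinical_only, expr_model),
    risk = risk,
    logrank_p = vapply(risk, function(r)
      if (is.null(r)) NA_real_ else r$logrank_p, numeric(1L))),
    class = "survival_model_set")
}
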