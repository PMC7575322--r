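#' Fit a linear mixed model with a random animal intercept
#'
#' Fits `response ~ fixed_predictors + (1 | group)` with a random intercept
#' per group (the animal), the structure used throughout the analysis to
#' account for variability across animals. Rows with a missing value in any
#' used column are dropped (listwise deletion) and the count is reported.
#' Fixed-effect significance is assessed with Satterthwaite t/F tests (the
#' ANOVA-on-mixed-model convention); models intended for likelihood-ratio
#' comparison must be fit with `method = "ML"`.
#'
#' @param table data.frame with the response, predictor and grouping
#'   columns.
#' @param response Response column name.
#' @param fixed_predictors Character vector of predictor column names (may
#'   be empty for an intercept-only model).
#' @param group Grouping column for the random intercept (default
#'   `"animal_id"`); `NULL` fits a plain linear model.
#' @param method `"ML"` (default, required for likelihood-ratio tests) or
#'   `"REML"` (for variance-component reporting).
#' @return An object of class `lmm_fit`: the fitted model plus
#'   `coefficients` (estimate, SE, df, t, p), `logLik`, `n_obs`,
#'   `n_groups`, `n_dropped`, `singular`, `method`, and the columns used.
#' @export
fit_lmm <- function(table, response, fixed_predictors = character(),
                    group = "animal_id", method = c("ML", "REML")) {
  method <- match.arg(method)
  used <- c(response, fixed_predictors, group)
  stopifnot(all(used %in% names(table)))
  dat <- table[, used, drop = FALSE]
  keep <- stats::complete.cases(dat)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("fit_lmm: dropped %d row(s) with missing values", n_dropped))
  dat <- dat[keep, , drop = FALSE]
  rhs <- if (length(fixed_predictors)) paste(fixed_predictors, collapse = " + ") else "1"
  n_groups <- if (is.null(group)) 0L else length(unique(dat[[group]]))
  if (is.null(group) || n_groups < 2L) {
    if (!is.null(group) && n_groups < 2L)
      warning("fewer than 2 groups; fitting a plain linear model")
    fit <- stats::lm(stats::as.formula(paste(response, "~", rhs)), data = dat)
    co <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                        df = fit$df.residual, t = co[, 3], p = co[, 4],
                        row.names = NULL)
    singular <- FALSE
  } else {
    f <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", group, ")"))
    # Satterthwaite machinery can fail on degenerate (zero-variance) fits;
    # fall back to the plain lme4 fit with normal-approximation p-values.
    fit <- tryCatch(lmerTest::lmer(f, data = dat, REML = (method == "REML")),
                    error = function(e) lme4::lmer(f, data = dat,
                                                   REML = (method == "REML")))
    co <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
    if (is.null(co)) {  # degenerate fit: report estimates without inference
      est <- lme4::fixef(fit)
      co <- cbind(Estimate = est, `Std. Error` = NA_real_,
                  `t value` = NA_real_)
    }
    if ("Pr(>|t|)" %in% colnames(co)) {
      coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                          se = co[, "Std. Error"], df = co[, "df"],
                          t = co[, "t value"], p = co[, "Pr(>|t|)"],
                          row.names = NULL)
    } else {
      coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                          se = co[, "Std. Error"], df = NA_real_,
                          t = co[, "t value"],
                          p = 2 * stats::pnorm(-abs(co[, "t value"])),
                          row.names = NULL)
    }
    singular <- lme4::isSingular(fit)
  }
  structure(list(model = fit, coefficients = coefs,
                 logLik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(dat), n_groups = n_groups,
                 n_dropped = n_dropped, singular = singular, method = method,
                 response = response, fixed_predictors = fixed_predictors,
                 group = if (n_groups >= 2L) group else NULL,
                 rows_used = which(keep)),
            class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  kind <- if (is.null(x$group)) "linear model" else
    sprintf("linear mixed model (random intercept: %s, %d groups)",
            x$group, x$n_groups)
  cat(sprintf("<lmm_fit> %s ~ %s; %s; %s fit; n = %d; logLik = %.3f%s\n",
              x$response,
              if (length(x$fixed_predictors)) paste(x$fixed_predictors, collapse = " + ") else "1",
              kind, x$method, x$n_obs, x$logLik,
              if (x$singular) " [singular]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Likelihood-ratio test for the animal random effect
#'
#' Compares a mixed model with a random animal intercept against the linear
#' model without it: `stat = 2 * (logLik_with - logLik_without)`, referred
#' to a chi-square with 1 df. Both models must be ML fits of the same fixed
#' structure on the same rows. Testing a variance component on its boundary
#' makes the chi-square(1) reference conservative (the true null
#' distribution is a 50:50 mixture of a point mass at 0 and chi-square(1)),
#' which is accepted and documented rather than corrected.
#'
#' @param model_with A [fit_lmm()] with the random intercept.
#' @param model_without A [fit_lmm()] with `group = NULL`.
#' @return List with `stat` and `p`.
#' @export
lrt_random_effect <- function(model_with, model_without) {
  stopifnot(inherits(model_with, "lmm_fit"), inherits(model_without, "lmm_fit"))
  if (model_with$method != "ML" || model_without$method != "ML")
    stop("likelihood-ratio comparison requires ML fits")
  if (model_with$n_obs != model_without$n_obs ||
      !identical(model_with$rows_used, model_without$rows_used))
    stop("models were fit on different observation sets")
  stat <- 2 * (model_with$logLik - model_without$logLik)
  if (stat < 0 && stat > -1e-6) stat <- 0  # convergence jitter
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Drop-one model comparison: independent contribution of each predictor
#'
#' For each candidate predictor, the full mixed model (all candidates plus
#' the random animal intercept) is compared against the model dropping that
#' predictor, fit by ML on the same rows, with a likelihood-ratio test.
#' A predictor is declared an independent contributor when the comparison
#' is significant: this reproduces the "does X still predict the response
#' once Y is taken into consideration" logic. Satterthwaite t-test p-values
#' of the full model are reported alongside.
#'
#' @param table data.frame.
#' @param response Response column name.
#' @param candidate_predictors Character vector (>= 2 columns).
#' @param group Random-intercept column, default `"animal_id"`.
#' @param condition_warn Condition-number threshold above which a
#'   collinearity warning is issued. Default 1e6.
#' @return data.frame(predictor, estimate, chisq, df, p, p_t) with one row
#'   per candidate; `p` is the drop-one likelihood-ratio p-value.
#' @export
model_comparison <- function(table, response, candidate_predictors,
                             group = "animal_id", condition_warn = 1e6) {
  stopifnot(length(candidate_predictors) >= 2L)
  used <- c(response, candidate_predictors, group)
  dat <- table[stats::complete.cases(table[, used, drop = FALSE]), used, drop = FALSE]
  X <- as.matrix(dat[, candidate_predictors, drop = FALSE])
  kx <- kappa(cbind(1, scale(X)), exact = TRUE)
  if (!is.finite(kx) || kx > condition_warn)
    warning(sprintf("candidate predictors are near-collinear (condition number %.3g)", kx))
  full <- fit_lmm(dat, response, candidate_predictors, group, method = "ML")
  out <- lapply(candidate_predictors, function(pred) {
    red <- fit_lmm(dat, response, setdiff(candidate_predictors, pred),
                   group, method = "ML")
    stat <- 2 * (full$logLik - red$logLik)
    if (stat < 0 && stat > -1e-6) stat <- 0
    ct <- full$coefficients
    est <- ct$estimate[ct$term == pred]
    p_t <- ct$p[ct$term == pred]
    data.frame(predictor = pred,
               estimate = if (length(est)) est else NA_real_,
               chisq = stat, df = 1L,
               p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               p_t = if (length(p_t)) p_t else NA_real_)
  })
  do.call(rbind, out)
}

#' Partial correlation by residualisation
#'
#' Correlation of `x` and `y` after linearly removing the `controls` from
#' both; with no controls this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param controls Optional numeric vector, matrix or data.frame of control
#'   variables.
#' @return Partial correlation coefficient, or NA when either residual is
#'   constant or fewer than `ncol(controls) + 3` complete rows remain.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls)) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) return(NA_real_)
    return(stats::cor(x[ok], y[ok]))
  }
  Z <- as.matrix(as.data.frame(controls))
  ok <- stats::complete.cases(x, y, Z)
  if (sum(ok) < ncol(Z) + 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  rx <- stats::lm.fit(cbind(1, Z), x)$residuals
  ry <- stats::lm.fit(cbind(1, Z), y)$residuals
  cx <- stats::sd(rx) < 1e-12; cy <- stats::sd(ry) < 1e-12
  if (cx && cy) return(NA_real_)    # both constant: undefined
  if (cx || cy) return(0)           # one fully explained by the controls
  stats::cor(rx, ry)
}

#' Compare two correlation coefficients (Fisher Z-test)
#'
#' Tests whether two independent correlations differ:
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value. Used to compare a cross-session correlation against the
#' within-session split-half stability baseline.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (>= 4).
#' @return List with `Z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("fisher_z_compare requires |r| < 1")
  Z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank test of a location difference between two samples
#' (normal approximation for ties).
#'
#' @param a,b Numeric samples.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Holm-Bonferroni step-down correction
#'
#' @param pvals Numeric vector of p-values.
#' @param alpha Family-wise error rate. Default 0.05.
#' @return data.frame(p, p_adj, reject) in the input order (empty input
#'   gives an empty frame).
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (!length(pvals))
    return(data.frame(p = numeric(), p_adj = numeric(), reject = logical()))
  adj <- stats::p.adjust(pvals, method = "holm")
  data.frame(p = pvals, p_adj = adj, reject = adj <= alpha)
}

#' R-squared with a bootstrap confidence interval
#'
#' Coefficient of determination of the linear regression of `response` on
#' `predictors`, with a seeded nonparametric bootstrap (resampling rows)
#' percentile confidence interval.
#'
#' @param table data.frame.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns.
#' @param n_boot Bootstrap resamples. Default 1000.
#' @param conf Confidence level. Default 0.95.
#' @param seed Optional integer seed for the bootstrap.
#' @return List with `r2` and `ci` (length-2 numeric).
#' @export
r2_with_ci <- function(table, response, predictors, n_boot = 1000,
                       conf = 0.95, seed = NULL) {
  used <- c(response, predictors)
  dat <- table[stats::complete.cases(table[, used, drop = FALSE]), used, drop = FALSE]
  f <- stats::as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  r2 <- summary(stats::lm(f, data = dat))$r.squared
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dat)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    summary(stats::lm(f, data = dat[idx, , drop = FALSE]))$r.squared
  }, numeric(1))
  a <- (1 - conf) / 2
  list(r2 = r2, ci = unname(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE)))
}
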