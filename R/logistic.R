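# Multivariable binary logistic regression with Wald statistics and odds
# ratios, plus the odds-ratio arithmetic used in the published table.

#' Odds ratio and 95% CI from a logistic coefficient
#'
#' OR = exp(beta); CI = exp(beta +/- 1.96 se).
#'
#' @param beta coefficient (log-odds per unit).
#' @param se its standard error (> 0 for a CI; 0 collapses the CI to the OR).
#' @return list with `or`, `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' or_from_beta(0.171, 0.041)  # OR 1.19, CI 1.09-1.29
or_from_beta <- function(beta, se) {
  if (se < 0) stop("se must be non-negative")
  list(or = exp(beta), ci_lower = exp(beta - 1.96 * se),
       ci_upper = exp(beta + 1.96 * se))
}

#' Multivariable binary logistic regression
#'
#' Maximum-likelihood fit by iteratively reweighted least squares (via
#' `stats::glm`), standard errors from the observed information, Wald
#' chi-square = (beta/se)^2 with p from chi-square(1), and odds ratios with
#' 1.96-SE confidence intervals. Constant covariates are dropped and flagged;
#' (quasi-)perfect separation is detected and raised as an explicit error
#' rather than returned as a divergent fit.
#'
#' @param x data.frame or matrix of covariates (one column per predictor).
#' @param y binary outcome: logical, 0/1, or "ASD"/"control" labels.
#' @return list of class `logit_result`: `coefficients` (data.frame with
#'   `term`, `beta`, `se`, `wald`, `p`, `or`, `or_lower`, `or_upper`,
#'   including the intercept row), `converged`, `dropped` (flagged constant
#'   covariates), `n`.
#' @export
logistic_fit <- function(x, y) {
  x <- as.data.frame(x)
  yl <- as.integer(check_labels(y))
  if (nrow(x) != length(yl)) stop("x and y dimensions differ")
  if (nrow(x) <= ncol(x) + 1) stop("need n > number of covariates + 1")
  const <- vapply(x, function(col) stats::var(as.numeric(col)) == 0, logical(1))
  dropped <- names(x)[const]
  x <- x[!const]
  dat <- cbind(x, .y = yl)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  if (!fit$converged || any(abs(cf[, "Estimate"][-1]) > 25) ||
      all(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8))
    stop("perfect separation detected; coefficients are not identifiable")
  beta <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  wald <- (beta / se)^2
  coefs <- data.frame(term = rownames(cf), beta = beta, se = se, wald = wald,
                      p = stats::pchisq(wald, 1, lower.tail = FALSE),
                      or = exp(beta), or_lower = exp(beta - 1.96 * se),
                      or_upper = exp(beta + 1.96 * se),
                      row.names = NULL)
  structure(list(coefficients = coefs, converged = fit$converged,
                 dropped = dropped, n = length(yl),
                 loglik = as.numeric(stats::logLik(fit))),
            class = "logit_result")
}
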