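# ROC analysis: nonparametric AUC, Hanley-McNeil standard error, Youden
# cut-offs, stratified cross-validated and bootstrap bias-corrected AUC.

# Coerce labels to logical case indicators: "ASD" is the positive class for
# character/factor labels, the larger value for numeric 0/1 coding.
check_labels <- function(labels) {
  if (is.logical(labels)) {
    l <- labels
  } else if (is.numeric(labels)) {
    l <- labels == max(labels)
  } else {
    ch <- as.character(labels)
    pos <- if ("ASD" %in% ch) "ASD" else sort(unique(ch))[1]
    l <- ch == pos
  }
  if (all(l) || !any(l)) stop("both classes must be present")
  l
}

#' Nonparametric (Mann-Whitney) AUC
#'
#' Probability that a random case scores above a random control, ties counted
#' one half -- identical to the trapezoidal area under the empirical ROC
#' curve. Higher scores indicate the positive class.
#'
#' @param scores numeric predictor values.
#' @param labels case/control labels: logical, 0/1, or "ASD"/"control".
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))  # 0.75
roc_auc <- function(scores, labels) {
  l <- check_labels(labels)
  n1 <- as.numeric(sum(l)); n0 <- as.numeric(sum(!l))
  r <- rank(scores)
  (sum(r[l]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sensitivity and specificity of the rule `score >= threshold` evaluated at
#' every distinct observed score (plus the two extremes).
#'
#' @inheritParams roc_auc
#' @return data.frame sorted by descending threshold: `threshold`,
#'   `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  l <- check_labels(labels)
  u <- sort(unique(scores))
  thr <- c(Inf, rev(u), -Inf)
  sens <- vapply(thr, function(th) mean(scores[l] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(scores[!l] < th), numeric(1))
  data.frame(threshold = thr, sensitivity = sens, specificity = spec)
}

#' Hanley-McNeil standard error of the AUC
#'
#' Closed-form approximation under the exponential-distribution assumption:
#' Q1 = A/(2-A), Q2 = 2A^2/(1+A).
#'
#' @param auc the AUC estimate.
#' @param n_cases,n_controls class sizes.
#' @return standard error.
#' @export
hanley_mcneil_se <- function(auc, n_cases, n_controls) {
  if (auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  if (n_cases < 1 || n_controls < 1) stop("class counts must be >= 1")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_cases - 1) * (q1 - auc^2) +
          (n_controls - 1) * (q2 - auc^2)) / (n_cases * n_controls))
}

#' AUC standard error and Wald 95% confidence interval
#'
#' CI constructed as `auc +/- 1.96 * se`, clipped to \[0, 1\]; the SE defaults
#' to the Hanley-McNeil approximation but a known SE can be supplied.
#'
#' @inheritParams hanley_mcneil_se
#' @param se optional externally supplied standard error.
#' @return list with `se`, `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' auc_se_ci(0.776, 50, 50, se = 0.046)  # ci (0.686, 0.866)
auc_se_ci <- function(auc, n_cases, n_controls, se = NULL) {
  if (auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  se <- se %||% hanley_mcneil_se(auc, n_cases, n_controls)
  list(se = se, ci_lower = max(0, auc - 1.96 * se),
       ci_upper = min(1, auc + 1.96 * se))
}

#' Optimal cut-off by the Youden index
#'
#' Maximizes J = sensitivity + specificity - 1 under the decision rule
#' `score >= cutoff` is positive. Candidate cut-offs are the midpoints between
#' adjacent distinct scores (plus the extremes), so the reported value lies
#' between the data; ties in J are broken toward higher sensitivity.
#'
#' @inheritParams roc_auc
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  l <- check_labels(labels)
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) c(u[1] - 1, (u[-length(u)] + u[-1]) / 2,
                               u[length(u)] + 1)
          else c(u - 1, u + 1)
  sens <- vapply(cand, function(th) mean(scores[l] >= th), numeric(1))
  spec <- vapply(cand, function(th) mean(scores[!l] < th), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)   # numerical ties count as ties
  best <- best[sens[best] >= max(sens[best]) - 1e-12]
  best <- best[1]
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

stratified_folds <- function(l, k, seed) {
  set.seed(seed)
  fold <- integer(length(l))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(l == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated AUC of a univariate index
#'
#' Stratified k-fold resampling: the held-out AUC is computed per fold from
#' the raw score (no model fitting is needed for a single index; folding
#' quantifies sampling variability of the estimate). Folds are redrawn with a
#' new derived seed if any fold lacks a class.
#'
#' @inheritParams roc_auc
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list with `auc` (mean over folds), `ci_lower`, `ci_upper` (normal
#'   CI from the fold spread), and `fold_aucs`.
#' @export
crossval_auc <- function(scores, labels, k = 10, seed = 1L) {
  l <- check_labels(labels)
  if (length(scores) < k) stop("need n >= k")
  for (attempt in 1:20) {
    fold <- stratified_folds(l, k, child_seed(seed, 40L + attempt))
    ok <- all(vapply(seq_len(k), function(f)
      any(l[fold == f]) && any(!l[fold == f]), logical(1)))
    if (ok) break
  }
  if (!ok) stop("could not stratify folds with both classes")
  aucs <- vapply(seq_len(k), function(f)
    roc_auc(scores[fold == f], l[fold == f]), numeric(1))
  m <- mean(aucs)
  half <- 1.96 * stats::sd(aucs) / sqrt(k)
  list(auc = m, ci_lower = max(0, m - half), ci_upper = min(1, m + half),
       fold_aucs = aucs)
}

#' Bootstrap bias-corrected AUC with percentile CI
#'
#' Stratified resampling (cases and controls drawn separately, so every
#' resample keeps both classes): bias-corrected estimate
#' `2 * auc_full - mean(auc_boot)` and the 2.5/97.5 percentile interval of the
#' bootstrap distribution.
#'
#' @inheritParams roc_auc
#' @param B number of resamples (default 1000).
#' @param seed integer seed.
#' @return list with `auc_full`, `auc_bc`, `ci_lower`, `ci_upper`.
#' @export
bootstrap_auc <- function(scores, labels, B = 1000, seed = 1L) {
  l <- check_labels(labels)
  set.seed(child_seed(seed, 50L))
  i1 <- which(l); i0 <- which(!l)
  full <- roc_auc(scores, l)
  aucs <- vapply(seq_len(B), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    roc_auc(scores[idx], l[idx])
  }, numeric(1))
  ci <- unname(stats::quantile(aucs, c(0.025, 0.975)))
  list(auc_full = full, auc_bc = 2 * full - mean(aucs),
       ci_lower = ci[1], ci_upper = ci[2])
}
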