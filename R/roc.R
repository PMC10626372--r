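#' DeLong ROC analysis of a continuous biomarker
#'
#' Empirical AUC via the Mann-Whitney estimator (ties counted 1/2), with the
#' DeLong standard error from placement-value variances, a Wald 95% CI
#' clipped to \[0, 1\], and the Youden-optimal operating point. The direction
#' is chosen automatically so the AUC is at least 0.5 and recorded:
#' `"greater"` means higher scores indicate the positive class (the reported
#' rule is score > threshold), `"less"` means score <= threshold.
#'
#' @param data A data frame.
#' @param score Column of biomarker scores (tidy-eval).
#' @param truth Column of class labels (tidy-eval): logical, 0/1, or a
#'   two-level factor/character (then `positive` names the positive level).
#' @param positive Positive class label, required for character/factor truth
#'   with no obvious positive level.
#' @return A one-row tibble of class `cu_roc`: `auc`, `se_auc`, `ci_low`,
#'   `ci_high`, `p_value` (vs AUC = 0.5), `direction`, `threshold`,
#'   `sensitivity`, `specificity`, `accuracy`, `youden_j`, `n_pos`, `n_neg`.
#'   The full ROC curve is attached as attribute `"curve"` and is returned by
#'   [tidy.cu_roc()].
#' @export
roc_delong <- function(data, score, truth, positive = NULL) {
  sc <- dplyr::pull(data, {{ score }})
  lb <- dplyr::pull(data, {{ truth }})
  pos <- as_positive_indicator(lb, positive)
  if (anyNA(sc)) stop("missing scores are not allowed")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos < 2 || n_neg < 2) stop("need at least 2 subjects in each class")
  res <- delong_components(sc, pos)
  direction <- "greater"
  if (res$auc < 0.5) {
    direction <- "less"
    res <- delong_components(-sc, pos)
  }
  se <- sqrt(res$var)
  ci <- pmin(1, pmax(0, res$auc + c(-1, 1) * stats::qnorm(0.975) * se))
  p <- if (se > 0) 2 * stats::pnorm(-abs(res$auc - 0.5) / se)
  else as.numeric(res$auc == 0.5)
  yo <- youden_search(sc, pos, direction)
  out <- tibble::tibble(
    auc = res$auc, se_auc = se, ci_low = ci[1], ci_high = ci[2],
    p_value = p, direction = direction,
    threshold = yo$threshold, sensitivity = yo$sensitivity,
    specificity = yo$specificity, accuracy = yo$accuracy,
    youden_j = yo$youden_j, n_pos = n_pos, n_neg = n_neg
  )
  attr(out, "curve") <- roc_curve_points(sc, pos, direction)
  class(out) <- c("cu_roc", class(out))
  out
}

# Placement values of the DeLong estimator. `pos` logical; higher scores
# indicate positives. V10[i]: fraction of negatives below positive i (ties
# 1/2); V01[j]: fraction of positives above negative j.
delong_components <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  n1 <- length(x); n0 <- length(y)
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n0, 0)
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / n1, 0)
  auc <- mean(v10)
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  list(auc = auc, v10 = v10, v01 = v01, var = s10 / n1 + s01 / n0)
}

as_positive_indicator <- function(labels, positive = NULL) {
  if (is.logical(labels)) {
    pos <- labels
  } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    pos <- labels == 1
  } else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("truth must have exactly 2 classes")
    if (is.null(positive)) {
      positive <- intersect(c("positive", "mutant", "TRUE", "1"), lv)
      if (length(positive) != 1) {
        stop(sprintf("specify the positive class (levels: %s)",
                     paste(lv, collapse = ", ")))
      }
    }
    if (!positive %in% lv) stop(sprintf("positive class '%s' not in labels", positive))
    pos <- as.character(labels) == positive
  }
  if (anyNA(pos)) stop("missing class labels are not allowed")
  pos
}

# Candidate thresholds: midpoints of consecutive sorted unique scores,
# plus -Inf and +Inf; maximizes Youden's J; ties -> smallest threshold.
youden_search <- function(scores, pos, direction = "greater") {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n1 <- sum(pos); n0 <- sum(!pos)
  stats <- vapply(cand, function(th) {
    pred <- if (direction == "greater") scores > th else scores <= th
    sens <- sum(pred & pos) / n1
    spec <- sum(!pred & !pos) / n0
    c(sens, spec, mean(pred == pos))
  }, numeric(3))
  j <- stats[1, ] + stats[2, ] - 1
  best <- which(j >= max(j) - 1e-12)[1]
  list(threshold = cand[best], sensitivity = stats[1, best],
       specificity = stats[2, best], accuracy = stats[3, best],
       youden_j = j[best])
}

roc_curve_points <- function(scores, pos, direction) {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  pts <- vapply(cand, function(th) {
    pred <- if (direction == "greater") scores > th else scores <= th
    c(sum(pred & pos) / sum(pos), 1 - sum(!pred & !pos) / sum(!pos))
  }, numeric(2))
  tibble::tibble(threshold = cand, sensitivity = pts[1, ], fpr = pts[2, ]) |>
    dplyr::arrange(.data$fpr, .data$sensitivity)
}

#' Youden-optimal cutpoint
#'
#' The threshold maximizing `J = sensitivity + specificity - 1`
#' (prevalence-independent); candidates are midpoints between consecutive
#' sorted unique scores plus the infinities; ties go to the smallest
#' threshold. Accuracy is reported at the chosen threshold (prevalence
#' dependent).
#'
#' @inheritParams roc_delong
#' @param direction `"auto"` (from the ROC direction), `"greater"` (score >
#'   threshold is positive) or `"less"` (score <= threshold is positive).
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `youden_j`, `direction`.
#' @export
youden_optimal <- function(data, score, truth, direction = c("auto", "greater", "less"),
                           positive = NULL) {
  direction <- match.arg(direction)
  sc <- dplyr::pull(data, {{ score }})
  lb <- dplyr::pull(data, {{ truth }})
  pos <- as_positive_indicator(lb, positive)
  if (sum(pos) < 1 || sum(!pos) < 1) stop("both classes must be present")
  if (direction == "auto") {
    auc <- delong_components(sc, pos)$auc
    direction <- if (auc >= 0.5) "greater" else "less"
  }
  yo <- youden_search(sc, pos, direction)
  tibble::tibble(threshold = yo$threshold, sensitivity = yo$sensitivity,
                 specificity = yo$specificity, accuracy = yo$accuracy,
                 youden_j = yo$youden_j, direction = direction)
}

#' Evaluate a fixed threshold on new data
#'
#' Sensitivity, specificity and accuracy of the decision rule frozen at a
#' given threshold and direction, e.g. a training-set Youden cutpoint applied
#' to an independent evaluation set.
#'
#' @inheritParams roc_delong
#' @param threshold Decision threshold.
#' @param direction `"greater"` (score > threshold is positive) or `"less"`.
#' @return A one-row tibble: `threshold`, `direction`, `sensitivity`,
#'   `specificity`, `accuracy`, `n_pos`, `n_neg`.
#' @export
evaluate_threshold <- function(data, score, truth, threshold,
                               direction = c("greater", "less"),
                               positive = NULL) {
  direction <- match.arg(direction)
  sc <- dplyr::pull(data, {{ score }})
  pos <- as_positive_indicator(dplyr::pull(data, {{ truth }}), positive)
  pred <- if (direction == "greater") sc > threshold else sc <= threshold
  tibble::tibble(
    threshold = threshold, direction = direction,
    sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos),
    accuracy = mean(pred == pos),
    n_pos = sum(pos), n_neg = sum(!pos)
  )
}

#' Compare two paired AUCs by the DeLong method
#'
#' Both markers are measured on the same subjects; the difference in AUCs is
#' tested with the DeLong paired covariance of the placement values and a
#' two-sided normal p-value. Each marker is oriented to its own AUC >= 0.5
#' before comparison.
#'
#' @param data A data frame.
#' @param score_a,score_b Columns of the two biomarker scores (tidy-eval).
#' @inheritParams roc_delong
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta_auc`, `se_delta`, `z`,
#'   `p_value`.
#' @export
compare_paired_auc <- function(data, score_a, score_b, truth, positive = NULL) {
  sa <- dplyr::pull(data, {{ score_a }})
  sb <- dplyr::pull(data, {{ score_b }})
  pos <- as_positive_indicator(dplyr::pull(data, {{ truth }}), positive)
  if (length(sa) != length(sb)) stop("paired scores must have the same length")
  ca <- delong_components(sa, pos)
  if (ca$auc < 0.5) ca <- delong_components(-sa, pos)
  cb <- delong_components(sb, pos)
  if (cb$auc < 0.5) cb <- delong_components(-sb, pos)
  n1 <- sum(pos); n0 <- sum(!pos)
  cov10 <- stats::cov(ca$v10, cb$v10)
  cov01 <- stats::cov(ca$v01, cb$v01)
  var_delta <- ca$var + cb$var - 2 * (cov10 / n1 + cov01 / n0)
  var_delta <- max(var_delta, 0)
  delta <- ca$auc - cb$auc
  se <- sqrt(var_delta)
  z <- if (se > 0) delta / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(delta == 0)
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, delta_auc = delta,
                 se_delta = se, z = z, p_value = p)
}
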