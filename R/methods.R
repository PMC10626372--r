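#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ROC result into per-threshold operating points
#'
#' @param x A `cu_roc` object from [roc_delong()].
#' @param ... Unused.
#' @return A tibble with one row per candidate threshold: `threshold`,
#'   `sensitivity`, `fpr`.
#' @export
tidy.cu_roc <- function(x, ...) {
  attr(x, "curve")
}

#' One-row summary of a ROC result
#'
#' @inheritParams tidy.cu_roc
#' @return A plain one-row tibble with the AUC, its SE and CI, the Youden
#'   operating point and class counts.
#' @export
glance.cu_roc <- function(x, ...) {
  out <- x
  attr(out, "curve") <- NULL
  class(out) <- setdiff(class(out), "cu_roc")
  out
}

#' Tidy a nonparametric test result
#'
#' For tests with a pairwise post hoc table (Dunn), the table is returned;
#' otherwise the one-row test summary without list-columns.
#'
#' @param x A `cu_htest` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cu_htest <- function(x, ...) {
  if ("pairwise" %in% names(x)) return(x$pairwise[[1]])
  out <- x[, !vapply(x, is.list, TRUE)]
  class(out) <- setdiff(class(out), "cu_htest")
  out
}

#' @rdname tidy.cu_htest
#' @export
glance.cu_htest <- function(x, ...) {
  out <- x[, !vapply(x, is.list, TRUE)]
  class(out) <- setdiff(class(out), "cu_htest")
  out
}

#' Plot a ROC curve
#'
#' The empirical ROC curve with the AUC and the Youden-optimal operating
#' point highlighted.
#'
#' @param object A `cu_roc` object from [roc_delong()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cu_roc <- function(object, ...) {
  curve <- attr(object, "curve")
  op <- tibble::tibble(fpr = 1 - object$specificity,
                       sensitivity = object$sensitivity)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(data = op, colour = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$ci_low, object$ci_high),
      subtitle = sprintf("Youden threshold %s %.3g: sens %.2f, spec %.2f",
                         ifelse(object$direction == "greater", ">", "≤"),
                         object$threshold, object$sensitivity,
                         object$specificity)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot the radial uptake profile of a phantom
#'
#' Fraction-of-maximum uptake against radius, with the compartment band
#' boundaries (80%, 75%, 60% of maximum) marked.
#'
#' @param object A [phantom_spec()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_spec <- function(object, ...) {
  rp <- radial_profile(object)
  gt <- rp$ground_truth
  r <- seq(0, 1.5 * gt$r60, length.out = 400)
  df <- tibble::tibble(radius_mm = r, fraction = rp$profile(r))
  bands <- tibble::tibble(
    r = c(gt$r80, gt$r75, gt$r60),
    band = c("80% (central edge)", "75%", "60% (lesion edge)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_mm, y = .data$fraction)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(data = bands,
                        ggplot2::aes(xintercept = .data$r, colour = .data$band),
                        linetype = "dotted") +
    ggplot2::labs(x = "Radius (mm)", y = "Fraction of SUVmax",
                  colour = "Isocontour") +
    ggplot2::theme_minimal()
}

#' Distribution of a biomarker by genotype
#'
#' Jittered points with group medians, on a log scale by default (the CU
#' ratio is log-normal by construction in the synthetic cohort).
#'
#' @param records Cohort tibble.
#' @param biomarker Biomarker column (tidy-eval).
#' @param label Grouping column (tidy-eval).
#' @param log_scale Use a log10 y-axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_group_distribution <- function(records, biomarker, label,
                                    log_scale = TRUE) {
  p <- ggplot2::ggplot(records, ggplot2::aes(x = {{ label }},
                                             y = {{ biomarker }})) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "red", linewidth = 0.4) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @keywords internal
#' @importFrom rlang .data
#' @importFrom tibble tibble
"_PACKAGE"
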