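new_htest <- function(method, statistic_name, statistic, p_value, tails,
                      n1, n2 = NA_integer_, ...) {
  out <- tibble::tibble(method = method, statistic_name = statistic_name,
                        statistic = statistic, p_value = p_value,
                        tails = tails, n1 = n1, n2 = n2, ...)
  class(out) <- c("cu_htest", class(out))
  out
}

#' Mann-Whitney U test for two independent groups
#'
#' Reports the U statistic in the min(Ux, Uy) convention. The p-value is
#' exact (from the null rank-sum distribution) when the combined sample size
#' is at most 12 and there are no ties, otherwise a normal approximation with
#' tie and continuity correction is used.
#'
#' @param data A data frame.
#' @param value Column of measurements (tidy-eval).
#' @param group Column with exactly two group labels (tidy-eval).
#' @param tails `"two"` (default) or `"one"` (smaller tail, i.e. the observed
#'   direction).
#' @return A one-row tibble of class `cu_htest` with the test and per-group
#'   median/IQR summaries (`summary` list-column).
#' @export
mann_whitney_u <- function(data, value, group, tails = c("two", "one")) {
  tails <- match.arg(tails)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  lv <- sort(unique(g))
  if (length(lv) != 2) stop("group must have exactly 2 levels")
  x <- v[g == lv[1]]; y <- v[g == lv[2]]
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  u <- min(ux, uy)
  ties <- length(unique(c(x, y))) < nx + ny
  if (!ties && nx + ny <= 12) {
    p_one <- stats::pwilcox(u, nx, ny)
    exact <- TRUE
  } else {
    mu <- nx * ny / 2
    nt <- table(c(x, y))
    tie_term <- sum(nt^3 - nt) / ((nx + ny) * (nx + ny - 1))
    sigma <- sqrt(nx * ny / 12 * ((nx + ny + 1) - tie_term))
    p_one <- stats::pnorm((u + 0.5 - mu) / sigma)
    exact <- FALSE
  }
  p <- if (tails == "two") min(1, 2 * p_one) else p_one
  summ <- dplyr::bind_rows(
    group_summary(x, lv[1]), group_summary(y, lv[2]))
  new_htest(
    method = if (exact) "Mann-Whitney U (exact)" else "Mann-Whitney U (normal approx.)",
    statistic_name = "U", statistic = u, p_value = p, tails = tails,
    n1 = nx, n2 = ny, summary = list(summ))
}

group_summary <- function(x, label) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(group = label, n = length(x), median = q[2], iqr = q[3] - q[1])
}

#' Wilcoxon signed-rank test for matched pairs
#'
#' Differences `x - y` are ranked by absolute value after dropping zeros
#' (the number dropped is recorded); the statistic is the sum of ranks of
#' positive differences. For n <= 12 the p-value is exact, from full
#' enumeration of all `2^n` sign assignments on the observed midranks (so
#' ties in |differences| remain exact); beyond that a normal approximation
#' with tie and continuity correction is used. Default one-tailed in the
#' observed direction.
#'
#' @param data A data frame with one row per pair.
#' @param x,y Paired measurement columns (tidy-eval).
#' @param tails `"one"` (default) or `"two"`.
#' @return A one-row tibble of class `cu_htest`; `n1` is the number of
#'   non-zero pairs, column `n_dropped` the zeros removed.
#' @export
wilcoxon_signed_rank <- function(data, x, y, tails = c("one", "two")) {
  tails <- match.arg(tails)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) != length(yv)) stop("paired vectors must have equal length")
  d <- xv - yv
  n_dropped <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 12) {
    # enumerate all 2^n sign assignments on the observed midranks, so the
    # tail is exact even with tied |differences|
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    p_less <- mean(w_all <= w + 1e-12)
    p_greater <- mean(w_all >= w - 1e-12)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    nt <- table(abs(d))
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(nt^3 - nt) / 48)
    p_less <- stats::pnorm((w + 0.5 - mu) / sigma)
    p_greater <- stats::pnorm(-(w - 0.5 - mu) / sigma)
    exact <- FALSE
  }
  p <- if (tails == "two") min(1, 2 * min(p_less, p_greater)) else min(p_less, p_greater)
  new_htest(
    method = if (exact) "Wilcoxon signed-rank (exact)" else "Wilcoxon signed-rank (normal approx.)",
    statistic_name = "W", statistic = w, p_value = p, tails = tails,
    n1 = n, n_dropped = n_dropped)
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Tie-corrected H with a chi-square p-value (via [stats::kruskal.test()]),
#' followed by Dunn's pairwise z tests on mean ranks with Holm-Sidak adjusted
#' p-values.
#'
#' @param data A data frame.
#' @param value Column of measurements (tidy-eval).
#' @param group Column with at least 3 group labels, each with n >= 2
#'   (tidy-eval).
#' @return A one-row tibble of class `cu_htest` with the omnibus test; the
#'   pairwise Dunn table (`group_a`, `group_b`, `z`, `p_value`,
#'   `p_adjusted`, `mean_rank_diff`) is in the `pairwise` list-column.
#' @export
kruskal_wallis_dunn <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  lv <- sort(unique(g))
  if (length(lv) < 3) stop("need at least 3 groups")
  ns <- table(g)
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  kt <- stats::kruskal.test(v, factor(g))
  n <- length(v)
  r <- rank(v)
  mean_ranks <- tapply(r, g, mean)
  nt <- table(v)
  tie_corr <- sum(nt^3 - nt) / (12 * (n - 1))
  pairs <- utils::combn(lv, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diffr <- mean_ranks[[a]] - mean_ranks[[b]]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- diffr / se
    tibble::tibble(group_a = a, group_b = b, mean_rank_diff = diffr,
                   z = z, p_value = 2 * stats::pnorm(-abs(z)))
  })
  pw$p_adjusted <- holm_sidak(pw$p_value)
  new_htest(
    method = "Kruskal-Wallis (tie-corrected) with Dunn post hoc",
    statistic_name = "H", statistic = unname(kt$statistic),
    p_value = kt$p.value, tails = "two",
    n1 = n, n2 = length(lv), pairwise = list(pw))
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts p-values ascending, sets `adj_i = 1 - (1 - p_(i))^(m - i + 1)`,
#' enforces monotone non-decreasing adjusted values, and restores the input
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
holm_sidak <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

#' Spearman rank correlation test
#'
#' Rho is the Pearson correlation of mid-ranks. The p-value is exact (full
#' permutation distribution of one rank vector) for n <= 8, otherwise the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param data A data frame.
#' @param x,y Measurement columns (tidy-eval); neither may be constant.
#' @param tails `"two"` (default) or `"one"`.
#' @return A one-row tibble of class `cu_htest` with `statistic = rho`.
#' @export
spearman_cor <- function(data, x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(xv)) < 2 || length(unique(yv)) < 2) {
    stop("constant input vector: rho undefined")
  }
  rx <- rank(xv); ry <- rank(yv)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    pm <- all_permutations(n)
    rho_perm <- apply(pm, 1, function(ix) stats::cor(rx, ry[ix]))
    p_two <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    p_one <- mean(rho_perm * sign(rho) >= abs(rho) - 1e-12)
    method <- "Spearman (exact permutation)"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_two <- 2 * stats::pt(-abs(tstat), n - 2)
    p_one <- stats::pt(-abs(tstat), n - 2)
    method <- "Spearman (t approximation)"
  }
  new_htest(method = method, statistic_name = "rho", statistic = rho,
            p_value = if (tails == "two") p_two else p_one,
            tails = tails, n1 = n)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Univariate logistic regression with predictive accuracy
#'
#' Maximum-likelihood fit of `P(positive) = logistic(a + b * score)` (IRLS
#' via [stats::glm()]); predictive accuracy is the fraction of subjects
#' correctly classified at a predicted-probability cutoff of 0.5. Complete
#' separation is detected and flagged; the accuracy is still reported.
#'
#' @inheritParams roc_delong
#' @return A one-row tibble: `intercept`, `slope`, `predictive_accuracy`,
#'   `separation`, `converged`, `n`.
#' @export
logistic_accuracy <- function(data, score, truth, positive = NULL) {
  sc <- dplyr::pull(data, {{ score }})
  pos <- as_positive_indicator(dplyr::pull(data, {{ truth }}), positive)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  separated <- max(sc[!pos]) < min(sc[pos]) || max(sc[pos]) < min(sc[!pos])
  fit <- withCallingHandlers(
    stats::glm(pos ~ sc, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged && !separated) {
    stop(sprintf("logistic fit did not converge (deviance %.4g after %d iterations)",
                 fit$deviance, fit$iter))
  }
  pred <- stats::fitted(fit) > 0.5
  tibble::tibble(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    predictive_accuracy = mean(pred == pos),
    separation = separated,
    converged = fit$converged,
    n = length(sc)
  )
}
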