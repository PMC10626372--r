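roc_df <- function(scores, labels) tibble::tibble(score = scores, y = labels)

test_that("the empirical AUC counts concordant pairs with ties at one half", {
  r <- roc_delong(roc_df(c(1, 2, 3, 4), c(0, 1, 0, 1)), score, y)
  expect_equal(r$auc, 0.75)
  expect_equal(r$direction, "greater")
  # perfect separation: AUC 1, SE 0, CI degenerate at 1
  p <- roc_delong(roc_df(c(1, 2, 10, 11), c(0, 0, 1, 1)), score, y)
  expect_equal(p$auc, 1)
  expect_equal(p$se_auc, 0)
  expect_equal(c(p$ci_low, p$ci_high), c(1, 1))
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 1)
  # reversed marker: direction flips, AUC still >= 0.5
  rev <- roc_delong(roc_df(c(10, 9, 1, 2), c(0, 0, 1, 1)), score, y)
  expect_equal(rev$direction, "less")
  expect_equal(rev$auc, 1)
  expect_error(roc_delong(roc_df(1:4, c(1, 1, 1, 1)), score, y), "2 classes|class")
})

test_that("AUC equals U/(n1 n0) from the rank-sum statistic on random data", {
  set.seed(301)
  for (rep in 1:50) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    sc <- c(rnorm(n1, 1), rnorm(n0))
    y <- rep(c(1, 0), c(n1, n0))
    r <- roc_delong(roc_df(sc, y), score, y)
    w <- suppressWarnings(wilcox.test(sc[y == 1], sc[y == 0]))$statistic
    auc_raw <- unname(w) / (n1 * n0)
    expect_equal(r$auc, if (r$direction == "greater") auc_raw else 1 - auc_raw)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(302)
  sc <- rnorm(40); y <- rbinom(40, 1, 0.4)
  if (sum(y) < 2 || sum(1 - y) < 2) y[1:2] <- c(0, 1)
  base <- roc_delong(roc_df(sc, y), score, y)
  expect_equal(roc_delong(roc_df(exp(sc), y), score, y)$auc, base$auc)
  expect_equal(roc_delong(roc_df(rank(sc), y), score, y)$auc, base$auc)
  expect_equal(roc_delong(roc_df(exp(sc), y), score, y)$se_auc, base$se_auc)
})

test_that("DeLong AUC and SE agree with an independent implementation", {
  set.seed(303)
  for (rep in 1:25) {
    n1 <- sample(5:15, 1); n0 <- sample(5:15, 1)
    sc <- c(rnorm(n1, 0.8), rnorm(n0))
    y <- rep(c(1, 0), c(n1, n0))
    r <- roc_delong(roc_df(sc, y), score, y)
    pr <- pROC::roc(y, sc, quiet = TRUE, direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    expect_equal(r$se_auc, sqrt(pROC::var(pr, method = "delong")),
                 tolerance = 1e-8)
  }
})

test_that("paired AUC comparison is antisymmetric and matches a bootstrap", {
  set.seed(304)
  n <- 40
  y <- rep(c(1, 0), c(18, 22))
  a <- rnorm(n) + y
  b <- 0.5 * a + rnorm(n, sd = 0.8) + 0.4 * y
  df <- tibble::tibble(a = a, b = b, y = y)
  ab <- compare_paired_auc(df, a, b, y)
  ba <- compare_paired_auc(df, b, a, y)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$p_value, ba$p_value)
  same <- compare_paired_auc(df, a, a, y)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)
  # subject-level bootstrap SE of the AUC difference
  auc_of <- function(s, yy) {
    r <- rank(s)
    (sum(r[yy == 1]) - sum(yy) * (sum(yy) + 1) / 2) / (sum(yy) * sum(1 - yy))
  }
  deltas <- replicate(10000, {
    ix <- sample(n, replace = TRUE)
    if (length(unique(y[ix])) < 2) return(NA_real_)
    auc_of(a[ix], y[ix]) - auc_of(b[ix], y[ix])
  })
  expect_equal(ab$se_delta, sd(deltas, na.rm = TRUE), tolerance = 0.25)
})

test_that("the Youden cutpoint equals exhaustive search and negates cleanly", {
  r <- youden_optimal(roc_df(c(1, 2, 3, 4), c(0, 0, 1, 1)), score, y)
  expect_equal(r$threshold, 2.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)
  # direction "less" on negated data negates the threshold
  neg <- youden_optimal(roc_df(-c(1, 2, 3, 4), c(0, 0, 1, 1)), score, y,
                        direction = "less")
  expect_equal(neg$threshold, -2.5)
  expect_equal(neg$sensitivity, 1)
  expect_equal(neg$specificity, 1)
  set.seed(305)
  for (rep in 1:30) {
    n <- sample(6:25, 1)
    sc <- round(rnorm(n), 1)  # deliberate ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    ours <- youden_optimal(roc_df(sc, y), score, y, direction = "greater")
    expect_equal(ours$youden_j, oracle_youden(sc, y == 1, "greater"),
                 tolerance = 1e-9)
    less <- youden_optimal(roc_df(-sc, y), score, y, direction = "less")
    expect_equal(less$youden_j, ours$youden_j, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U uses the min-U convention with exact small-sample p", {
  df <- tibble::tibble(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  r <- mann_whitney_u(df, v, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6)
  expect_match(r$method, "exact")
  summ <- r$summary[[1]]
  expect_equal(summ$median, c(1.5, 3.5))
  # agreement with base wilcox.test, exact and approximate
  set.seed(306)
  for (rep in 1:20) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    d2 <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), c(nx, ny)))
    ours <- mann_whitney_u(d2, v, g)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # exact vs normal approximation agree reasonably at the exactness boundary
  set.seed(307)
  x <- rnorm(6); y <- rnorm(6)
  d3 <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), each = 6))
  exact_p <- mann_whitney_u(d3, v, g)$p_value
  approx_p <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(exact_p, approx_p, tolerance = 0.1)
  expect_lt(abs(exact_p - approx_p), 0.02)
})

test_that("the null U statistic is centred at n1 n2 / 2", {
  set.seed(308)
  us <- replicate(400, {
    d <- tibble::tibble(v = rnorm(12), g = rep(c("a", "b"), c(5, 7)))
    u <- mann_whitney_u(d, v, g)$statistic
    u
  })
  # min-U convention: E[min(U, n1 n2 - U)] < 17.5, but near it
  expect_gt(mean(us), 17.5 - 2 * 35 / sqrt(12))
  expect_lte(max(us), 17.5)
})

test_that("Wilcoxon signed-rank drops zeros and has exact one-sided tails", {
  df <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2, 3, 4, 5, 6))
  r <- wilcoxon_signed_rank(df, x, y)
  expect_equal(r$p_value, 1 / 32)  # all differences negative, n = 5
  expect_equal(r$tails, "one")
  # zero differences reduce n
  df2 <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(1, 3, 4, 5, 6))
  r2 <- wilcoxon_signed_rank(df2, x, y)
  expect_equal(r2$n1, 4)
  expect_equal(r2$n_dropped, 1)
  expect_error(wilcoxon_signed_rank(tibble::tibble(x = 1:3, y = 1:3), x, y),
               "zero")
  # exact tail equals enumeration over all 2^8 sign patterns
  set.seed(309)
  d <- round(rnorm(8, 0.3, 1), 2)
  d <- d[d != 0]; n <- length(d)
  df3 <- tibble::tibble(x = d, y = 0)
  ours <- wilcoxon_signed_rank(df3, x, y)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% rk
  p_enum <- min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  expect_equal(ours$p_value, p_enum, tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches the rank-sum formula with Dunn post hoc", {
  ident <- tibble::tibble(v = rep(c(5, 5, 5), 3),
                          g = rep(c("a", "b", "c"), each = 3))
  # all values tied: H = 0 (tie-corrected), adjusted p all 1
  r0 <- kruskal_wallis_dunn(tibble::tibble(
    v = rep(1:3, 3), g = rep(c("a", "b", "c"), each = 3)), v, g)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_true(all(r0$pairwise[[1]]$p_adjusted > 0.99))
  # hand-ranked 3x3 example, no ties: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  df <- tibble::tibble(v = c(1, 4, 7, 2, 5, 8, 3, 6, 9),
                       g = rep(c("a", "b", "c"), 3))
  r <- kruskal_wallis_dunn(df, v, g)
  rbar <- c(mean(c(1, 2, 3)), mean(c(4, 5, 6)), mean(c(7, 8, 9)))
  h_hand <- 12 / (9 * 10) * sum(3 * rbar^2) - 3 * 10
  expect_equal(r$statistic, h_hand, tolerance = 1e-12)
  expect_error(kruskal_wallis_dunn(
    tibble::tibble(v = 1:4, g = rep(c("a", "b"), 2)), v, g), "3 groups")
  # chi-square p close to a permutation p at moderate n
  set.seed(310)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  rp <- kruskal_wallis_dunn(tibble::tibble(v = v, g = g), v, g)
  h_perm <- replicate(4000, {
    kruskal.test(v, factor(sample(g)))$statistic
  })
  p_perm <- mean(h_perm >= rp$statistic - 1e-12)
  expect_equal(rp$p_value, p_perm, tolerance = 0.35)
  expect_lt(abs(rp$p_value - p_perm), 0.03)
})

test_that("Holm-Sidak is the step-down Sidak with monotonicity", {
  expect_equal(holm_sidak(0.03), 0.03)
  expect_equal(holm_sidak(c(0, 0, 0)), c(0, 0, 0))
  adj <- holm_sidak(c(0.01, 0.04))
  expect_equal(adj, c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  # order restored, monotone in sorted order
  p <- c(0.2, 0.01, 0.8, 0.03)
  a <- holm_sidak(p)
  expect_equal(order(a), order(p))
  expect_true(all(diff(a[order(p)]) >= -1e-15))
  expect_error(holm_sidak(c(0.5, 1.2)), "0, 1")
})

test_that("Spearman rho hits the exact permutation tail for small n", {
  df <- tibble::tibble(x = 1:5, y = c(2, 4, 6, 8, 10))
  expect_equal(spearman_cor(df, x, y)$statistic, 1)
  expect_equal(spearman_cor(tibble::tibble(x = 1:5, y = 5:1), x, y)$statistic, -1)
  expect_error(spearman_cor(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               "constant")
  set.seed(311)
  for (rep in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    ours <- spearman_cor(tibble::tibble(x = x, y = y), x, y)
    expect_match(ours$method, "exact")
    expect_equal(ours$p_value, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
  # t approximation beyond n = 8
  big <- spearman_cor(tibble::tibble(x = rnorm(20), y = rnorm(20)), x, y)
  expect_match(big$method, "t approximation")
  expect_gte(big$p_value, 0)
  expect_lte(big$p_value, 1)
})

test_that("logistic accuracy classifies at probability 0.5 and flags separation", {
  sep <- tibble::tibble(s = c(1, 2, 3, 10, 11, 12),
                        y = c(0, 0, 0, 1, 1, 1))
  r <- logistic_accuracy(sep, s, y)
  expect_true(r$separation)
  expect_equal(r$predictive_accuracy, 1)
  # uninformative score: accuracy ~ majority class frequency
  set.seed(312)
  unin <- tibble::tibble(s = rnorm(200), y = rep(c(0, 1), c(120, 80)))
  r2 <- logistic_accuracy(unin, s, y)
  expect_false(r2$separation)
  expect_equal(r2$predictive_accuracy, 0.6, tolerance = 0.05)
  # fitted log-likelihood beats a parameter grid around the optimum
  set.seed(313)
  d10 <- tibble::tibble(s = rnorm(10), y = rbinom(10, 1, 0.5))
  if (length(unique(d10$y)) < 2) d10$y[1:2] <- c(0, 1)
  fit <- logistic_accuracy(d10, s, y)
  loglik <- function(a, b) {
    eta <- a + b * d10$s
    sum(d10$y * eta - log(1 + exp(eta)))
  }
  grid <- expand.grid(a = fit$intercept + seq(-1, 1, by = 0.05),
                      b = fit$slope + seq(-1, 1, by = 0.05))
  grid_best <- max(mapply(loglik, grid$a, grid$b))
  expect_gte(loglik(fit$intercept, fit$slope), grid_best - 1e-4)
})

test_that("tidy and glance methods expose curves and flat summaries", {
  set.seed(314)
  df <- roc_df(c(rnorm(10), rnorm(10, 2)), rep(c(0, 1), each = 10))
  r <- roc_delong(df, score, y)
  curve <- tidy(r)
  expect_true(all(c("threshold", "sensitivity", "fpr") %in% names(curve)))
  expect_gte(nrow(curve), 3)
  g <- glance(r)
  expect_false(inherits(g, "cu_roc"))
  expect_equal(g$auc, r$auc)
  ht <- mann_whitney_u(tibble::tibble(v = rnorm(10), g = rep(c("a", "b"), 5)),
                       v, g)
  expect_false("summary" %in% names(tidy(ht)))
  kw <- kruskal_wallis_dunn(tibble::tibble(v = rnorm(12),
                                           g = rep(c("a", "b", "c"), 4)), v, g)
  expect_true(all(c("z", "p_adjusted") %in% names(tidy(kw))))
  p1 <- autoplot(r)
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(small_phantom())
  expect_s3_class(p2, "ggplot")
})
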