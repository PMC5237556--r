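test_that("identical summaries give t = 0 with a symmetric CI", {
  g <- group_summary(mean = 5, sd = 2, n = 30)
  r <- pooled_t_test(g, g)
  expect_equal(r$t, 0)
  expect_equal(r$ci_lo, -r$ci_hi)
  expect_equal(r$df, 58)
})

test_that("published summary rows recompute to the printed statistics", {
  # reduced-sentence style row: means 2.95/4.08, sds 2.48/2.57, n 99/99
  r <- pooled_t_test(group_summary(mean = 2.95, sd = 2.48, n = 99),
                     group_summary(mean = 4.08, sd = 2.57, n = 99))
  expect_equal(r$df, 196)
  expect_lt(abs(r$t - (-3.15)), 0.005)
  expect_lt(abs(r$ci_lo - (-1.84)), 0.005)
  expect_lt(abs(r$ci_hi - (-0.42)), 0.005)
  # MLU-style row
  r2 <- pooled_t_test(group_summary(mean = 2.65, sd = 1.70, n = 99),
                      group_summary(mean = 4.03, sd = 2.25, n = 99))
  expect_lt(abs(r2$t - (-4.86)), 0.01)
})

test_that("pooled t is antisymmetric under group exchange", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(20, 1); y <- rnorm(25, 0, 2)
    a <- pooled_t_test(x, y); b <- pooled_t_test(y, x)
    expect_equal(a$t, -b$t)
    expect_equal(a$ci_lo, -b$ci_hi)
    expect_equal(a$p, b$p)
  }
})

test_that("p matches a numeric t-distribution integral to 1e-10", {
  for (tv in c(0.5, 1.7, 3.15, 4.86)) {
    for (df in c(10, 196)) {
      n <- (df + 2) / 2
      s <- sqrt(n / 2)            # makes the standard error exactly 1
      r <- pooled_t_test(group_summary(mean = tv, sd = s, n = n),
                         group_summary(mean = 0, sd = s, n = n))
      expect_equal(r$t, tv, tolerance = 1e-12)
      p_int <- 2 * stats::integrate(function(u) stats::dt(u, df), tv, Inf,
                                    rel.tol = 1e-13)$value
      expect_equal(r$p, p_int, tolerance = 1e-10)
    }
  }
})

test_that("degenerate variances behave per contract", {
  z <- group_summary(mean = 1, sd = 0, n = 5)
  expect_equal(pooled_t_test(z, z)$t, 0)
  z2 <- group_summary(mean = 2, sd = 0, n = 5)
  expect_error(pooled_t_test(z, z2), "degenerate")
})

test_that("Mann-Whitney U agrees with exhaustive enumeration on small samples", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  set.seed(5)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    r <- mann_whitney_u(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, mw_brute_force(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation is sane for larger samples", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(35, 1.2)
  r <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$U, unname(ref$statistic))
  expect_equal(r$p, ref$p.value, tolerance = 1e-6)
  # identical samples sit at the midpoint under midranks
  xx <- rep(1:10, 3)
  expect_equal(mann_whitney_u(xx, xx)$U, length(xx)^2 / 2)
})

test_that("logistic IRLS matches glm on a reference fit", {
  set.seed(12)
  n <- 150
  X <- cbind(age = rnorm(n, 70, 8), f1 = rnorm(n), f2 = rnorm(n))
  eta <- -0.5 + 0.04 * (X[, 1] - 70) + 0.9 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_mlr(X, y)
  ref <- stats::glm(y ~ X, family = binomial())
  expect_true(fit$converged)
  expect_equal(fit$coefficients$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_equal(fit$coefficients$wald_x2,
               (fit$coefficients$beta / fit$coefficients$se)^2)
})

test_that("a single binary predictor recovers the log cross-product ratio", {
  # 2x2 table: exposed cases 30, exposed controls 10, unexposed 20/40
  x <- c(rep(1, 40), rep(0, 60))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  fit <- fit_mlr(matrix(x, ncol = 1, dimnames = list(NULL, "exp")), y)
  expect_equal(fit$coefficients$beta[2], log((30 * 40) / (10 * 20)),
               tolerance = 1e-7)
})

test_that("odds-ratio arithmetic is exp(beta) with 1.96 normal bounds", {
  o <- odds_ratios(c(0, 0.185), c(1, 0.083))
  expect_equal(o$or, c(1, exp(0.185)))
  expect_equal(o$or_lo[2], exp(0.185 - 1.96 * 0.083))
  expect_equal(o$or_hi[2], exp(0.185 + 1.96 * 0.083))
})

test_that("mlr recovers a known beta within 3 SE and flags separation", {
  set.seed(21)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
  fit <- fit_mlr(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  b <- fit$coefficients[2, ]
  expect_lt(abs(b$beta - 0.8), 3 * b$se)
  # quasi-complete separation warns
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  expect_warning(fit_mlr(matrix(xs, ncol = 1, dimnames = list(NULL, "x")), ys),
                 "separation")
  # constant columns are refused
  expect_error(fit_mlr(cbind(k = rep(1, 10), x = rnorm(10)),
                       rep(c(0, 1), 5)), "constant")
})

test_that("screen_features mirrors the per-feature summary-table shape", {
  co <- generate_cohort(cohort_config(n_per_group = 12), seed = 31)
  ft <- cohort_feature_table(co)
  scr <- screen_features(ft)
  expect_equal(scr$feature, intersect(feature_names_23(), names(ft)))
  expect_true(all(scr$df == 22))
  expect_true(all(scr$p >= 0 & scr$p <= 1))
  expect_true(all(scr$ci_lo <= scr$ci_hi))
  i <- which(scr$feature == "utterances")
  byhand <- pooled_t_test(ft$utterances[ft$group == "PrADG"],
                          ft$utterances[ft$group == "HEG"])
  expect_equal(scr$t[i], byhand$t)
})
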