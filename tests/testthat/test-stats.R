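# Statistical battery: closed forms, algebraic identities, simulation checks

test_that("Shapiro-Wilk gate rejects constants, keeps its level, and detects skew", {
  expect_error(shapiro_gate(rep(3, 10)), "constant")

  set.seed(19)
  rejections <- sum(replicate(500, {
    suppressWarnings(shapiro_gate(rnorm(5000))$p) < 0.05
  }))
  se <- sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(rejections / 500 - 0.05), 3 * se)

  power <- mean(replicate(300, {
    suppressWarnings(shapiro_gate(rexp(100))$p) < 0.05
  }))
  expect_gte(power, 0.99)

  expect_warning(shapiro_gate(rexp(100)), "parametric")
})

test_that("t test honours identity, degenerate and algebraic-identity cases", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  p <- t_test(a, a, paired = TRUE)
  expect_equal(p$statistic, 0)
  expect_equal(p$p, 1)

  expect_error(t_test(1:4, 1:5, paired = TRUE), "equal length")

  dz <- t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(dz$p, 1)
  expect_equal(t_test(c(2, 2, 2), c(3, 3, 3))$p, 0)

  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(8 + i); y <- rnorm(11, 0.4)
    tt <- t_test(x, y)
    av <- oneway_anova(list(x, y))
    expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(av$p, tt$p, tolerance = 1e-10)
  }
})

test_that("pooled t test agrees with a permutation test for a moderate effect", {
  set.seed(77)
  x <- rnorm(15); y <- rnorm(15, 0.9)
  tt <- t_test(x, y)
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  # pooled-variance t is monotone in |mean difference| at fixed group sizes,
  # so permuting the mean difference is an exact permutation test of t
  perm <- replicate(2e4, {
    idx <- sample(30, 15)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- (1 + sum(perm >= obs)) / (2e4 + 1)
  expect_lt(abs(p_perm - tt$p), 3 * sqrt(tt$p * (1 - tt$p) / 2e4) + 0.005)
})

test_that("chi-square matches the direct O/E formula and its boundary cases", {
  even <- chi_square_counts(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)
  expect_lt(chi_square_counts(matrix(c(20, 0, 0, 20), 2))$p, 1e-6)
  expect_error(chi_square_counts(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi_square_counts(matrix(c(1.5, 2, 3, 4), 2)), "integer")

  set.seed(6)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_counts(tab)$statistic, sum((tab - E)^2 / E),
                 tolerance = 1e-12)
  }
})

test_that("ANOVA from sufficient statistics reproduces the raw computation", {
  g0 <- list(rep(1, 5), rep(1, 6))
  z <- oneway_anova(g0)
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)

  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(sample(5:20, 1), j * 0.3))
    raw <- oneway_anova(g)
    suf <- summary_anova(vapply(g, mean, 1), vapply(g, sd, 1),
                         vapply(g, length, 1L))
    expect_equal(raw$statistic, suf$statistic, tolerance = 1e-10)
    expect_equal(raw$p, suf$p, tolerance = 1e-10)
    expect_identical(raw$df, suf$df)
    expect_true(raw$p >= 0 && raw$p <= 1)
  }
})

test_that("post hoc adjustments: Bonferroni arithmetic, Tukey dominance, null behaviour", {
  set.seed(25)
  g <- lapply(1:4, function(i) rnorm(10))
  pb <- posthoc(g, "bonferroni")
  expect_equal(pb$adj_p, pmin(1, pb$raw_p * 6), tolerance = 1e-12)
  expect_true(all(pb$adj_p >= pb$raw_p))

  same <- posthoc(lapply(1:3, function(i) c(5, 5.01, 4.99, 5.02, 4.97)),
                  "tukey")
  expect_false(any(same$significant))

  # with one shifted group, both adjustments flag the same pairs, and the
  # studentized-range adjustment is no more conservative than Bonferroni in
  # the vast majority of random draws
  dominated <- 0; total <- 0; agree <- TRUE
  for (i in 1:200) {
    g <- c(lapply(1:3, function(j) rnorm(9)), list(rnorm(9, 4)))
    pt_ <- posthoc(g, "tukey"); pb_ <- posthoc(g, "bonferroni")
    dominated <- dominated + sum(pt_$adj_p <= pb_$adj_p + 1e-12)
    total <- total + nrow(pt_)
    big <- pt_$group_2 == "g4"    # the large-effect pairs
    if (!identical(pt_$significant[big], pb_$significant[big])) agree <- FALSE
  }
  expect_gte(dominated / total, 0.95)
  expect_true(agree)
})

test_that("percentage difference follows the reference-mean convention", {
  expect_equal(percent_difference(100, 80), 20)
  expect_equal(percent_difference(55.5, 55.5), 0)
  expect_equal(percent_difference(1419.39, 929.46), 34.52, tolerance = 1e-3)
  expect_error(percent_difference(0, 5), "positive")
})

test_that("ICC matches aov-derived mean squares and its closed forms", {
  x <- rnorm(12, 100, 20)
  expect_equal(icc(cbind(x, x), "icc2_1"), 1)
  expect_equal(icc(cbind(x, x), "icc3_1"), 1)
  shifted <- cbind(x, x + 15)
  expect_equal(icc(shifted, "icc3_1"), 1)
  expect_lt(icc(shifted, "icc2_1"), 1)
  expect_error(icc(matrix(5, 6, 2), "icc2_1"), "between-subject")

  set.seed(44)
  for (i in 1:100) {
    n <- sample(5:15, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 50, 10), n, k)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    expect_equal(icc(m, "icc2_1"),
                 (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
                 tolerance = 1e-10)
    expect_equal(icc(m, "icc3_1"),
                 (msr - mse) / (msr + (k - 1) * mse),
                 tolerance = 1e-10)
  }
})

test_that("Dahlberg error: closed forms and invariances", {
  x <- rnorm(9)
  expect_equal(dahlberg(x, x), 0)
  expect_equal(dahlberg(x, x + 3), 3 / sqrt(2))
  expect_equal(dahlberg(c(0, 0), c(2, 4)), sqrt(5))
  y <- x + rnorm(9)
  expect_equal(dahlberg(x, y), dahlberg(y, x))
  o <- sample(9)
  expect_equal(dahlberg(x[o], y[o]), dahlberg(x, y))
  expect_error(dahlberg(numeric(0), numeric(0)))
})

test_that("required sample size matches an independent power scan and is monotone", {
  expect_identical(required_n_two_means(0, 1, 100, 1), 2L)
  expect_error(required_n_two_means(5, 1, 5, 1), "effect")

  # independent oracle: scan power.t.test's power over n
  oracle <- function(d, alpha = 0.05, power = 0.95) {
    for (n in 2:1000) {
      if (stats::power.t.test(n = n, delta = d, sd = 1,
                              sig.level = alpha)$power >= power) return(n)
    }
  }
  for (d in c(0.5, 1.0, 1.5)) {
    expect_identical(required_n_two_means(0, 1, d, 1), oracle(d))
  }

  n1 <- required_n_two_means(100, 10, 110, 10)
  n2 <- required_n_two_means(100, 10, 120, 10)
  expect_gte(n1, n2)                     # non-increasing in effect
  n3 <- required_n_two_means(100, 20, 110, 20)
  expect_gte(n3, n1)                     # non-decreasing in SD
  n4 <- required_n_two_means(100, 10, 110, 10, power = 0.8)
  expect_gte(n1, n4)                     # non-decreasing in power

  # with reference-study condyle values no convention reproduces fewer than
  # 24 subjects per group
  expect_identical(required_n_two_means(1007.82, 384.27, 1424.69, 417.64), 26L)
  expect_identical(required_n_two_means(1007.82, 384.27, 1424.69, 417.64,
                                        sd_mode = "group1"), 24L)
})
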