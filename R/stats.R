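# The study's statistical battery: normality gate, t tests, chi-square,
# one-way ANOVA (raw and from sufficient statistics), Tukey/Bonferroni post
# hoc comparisons, percentage differences, ICC, Dahlberg method error and
# a-priori sample size from noncentral-t power.

test_result <- function(statistic, df, p, method, groups = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(min(1, max(0, p))), method = method,
                 groups = groups),
            class = "mv_test")
}

#' @export
print.mv_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p))
  if (!is.null(x$groups)) print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test; when normality is rejected at `alpha` the
#' pipeline still proceeds parametrically (as the source analysis did) but a
#' warning is logged.
#'
#' @param values numeric sample, `3 <= n <= 5000`, non-constant.
#' @param alpha significance level of the gate.
#' @return An `mv_test` with the W statistic.
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000",
                              call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("normality test undefined for constant input", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  if (sw$p.value < alpha) {
    warning(sprintf("normality rejected (W = %.3f, p = %.3g); proceeding parametric",
                    sw$statistic, sw$p.value))
  }
  test_result(sw$statistic, n, sw$p.value, "shapiro_wilk")
}

group_summary <- function(...) {
  gs <- list(...)
  data.frame(n = vapply(gs, length, 1L),
             mean = vapply(gs, mean, 1),
             sd = vapply(gs, stats::sd, 1))
}

#' Two-tailed t test
#'
#' Independent (pooled variance by default, Welch optional) or paired
#' two-tailed t test. Degenerate inputs follow fixed conventions: zero
#' variance everywhere with equal means gives `t = 0, p = 1`; zero variance
#' with unequal means gives `p = 0`.
#'
#' @param a,b numeric samples (equal length when `paired`).
#' @param paired logical.
#' @param var_equal pooled-variance assumption for the independent test.
#' @return An `mv_test`.
#' @export
t_test <- function(a, b, paired = FALSE, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (paired && length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  method <- if (paired) "paired_t" else if (var_equal) "pooled_t" else "welch_t"
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    eq <- if (paired) mean(a - b) == 0 else mean(a) == mean(b)
    df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    return(test_result(if (eq) 0 else Inf, df, if (eq) 1 else 0, method,
                       group_summary(a, b)))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
  test_result(tt$statistic, tt$parameter, tt$p.value, method,
              group_summary(a, b))
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' @param table 2 x 2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correct apply the Yates continuity correction (off by default).
#' @return An `mv_test` with df = 1.
#' @export
chi_square_counts <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square undefined with a zero margin", call. = FALSE)
  }
  # small expected counts are routine in these sex tables; the Pearson
  # statistic is still the emulated protocol, so the approximation warning
  # is silenced
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  test_result(ct$statistic, ct$parameter, ct$p.value,
              if (correct) "chi_square_yates" else "chi_square")
}

#' One-way ANOVA
#'
#' `oneway_anova()` takes raw samples; `summary_anova()` computes the
#' identical F from sufficient statistics (group means, SDs, sizes), as
#' needed when only published summaries are available.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return An `mv_test` with `df = c(k - 1, N - k)`.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  if (stats::sd(unlist(groups)) == 0) {
    k <- length(groups); N <- length(unlist(groups))
    return(test_result(0, c(k - 1, N - k), 1, "oneway_anova",
                       do.call(group_summary, groups)))
  }
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ow <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  test_result(ow$statistic, ow$parameter, ow$p.value, "oneway_anova",
              do.call(group_summary, groups))
}

#' @rdname oneway_anova
#' @param means,sds,ns group means, standard deviations and sizes.
#' @export
summary_anova <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns),
            length(means) >= 2, all(ns >= 2))
  k <- length(means)
  N <- sum(ns)
  gm <- sum(ns * means) / N
  msb <- sum(ns * (means - gm)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  if (msw == 0) {
    if (msb == 0) return(test_result(0, c(k - 1, N - k), 1, "summary_anova"))
    return(test_result(Inf, c(k - 1, N - k), 0, "summary_anova"))
  }
  f <- msb / msw
  test_result(f, c(k - 1, N - k),
              stats::pf(f, k - 1, N - k, lower.tail = FALSE),
              "summary_anova",
              data.frame(n = ns, mean = means, sd = sds))
}

#' Post hoc pairwise comparisons after one-way ANOVA
#'
#' All pairwise mean differences with adjusted p values, using the pooled
#' within-group mean square (error df `N - k`). `"bonferroni"` multiplies
#' the pairwise pooled-t p values by the number of pairs `k(k-1)/2`, capped
#' at 1; `"tukey"` uses the studentized-range distribution.
#'
#' @param groups list of numeric samples, optionally named.
#' @param method `"bonferroni"` (default) or `"tukey"`.
#' @param alpha significance level for the `significant` flag.
#' @return A data frame of class `posthoc_table`: one row per pair with
#'   `mean_diff`, `raw_p`, `adj_p`, `significant`.
#' @export
posthoc <- function(groups, method = c("bonferroni", "tukey"), alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  N <- sum(ns)
  mse <- sum((ns - 1) * vapply(groups, stats::var, 1)) / (N - k)
  df <- N - k
  npairs <- k * (k - 1) / 2
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      diff <- means[i] - means[j]
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      if (se == 0) {
        raw <- if (diff == 0) 1 else 0
        adj <- raw
      } else {
        tval <- diff / se
        raw <- 2 * stats::pt(-abs(tval), df)
        adj <- switch(method,
          bonferroni = min(1, raw * npairs),
          tukey = stats::ptukey(abs(tval) * sqrt(2), k, df,
                                lower.tail = FALSE))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_1 = nm[i], group_2 = nm[j], mean_diff = unname(diff),
        raw_p = unname(raw), adj_p = unname(adj),
        significant = unname(adj < alpha))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  attr(out, "df_error") <- df
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Percentage difference between two group means
#'
#' `100 * (mean_ref - mean_other) / mean_ref`, with the reference taken as
#' the first (by convention, larger) group. The denominator convention is
#' documented rather than inferred: the source table is internally
#' inconsistent on this point.
#'
#' @param mean_ref reference mean (> 0).
#' @param mean_other comparison mean.
#' @return Percentage difference (positive when the reference is larger).
#' @export
percent_difference <- function(mean_ref, mean_other) {
  if (mean_ref <= 0) stop("reference mean must be positive", call. = FALSE)
  100 * (mean_ref - mean_other) / mean_ref
}

#' Intraclass correlation coefficient
#'
#' Single-rater ICC from the two-way ANOVA mean squares of a subjects x
#' raters matrix. `icc2_1` is the two-way random-effects absolute-agreement
#' form ICC(2,1) (default: raters are interchangeable and systematic rater
#' offsets count against agreement); `icc3_1` is the two-way mixed
#' consistency form ICC(3,1).
#'
#' @param ratings numeric matrix, subjects in rows (>= 5), raters in columns
#'   (>= 2), no missing cells.
#' @param model `"icc2_1"` or `"icc3_1"`.
#' @return The ICC value (<= 1).
#' @export
icc <- function(ratings, model = c("icc2_1", "icc3_1")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 5, k >= 2, all(is.finite(ratings)))
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < .Machine$double.eps * max(1, grand^2)) {
    stop("ICC undefined: no between-subject variance", call. = FALSE)
  }
  switch(model,
    icc2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    icc3_1 = (msr - mse) / (msr + (k - 1) * mse))
}

#' Dahlberg method error
#'
#' `sqrt(sum((x1 - x2)^2) / (2 n))` over n repeated-measurement pairs -- the
#' classic cephalometric random-error statistic, in the unit of the
#' measurements (here mm^3).
#'
#' @param x1,x2 paired repeated measurements (equal length, n >= 1).
#' @return The Dahlberg error (>= 0).
#' @export
dahlberg <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 1)
  sqrt(sum((x1 - x2)^2) / (2 * length(x1)))
}

#' A-priori sample size for a two-sample t test
#'
#' Smallest integer n per group such that the two-sample t test (noncentral
#' t with `ncp = d * sqrt(n / 2)`, `df = 2 n - 2`) reaches the target power
#' at level `alpha`. The standardised effect `d` uses the pooled SD
#' `sqrt((sd1^2 + sd2^2) / 2)` by default; G*Power-style runs sometimes
#' standardise by a single group's SD, hence `sd_mode`.
#'
#' @param m1,sd1,m2,sd2 group means and SDs (`m1 != m2`, SDs > 0).
#' @param alpha type-I error probability.
#' @param power target power in (alpha, 1).
#' @param tails 1 or 2.
#' @param sd_mode `"pooled"`, `"group1"` or `"group2"`.
#' @param n_max search cap.
#' @return Required n per group (integer >= 2).
#' @export
required_n_two_means <- function(m1, sd1, m2, sd2, alpha = 0.05,
                                 power = 0.95, tails = 2,
                                 sd_mode = c("pooled", "group1", "group2"),
                                 n_max = 1e6) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(sd1 > 0, sd2 > 0, alpha > 0, alpha < 1, power > alpha, power < 1,
            tails %in% c(1, 2))
  if (m1 == m2) stop("zero effect size: target power unreachable", call. = FALSE)
  sd_eff <- switch(sd_mode,
                   pooled = sqrt((sd1^2 + sd2^2) / 2),
                   group1 = sd1, group2 = sd2)
  d <- abs(m1 - m2) / sd_eff
  for (n in 2:n_max) {
    if (two_sample_t_power(d, n, alpha, tails) >= power) return(n)
  }
  stop("required n exceeds search cap", call. = FALSE)
}

# power of the two-sample t test at n per group
two_sample_t_power <- function(d, n, alpha, tails = 2) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tcrit <- stats::qt(1 - alpha / tails, df)
  pw <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) pw <- pw + stats::pt(-tcrit, df, ncp = ncp)
  pw
}
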