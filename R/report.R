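# Orchestration of the study-level analysis: compatibility of the arms,
# within-arm side contrasts, the four-group ANOVA per segment with post hoc
# comparisons, mean/percentage differences, and the reliability report.

#' Full study report over the three arms
#'
#' Reproduces the structure of the study's result tables from three cohort
#' tables:
#' \describe{
#'   \item{compatibility}{JIA (unilateral + bilateral) vs control: t tests
#'     for age, ANB and intermaxillary divergence, chi-square for sex.}
#'   \item{side_contrasts}{per segment: paired t of affected vs unaffected
#'     side (unilateral arm) and right vs left (bilateral and control arms).}
#'   \item{anova}{per segment, the four groups unilateral-affected,
#'     unilateral-unaffected, bilateral (per-subject side average) and
#'     control (side average), with post hoc pairwise comparisons; the total
#'     mandible compares the three arms.}
#'   \item{differences}{pairwise mean differences with percentage
#'     differences relative to the larger group mean.}
#' }
#'
#' A Shapiro-Wilk gate is run per analysis group; failures warn but do not
#' switch the pipeline to nonparametric tests (the parametric path is part
#' of the emulated protocol).
#'
#' @param cohorts named list with elements `uni_jia`, `bil_jia`, `control`
#'   ([simulate_cohort()] tables or equivalent).
#' @param alpha significance level.
#' @param posthoc_method `"bonferroni"` or `"tukey"`.
#' @param normality_gate run the Shapiro-Wilk gate (set `FALSE` to silence
#'   it in simulation loops).
#' @return An object of class `study_report`.
#' @export
full_study_report <- function(cohorts, alpha = 0.05,
                              posthoc_method = c("bonferroni", "tukey"),
                              normality_gate = TRUE) {
  posthoc_method <- match.arg(posthoc_method)
  need <- c("uni_jia", "bil_jia", "control")
  if (!all(need %in% names(cohorts))) {
    stop("cohorts must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  uni <- cohorts$uni_jia; bil <- cohorts$bil_jia; ctl <- cohorts$control

  subj_cov <- function(co) unique(co[, c("subject", "age", "sex", "anb",
                                         "divergence")])
  cu <- subj_cov(uni); cb <- subj_cov(bil); cc <- subj_cov(ctl)
  jia <- rbind(cu, cb)
  sex_tab <- rbind(table(factor(jia$sex, c("M", "F"))),
                   table(factor(cc$sex, c("M", "F"))))
  compatibility <- list(
    age = t_test(jia$age, cc$age),
    anb = t_test(jia$anb, cc$anb),
    divergence = t_test(jia$divergence, cc$divergence),
    sex = chi_square_counts(sex_tab))

  seg_vals <- function(co, seg) co[co$segment == seg, ]
  side_pair <- function(co, seg, by_affected) {
    d <- seg_vals(co, seg)
    d <- d[order(d$subject), ]
    if (by_affected) {
      list(a = d$volume_mm3[d$affected], b = d$volume_mm3[!d$affected])
    } else {
      list(a = d$volume_mm3[d$side == "R"], b = d$volume_mm3[d$side == "L"])
    }
  }
  side_avg <- function(co, seg) {
    d <- seg_vals(co, seg)
    as.numeric(tapply(d$volume_mm3, d$subject, mean))
  }

  segments <- c("hemimandible", "condyle", "ramus", "hemibody")
  side_contrasts <- list()
  anova_tables <- list()
  differences <- list()
  for (seg in segments) {
    pu <- side_pair(uni, seg, TRUE)
    pb <- side_pair(bil, seg, FALSE)
    pc <- side_pair(ctl, seg, FALSE)
    side_contrasts[[seg]] <- list(
      uni_aff_vs_unaff = t_test(pu$a, pu$b, paired = TRUE),
      bil_right_vs_left = t_test(pb$a, pb$b, paired = TRUE),
      ctrl_right_vs_left = t_test(pc$a, pc$b, paired = TRUE))

    groups <- list(uni_aff = pu$a, uni_unaff = pu$b,
                   bil = side_avg(bil, seg), ctrl = side_avg(ctl, seg))
    if (normality_gate) {
      for (gnm in names(groups)) {
        try(shapiro_gate(groups[[gnm]], alpha), silent = FALSE)
      }
    }
    anova_tables[[seg]] <- list(
      anova = oneway_anova(groups),
      posthoc = posthoc(groups, method = posthoc_method, alpha = alpha))

    m <- vapply(groups, mean, 1)
    pairs <- utils::combn(names(groups), 2)
    differences[[seg]] <- do.call(rbind, lapply(seq_len(ncol(pairs)),
      function(i) {
        g1 <- pairs[1, i]; g2 <- pairs[2, i]
        ref <- if (m[g1] >= m[g2]) g1 else g2
        oth <- if (ref == g1) g2 else g1
        data.frame(group_1 = g1, group_2 = g2,
                   mean_diff = unname(m[g1] - m[g2]),
                   reference = ref,
                   pct_diff = percent_difference(m[[ref]], m[[oth]]))
      }))
  }

  totals <- list(
    uni = seg_vals(uni, "total_mandible")$volume_mm3,
    bil = seg_vals(bil, "total_mandible")$volume_mm3,
    ctrl = seg_vals(ctl, "total_mandible")$volume_mm3)
  total_anova <- list(anova = oneway_anova(totals),
                      posthoc = posthoc(totals, method = posthoc_method,
                                        alpha = alpha))

  structure(list(alpha = alpha, posthoc_method = posthoc_method,
                 compatibility = compatibility,
                 side_contrasts = side_contrasts,
                 anova = anova_tables,
                 total_mandible = total_anova,
                 differences = differences,
                 group_sizes = c(uni_jia = nrow(cu), bil_jia = nrow(cb),
                                 control = nrow(cc))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> alpha =", x$alpha, ", post hoc:", x$posthoc_method, "\n")
  cat("group sizes:", paste(names(x$group_sizes), x$group_sizes,
                            sep = " = ", collapse = ", "), "\n")
  cat("\nCompatibility (JIA vs control):\n")
  for (nm in names(x$compatibility)) {
    t <- x$compatibility[[nm]]
    cat(sprintf("  %-11s p = %.3f\n", nm, t$p))
  }
  cat("\nFour-group ANOVA per segment:\n")
  for (seg in names(x$anova)) {
    a <- x$anova[[seg]]$anova
    cat(sprintf("  %-13s F(%g, %g) = %.2f, p = %.4g\n", seg,
                a$df[1], a$df[2], a$statistic, a$p))
  }
  a <- x$total_mandible$anova
  cat(sprintf("  %-13s F(%g, %g) = %.2f, p = %.4g\n", "total", a$df[1],
              a$df[2], a$statistic, a$p))
  invisible(x)
}

mv_test_to_list <- function(t) {
  list(statistic = t$statistic, df = t$df, p = t$p, method = t$method,
       groups = if (is.null(t$groups)) NULL else as.list(t$groups))
}

#' Serialize a study report to a plain list / JSON
#'
#' @param report a [full_study_report()] result.
#' @return A plain nested list mirroring the report (for
#'   `report_to_json()`).
#' @export
report_to_list <- function(report) {
  ph_to_list <- function(p) {
    l <- as.list(as.data.frame(p))
    l$method <- attr(p, "method")
    l
  }
  list(
    alpha = report$alpha,
    posthoc_method = report$posthoc_method,
    group_sizes = as.list(report$group_sizes),
    compatibility = lapply(report$compatibility, mv_test_to_list),
    side_contrasts = lapply(report$side_contrasts,
                            function(s) lapply(s, mv_test_to_list)),
    anova = lapply(report$anova, function(a)
      list(anova = mv_test_to_list(a$anova), posthoc = ph_to_list(a$posthoc))),
    total_mandible = list(
      anova = mv_test_to_list(report$total_mandible$anova),
      posthoc = ph_to_list(report$total_mandible$posthoc)),
    differences = lapply(report$differences, as.list)
  )
}

#' @rdname report_to_list
#' @param path output JSON path.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Reliability report: per-segment ICC and Dahlberg error
#'
#' Compares two measurement sessions of the same subjects (e.g. repeated
#' landmark digitisation and re-segmentation).
#'
#' @param rep1,rep2 data frames with columns `subject`, `segment`,
#'   `volume_mm3` (matching subject/segment sets).
#' @param model ICC model, see [icc()].
#' @return Data frame with columns `segment`, `n`, `icc`, `dahlberg_mm3`.
#' @export
reliability_report <- function(rep1, rep2, model = "icc2_1") {
  stopifnot(all(c("subject", "segment", "volume_mm3") %in% names(rep1)),
            all(c("subject", "segment", "volume_mm3") %in% names(rep2)))
  segs <- sort(unique(rep1$segment))
  out <- lapply(segs, function(seg) {
    a <- rep1[rep1$segment == seg, ]
    b <- rep2[rep2$segment == seg, ]
    a <- a[order(a$subject), ]
    b <- b[order(b$subject), ]
    if (!identical(a$subject, b$subject)) {
      stop("subject sets differ for segment ", seg, call. = FALSE)
    }
    data.frame(segment = seg, n = nrow(a),
               icc = icc(cbind(a$volume_mm3, b$volume_mm3), model = model),
               dahlberg_mm3 = dahlberg(a$volume_mm3, b$volume_mm3))
  })
  do.call(rbind, out)
}
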