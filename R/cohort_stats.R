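# Reliability metrics (CV%, ICC%), three-group comparisons (one-way ANOVA,
# pairwise tests, percent differences), 95% reference ranges, and the
# cohort comparison report.

#' Within-replicate coefficient of variation (CV%)
#'
#' Random differences between replicates as a percentage of the grand mean:
#' per-subject replicate variance `s_i^2 = sum (x - subject mean)^2 / (k-1)`,
#' `CV% = 100 * sqrt(mean_i s_i^2) / grand mean`.
#'
#' @param values numeric replicate readings.
#' @param subject subject id for each reading.
#' @return CV in percent.
#' @export
cv_percent <- function(values, subject) {
  stopifnot(length(values) == length(subject))
  sp <- split(values, subject)
  sp <- sp[vapply(sp, length, 0L) >= 2L]
  if (length(sp) == 0L) stop("need at least one subject with >= 2 replicates")
  gm <- mean(unlist(sp))
  if (abs(gm) < 1e-12) stop("grand mean is zero; CV undefined")
  s2 <- vapply(sp, stats::var, 0)
  100 * sqrt(mean(s2)) / gm
}

#' Intraclass correlation coefficient (ICC%), two-way random, absolute
#' agreement, single measures
#'
#' The between-subject variability as a percentage of the total variation
#' among readings: ICC(2,1) x 100 from the two-way mean squares
#' (subjects x raters, one reading per cell).
#'
#' @param values numeric readings.
#' @param subject subject id per reading.
#' @param rater rater id per reading.
#' @return ICC in percent.
#' @export
icc_percent <- function(values, subject, rater) {
  subject <- factor(subject); rater <- factor(rater)
  n <- nlevels(subject); k <- nlevels(rater)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters")
  if (length(values) != n * k)
    stop("expected one reading per subject x rater cell")
  m <- tapply(values, list(subject, rater), mean)
  if (anyNA(m)) stop("missing subject x rater cells")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((m - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (abs(denom) < 1e-300) stop("zero total variance; ICC undefined")
  100 * (MSR - MSE) / denom
}

#' One-way fixed-effects ANOVA on raw values
#'
#' @param values numeric observations.
#' @param group group label per observation (>= 2 groups, each n >= 2).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  ns <- tabulate(group)
  if (k < 2L || any(ns < 2L)) stop("need >= 2 groups with n >= 2 each")
  N <- length(values)
  gm <- mean(values)
  means <- tapply(values, group, mean)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[group])^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw <= 1e-300) {
    if (ssb <= 1e-300) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = stats::pf(F, df1, df2,
                                                  lower.tail = FALSE))
}

#' One-way ANOVA from per-group summaries
#'
#' Recovers the classic F test from printed group sizes, means and SDs:
#' `SSB = sum n_i (mean_i - grand mean)^2`, `SSW = sum (n_i - 1) SD_i^2`.
#'
#' @param n,mean,sd per-group summaries (equal-length vectors, >= 2 groups).
#' @return list with `F`, `df1`, `df2`, `p`, and `zero_within` flag when
#'   SSW = 0 with SSB > 0.
#' @export
anova_from_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(mean) == length(sd),
            length(n) >= 2L, all(n >= 2L))
  N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- length(n) - 1L; df2 <- N - length(n)
  if (ssw <= 1e-300) {
    if (ssb <= 1e-300)
      return(list(F = 0, df1 = df1, df2 = df2, p = 1, zero_within = TRUE))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, zero_within = TRUE))
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE), zero_within = FALSE)
}

#' Signed percent difference of a comparison mean versus a reference mean
#'
#' @param reference reference group mean (non-zero).
#' @param comparison comparison group mean.
#' @return `100 * (comparison - reference) / reference`.
#' @export
percent_difference <- function(reference, comparison) {
  if (any(abs(reference) < 1e-300)) stop("reference mean is zero")
  100 * (comparison - reference) / reference
}

#' Pairwise two-sample tests between all group pairs
#'
#' @param values numeric observations.
#' @param group group labels.
#' @param method `"welch"` (default) or `"pooled"` two-sample t test.
#' @param bonferroni multiply p by the number of pairs (capped at 1).
#' @return data.frame with `group1`, `group2`, `t`, `df`, `p`.
#' @export
pairwise_tests <- function(values, group, method = c("welch", "pooled"),
                           bonferroni = FALSE) {
  method <- match.arg(method)
  group <- factor(group)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2L)
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    t = NA_real_, df = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    x <- values[group == pairs[1L, i]]
    y <- values[group == pairs[2L, i]]
    if (length(x) < 2L || length(y) < 2L)
      stop("each group needs n >= 2 for pairwise tests")
    tt <- stats::t.test(x, y, var.equal = (method == "pooled"))
    out$t[i] <- unname(tt$statistic)
    out$df[i] <- unname(tt$parameter)
    out$p[i] <- tt$p.value
  }
  if (bonferroni) out$p <- pmin(out$p * ncol(pairs), 1)
  out
}

#' 95% reference range by two methods
#'
#' @param values numeric sample.
#' @param method `"percentile"` (empirical 2.5th/97.5th percentiles, linear
#'   interpolation; needs n >= 20) or `"normal"` (mean +/- 1.96 SD).
#' @return named vector `c(low, high)`; the normal method on n < 20 carries
#'   attribute `small_sample = TRUE`.
#' @export
reference_range_95 <- function(values, method = c("percentile", "normal")) {
  method <- match.arg(method)
  n <- length(values)
  if (method == "percentile") {
    if (n < 20L)
      stop("percentile reference range needs n >= 20; use method = 'normal'")
    q <- stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
    return(c(low = q[1L], high = q[2L]))
  }
  m <- mean(values); s <- stats::sd(values)
  out <- c(low = m - 1.96 * s, high = m + 1.96 * s)
  if (n < 20L) attr(out, "small_sample") <- TRUE
  out
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
normality_test <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) < 1e-300) stop("constant sample; normality undefined")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Reliability report (CV% and ICC%) from a long rater table
#'
#' CV% uses the replicates of the first rater; ICC% uses the per-rater
#' subject averages of the first two raters.
#'
#' @param table long data.frame as produced by [simulate_raters()]
#'   (columns `subject`, `rater`, `replicate`, `parameter`, `value`).
#' @return data.frame with one row per parameter: `parameter`, `cv_percent`,
#'   `icc_percent`, `n_subjects`, `n_raters`, `n_replicates`.
#' @export
reliability_report <- function(table) {
  need <- c("subject", "rater", "replicate", "parameter", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  params <- unique(table$parameter)
  raters <- sort(unique(table$rater))
  out <- lapply(params, function(p) {
    d <- table[table$parameter == p, ]
    d1 <- d[d$rater == raters[1L], ]
    cv <- if (max(table(d1$subject)) >= 2L)
      cv_percent(d1$value, d1$subject) else NA_real_
    icc <- NA_real_
    if (length(raters) >= 2L) {
      d2 <- d[d$rater %in% raters[1:2], ]
      ag <- stats::aggregate(value ~ subject + rater, data = d2, FUN = mean)
      icc <- icc_percent(ag$value, ag$subject, ag$rater)
    }
    data.frame(parameter = p, cv_percent = cv, icc_percent = icc,
               n_subjects = length(unique(d$subject)),
               n_raters = length(raters),
               n_replicates = max(d$replicate))
  })
  do.call(rbind, out)
}

#' Build the three-group comparison report
#'
#' Per parameter: group summaries (n, mean, SD, 95% reference range by both
#' the percentile and the normal method), Shapiro-Wilk normality flags, the
#' overall one-way ANOVA, unadjusted pairwise tests, and signed percent
#' differences (II vs NII, II vs control, NII vs control when those groups
#' are present; otherwise all ordered pairs).
#'
#' @param cohort data.frame with a `group` column and one numeric column per
#'   parameter (as from [simulate_cohort()]).
#' @param parameters parameter columns to analyze; defaults to the eight
#'   acromial parameters present in the cohort.
#' @param pairwise_method passed to [pairwise_tests()].
#' @param bonferroni passed to [pairwise_tests()].
#' @return object of class `comparison_report`: list with `summaries`,
#'   `anova`, `pairwise`, `percent_diff` data.frames.
#' @export
build_table3_report <- function(cohort,
                                parameters = NULL,
                                pairwise_method = "welch",
                                bonferroni = FALSE) {
  if (!"group" %in% names(cohort)) stop("cohort must have a 'group' column")
  default_params <- c("AHI", "AAP", "AIP", "AC_angle", "a", "b", "c",
                      "ratio_percent")
  if (is.null(parameters))
    parameters <- intersect(default_params, names(cohort))
  miss <- setdiff(parameters, names(cohort))
  if (length(miss))
    stop("missing parameter columns: ", paste(miss, collapse = ", "))
  group <- factor(cohort$group)
  lv <- levels(group)
  summaries <- list(); anova <- list(); pw <- list(); pd <- list()
  for (p in parameters) {
    v <- cohort[[p]]
    for (g in lv) {
      x <- v[group == g]
      rr_p <- tryCatch(reference_range_95(x, "percentile"),
                       error = function(e) c(low = NA_real_, high = NA_real_))
      rr_n <- reference_range_95(x, "normal")
      swp <- tryCatch(normality_test(x)$p, error = function(e) NA_real_)
      summaries[[length(summaries) + 1L]] <- data.frame(
        parameter = p, group = g, n = length(x), mean = mean(x),
        sd = stats::sd(x), ci95_low_pct = rr_p[["low"]],
        ci95_high_pct = rr_p[["high"]], ci95_low_norm = rr_n[["low"]],
        ci95_high_norm = rr_n[["high"]], shapiro_p = swp,
        normal_ok = is.na(swp) | swp > 0.05)
    }
    av <- anova_oneway(v, group)
    anova[[length(anova) + 1L]] <- data.frame(parameter = p, F = av$F,
                                              df1 = av$df1, df2 = av$df2,
                                              p = av$p)
    pwp <- pairwise_tests(v, group, method = pairwise_method,
                          bonferroni = bonferroni)
    pwp <- cbind(parameter = p, pwp)
    pw[[length(pw) + 1L]] <- pwp
    means <- tapply(v, group, mean)
    cmp <- if (all(c("control", "NII", "II") %in% lv))
      rbind(c("NII", "II"), c("control", "II"), c("control", "NII"))
    else t(utils::combn(lv, 2L))
    for (i in seq_len(nrow(cmp))) {
      ref <- cmp[i, 1L]; com <- cmp[i, 2L]
      pd[[length(pd) + 1L]] <- data.frame(
        parameter = p, reference = ref, comparison = com,
        percent = round(percent_difference(means[[ref]], means[[com]]), 1L))
    }
  }
  structure(list(summaries = do.call(rbind, summaries),
                 anova = do.call(rbind, anova),
                 pairwise = do.call(rbind, pw),
                 percent_diff = do.call(rbind, pd),
                 config = list(pairwise_method = pairwise_method,
                               bonferroni = bonferroni)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 4L, ...) {
  cat("Three-group comparison report\n\n")
  s <- x$summaries
  for (p in unique(s$parameter)) {
    sp <- s[s$parameter == p, ]
    av <- x$anova[x$anova$parameter == p, ]
    cat(sprintf("%-14s F = %.3f (df %d, %d), P = %s\n", p, av$F, av$df1,
                av$df2, format.pval(av$p, digits = digits)))
    for (i in seq_len(nrow(sp))) {
      cat(sprintf("  %-8s n=%4d  %6.2f +/- %.2f  [%.1f, %.1f] (pctl)\n",
                  sp$group[i], sp$n[i], sp$mean[i], sp$sd[i],
                  sp$ci95_low_pct[i], sp$ci95_high_pct[i]))
    }
  }
  invisible(x)
}

#' Risk-threshold report from reference ranges
#'
#' The upper bound of a group's 95% reference range serves as the risk
#' cutoff for a parameter (the study's published cutoffs are the upper ends
#' of the impingement-injury group's ranges: a > 16.8 mm, b > 12.9 mm,
#' ratio > 33.5%).
#'
#' @param cohort cohort data.frame.
#' @param group group whose reference range supplies the cutoffs.
#' @param parameters parameters to report.
#' @param method reference-range method, see [reference_range_95()].
#' @return data.frame with `parameter`, `low`, `high`, `threshold`.
#' @export
threshold_report <- function(cohort, group = "II",
                             parameters = c("a", "b", "ratio_percent"),
                             method = "normal") {
  d <- cohort[cohort$group == group, , drop = FALSE]
  if (nrow(d) == 0L) stop("group not found: ", group)
  out <- lapply(parameters, function(p) {
    rr <- reference_range_95(d[[p]], method)
    data.frame(parameter = p, low = rr[["low"]], high = rr[["high"]],
               threshold = rr[["high"]])
  })
  do.call(rbind, out)
}

#' Published risk thresholds
#'
#' Carried as read-in reference constants (their construction from the
#' printed summaries is not reproducible); see the methods vignette.
#'
#' @return data.frame with `parameter`, `threshold`, `unit`.
#' @export
published_thresholds <- function() {
  data.frame(parameter = c("a", "b", "ratio_percent"),
             threshold = c(16.8, 12.9, 33.5),
             unit = c("mm", "mm", "%"))
}
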