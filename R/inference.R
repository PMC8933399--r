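#' Split a cohort into high and average Gf groups
#'
#' Subjects scoring above the cohort mean Gf go to the high group, the rest to
#' the average group.  The separation between the two group means is reported
#' in units of the standardized test's population SD (WAIS-IV: 15); a warning
#' (not an error) is raised when the groups are less than one such SD apart,
#' since the split is then not psychometrically meaningful.
#'
#' @param records data frame with at least `subject_id` and `gf` columns
#'   (finite scores).
#' @param sd_standard population SD of the standardized score (default 15).
#' @return An object of class `gf_group_split` with elements `high_ids`,
#'   `avg_ids`, `mean_high`, `sd_high`, `mean_avg`, `sd_avg`,
#'   `separation_sd_units`, `warning_low_separation`.
#' @examples
#' rec <- data.frame(subject_id = paste0("s", 1:4),
#'                   gf = c(120, 118, 101, 100))
#' assign_gf_groups(rec)$separation_sd_units   # 18.5 / 15
#' @export
assign_gf_groups <- function(records, sd_standard = 15) {
  stopifnot(is.data.frame(records), all(c("subject_id", "gf") %in% names(records)))
  gf <- records$gf
  if (length(gf) < 4) stop("need at least 4 subjects")
  if (any(!is.finite(gf))) stop("all Gf scores must be finite")
  if (sd(gf) == 0) stop("all Gf scores identical: no split possible")
  hi <- gf > mean(gf)
  mean_high <- mean(gf[hi]); mean_avg <- mean(gf[!hi])
  sep <- abs(mean_high - mean_avg) / sd_standard
  low <- sep < 1
  if (low)
    warning(sprintf("group means are only %.2f standard-score SDs apart (< 1)", sep))
  structure(list(high_ids = as.character(records$subject_id[hi]),
                 avg_ids = as.character(records$subject_id[!hi]),
                 mean_high = mean_high, sd_high = sd(gf[hi]),
                 mean_avg = mean_avg, sd_avg = sd(gf[!hi]),
                 separation_sd_units = sep,
                 warning_low_separation = low),
            class = "gf_group_split")
}

#' @export
print.gf_group_split <- function(x, ...) {
  cat(sprintf("<gf_group_split> high n=%d (%.2f +/- %.2f), average n=%d (%.2f +/- %.2f)\n",
              length(x$high_ids), x$mean_high, x$sd_high,
              length(x$avg_ids), x$mean_avg, x$sd_avg))
  cat(sprintf("  separation: %.2f standard-score SDs%s\n", x$separation_sd_units,
              if (x$warning_low_separation) " (below 1!)" else ""))
  invisible(x)
}

#' Welch two-sample t statistic from summary statistics
#'
#' \deqn{t = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' with Welch-Satterthwaite degrees of freedom.  Useful when only published
#' group means and SDs are available.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return A list with elements `t`, `df` and the two-sided `p`.
#' @examples
#' welch_t_from_summary(117.72, 4.66, 38, 102.98, 6.09, 31)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Bartlett test of equal variances between two groups
#'
#' Pre-check used before the permutation tests: the null hypothesis is that
#' the within-group variances are equal.  Thin wrapper around the standard
#' chi-square Bartlett test with k - 1 = 1 degree of freedom.
#'
#' @param x,y numeric samples for the two groups (each n >= 2 with positive
#'   variance).
#' @return A list with `statistic`, `df` and `p`.
#' @export
bartlett_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (var(x) == 0 || var(y) == 0) stop("zero within-group variance")
  bt <- stats::bartlett.test(list(x, y))
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p = bt$p.value)
}
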