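#' ANCOVA on a per-subject global metric
#'
#' Fits the linear model `value ~ group + sex + age + education` (group and
#' sex between-subject factors, age and education covariates; no interactions)
#' and tests each term with a type-II F-test.  The corrected alpha defaults to
#' `alpha / 24`, the Bonferroni denominator for four global measures across
#' five functional bands plus one structural network.
#'
#' @param values numeric vector, one metric value per subject.
#' @param group,sex factors with at least 2 levels each.
#' @param age,education numeric covariates.
#' @param alpha nominal level (default 0.05).
#' @param n_comparisons Bonferroni denominator (default 24).
#' @return An object of class `ancova_result`: `term_names`, `f_stats`,
#'   `p_values`, `df_model`, `df_resid`, `alpha_corrected`, plus the fitted
#'   `lm` object.
#' @export
ancova_global_metric <- function(values, group, sex, age, education,
                                 alpha = 0.05, n_comparisons = 24) {
  df <- data.frame(value = as.numeric(values), group = factor(group),
                   sex = factor(sex), age = as.numeric(age),
                   education = as.numeric(education))
  if (anyNA(df)) stop("missing values in the design")
  if (nlevels(df$group) < 2 || nlevels(df$sex) < 2)
    stop("'group' and 'sex' each need at least 2 levels")
  if (var(df$value) == 0)
    stop("degenerate response: all metric values identical")
  fit <- lm(value ~ group + sex + age + education, data = df)
  mm <- model.matrix(fit)
  if (qr(mm)$rank < ncol(mm)) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient design; collinear columns: ",
         paste(rownames(al), collapse = ", "))
  }
  sigma <- suppressWarnings(summary(fit)$sigma)
  if (sigma < 1e-10 * max(abs(df$value), 1))
    stop("degenerate fit: zero residual variance")
  aov2 <- car::Anova(fit, type = 2)
  keep <- rownames(aov2) != "Residuals"
  structure(list(term_names = rownames(aov2)[keep],
                 f_stats = aov2$`F value`[keep],
                 p_values = aov2$`Pr(>F)`[keep],
                 df_model = sum(aov2$Df[keep]),
                 df_resid = aov2$Df[!keep],
                 alpha_corrected = alpha / n_comparisons,
                 fit = fit), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> type-II F-tests, residual df = %d, corrected alpha = %.4g\n",
              x$df_resid, x$alpha_corrected))
  for (i in seq_along(x$term_names))
    cat(sprintf("  %-10s F = %8.3f  p = %.4g%s\n", x$term_names[i],
                x$f_stats[i], x$p_values[i],
                if (x$p_values[i] <= x$alpha_corrected) "  *" else ""))
  invisible(x)
}

#' Group test of structural-functional connectivity similarity
#'
#' For each subject and frequency band, the Pearson correlation between the
#' vectorized upper triangles of the structural and functional matrices
#' measures how similar the two modalities are in that subject; the
#' correlations are then compared between groups with
#' [ancova_global_metric()] (group and sex factors, age and education
#' covariates), independently per band.
#'
#' @param sc_by_subject list of structural [weighted_network]s, one per
#'   subject.
#' @param fc_by_subject_band named list (one element per band) of lists of
#'   functional [weighted_network]s parallel to `sc_by_subject`.
#' @param groups group label per subject.
#' @param covariates data frame with columns `sex`, `age`, `education`.
#' @param alpha,n_comparisons passed to [ancova_global_metric()];
#'   `n_comparisons` defaults to the number of bands.
#' @return A list with one element per band, each containing `r` (per-subject
#'   similarity) and `ancova` (an `ancova_result`).
#' @export
sc_fc_similarity_test <- function(sc_by_subject, fc_by_subject_band, groups,
                                  covariates, alpha = 0.05,
                                  n_comparisons = length(fc_by_subject_band)) {
  ns <- length(sc_by_subject)
  stopifnot(length(groups) == ns, nrow(covariates) == ns)
  sc_vec <- lapply(sc_by_subject, function(net) upper_weights(assert_network(net)))
  out <- lapply(names(fc_by_subject_band), function(bn) {
    fcs <- fc_by_subject_band[[bn]]
    if (length(fcs) != ns) stop("band '", bn, "': subject lists do not match")
    r <- vapply(seq_len(ns), function(i) {
      a <- sc_vec[[i]]
      b <- upper_weights(assert_network(fcs[[i]]))
      if (length(a) != length(b)) stop("matrix sizes differ for subject ", i)
      if (sd(a) == 0 || sd(b) == 0)
        stop("constant connectivity matrix for subject ", i)
      cor(a, b)
    }, numeric(1))
    list(band = bn, r = r,
         ancova = ancova_global_metric(r, groups, covariates$sex,
                                       covariates$age, covariates$education,
                                       alpha, n_comparisons))
  })
  names(out) <- names(fc_by_subject_band)
  out
}
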