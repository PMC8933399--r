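#' Monte-Carlo permutation test on per-ROI node metrics
#'
#' The whole-brain test used for degree and for the segregation coefficient.
#' The observed statistic is the pair of counts (n_pos, n_neg): the number of
#' ROIs whose median metric is higher, respectively lower, in the high group
#' than in the average group (exact zero differences count in neither tail).
#' Group labels are permuted `n_perm` times (group sizes preserved), the
#' counts recomputed each time, and each tail's p-value is the add-one
#' smoothed proportion of permuted counts at least as large as the observed
#' one:
#' \deqn{p = \frac{1 + \#\{\text{perm count} \ge \text{observed}\}}{n_{perm} + 1}.}
#' The corrected alpha is `alpha / n_tests_for_bonferroni`, e.g. 0.05/2 for a
#' single structural network tested on both tails, or 0.05/10 across five
#' frequency bands times two tails.
#'
#' ROIs with undefined values in any subject (e.g. segregation of isolated
#' nodes) are dropped listwise and recorded in `dropped_rois`.
#'
#' @param metric_by_subject subjects x ROI numeric matrix (rownames = subject
#'   ids, colnames = ROI labels if available).
#' @param groups vector of group labels, one per subject, with exactly two
#'   distinct values.
#' @param n_perm number of label permutations (default 10000).
#' @param alpha nominal significance level before correction.
#' @param n_tests_for_bonferroni Bonferroni denominator.
#' @param seed integer seed; identical seeds give identical results.
#' @param high the label identifying the high group.
#' @return An object of class `mcs_result`: `median_diff`, `n_pos`, `n_neg`,
#'   `perm_counts_pos`, `perm_counts_neg`, `p_pos`, `p_neg`,
#'   `alpha_corrected`, `n_perm`, `seed`, `dropped_rois`.
#' @export
mcs_node_metric_test <- function(metric_by_subject, groups, n_perm = 10000,
                                 alpha = 0.05, n_tests_for_bonferroni = 2,
                                 seed = 1, high = "high") {
  if (!is.matrix(metric_by_subject)) stop("'metric_by_subject' must be a matrix")
  groups <- as.character(groups)
  if (length(groups) != nrow(metric_by_subject))
    stop("'groups' must have one label per subject (row)")
  labs <- unique(groups)
  if (length(labs) != 2 || !(high %in% labs))
    stop("'groups' must contain exactly two labels including '", high, "'")
  if (n_tests_for_bonferroni < 1) stop("Bonferroni denominator must be >= 1")
  n_high <- sum(groups == high)
  n_avg <- sum(groups != high)
  if (n_high < 2 || n_avg < 2) stop("need at least 2 subjects per group")

  bad <- apply(metric_by_subject, 2L, function(v) any(!is.finite(v)))
  dropped <- colnames(metric_by_subject)[bad]
  if (is.null(dropped) && any(bad)) dropped <- which(bad)
  metric <- metric_by_subject[, !bad, drop = FALSE]
  if (ncol(metric) == 0) stop("no ROI with complete finite values")

  n_subj <- length(groups)
  set.seed(seed)
  # each permutation reassigns the label multiset to subjects; building the
  # rows from the permuted labels makes swapping the group names swap the
  # (n_pos, p_pos) and (n_neg, p_neg) pairs exactly
  perms <- matrix(0L, n_perm + 1L, n_subj)
  perms[1L, ] <- c(which(groups == high), which(groups != high))
  for (p in seq_len(n_perm)) {
    newlab <- groups[sample.int(n_subj)]
    perms[p + 1L, ] <- c(which(newlab == high), which(newlab != high))
  }
  res <- mcs_count_engine(metric, perms, n_high)

  obs_pos <- res$n_pos[1L]
  obs_neg <- res$n_neg[1L]
  perm_pos <- res$n_pos[-1L]
  perm_neg <- res$n_neg[-1L]
  structure(list(
    median_diff = setNames(res$first_diff, colnames(metric)),
    n_pos = obs_pos, n_neg = obs_neg,
    perm_counts_pos = perm_pos, perm_counts_neg = perm_neg,
    p_pos = (1 + sum(perm_pos >= obs_pos)) / (n_perm + 1),
    p_neg = (1 + sum(perm_neg >= obs_neg)) / (n_perm + 1),
    alpha_corrected = alpha / n_tests_for_bonferroni,
    n_perm = n_perm, seed = seed,
    dropped_rois = dropped), class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  n <- length(x$median_diff)
  cat(sprintf("<mcs_result> %d ROIs, %d permutations\n", n, x$n_perm))
  cat(sprintf("  observed: %d ROIs higher in high group (p = %.4g), %d lower (p = %.4g)\n",
              x$n_pos, x$p_pos, x$n_neg, x$p_neg))
  cat(sprintf("  corrected alpha: %.4g;%s%s\n", x$alpha_corrected,
              if (x$p_pos <= x$alpha_corrected) " positive tail significant;" else "",
              if (x$p_neg <= x$alpha_corrected) " negative tail significant;" else ""))
  if (length(x$dropped_rois))
    cat("  dropped (undefined):", paste(x$dropped_rois, collapse = ", "), "\n")
  invisible(x)
}

#' Modularity null test by edge-weight shuffling
#'
#' Tests whether the community structure of a group-mean network is stronger
#' than that of equivalent networks with the same weights placed at random.
#' Each permutation shuffles the upper-triangle weights uniformly at random,
#' mirrors them to symmetry and zeroes the diagonal, then the modularity of
#' the shuffled network is recomputed with
#' [leading_eigenvector_communities()].  The observed modularity is declared
#' significant only if it exceeds the 99.9th percentile of the permuted
#' values.  A degree-preserving rewiring null is available via
#' `null = "rewire"` but weight shuffling is the default.
#'
#' @param mean_net a nonnegative [weighted_network] (typically a group mean).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param percentile significance percentile (default 99.9).
#' @param null `"shuffle"` (default) or `"rewire"` (igraph keeping_degseq
#'   rewiring of the binary topology, weights shuffled among edges).
#' @return An object of class `modularity_null`: `q_observed`, `q_permuted`,
#'   `percentile`, `significant`, `n_perm`, `seed`, plus the observed
#'   partition.
#' @export
modularity_null_test <- function(mean_net, n_perm = 1000, seed = 1,
                                 percentile = 99.9,
                                 null = c("shuffle", "rewire")) {
  assert_network(mean_net)
  null <- match.arg(null)
  w <- mean_net$weights
  if (any(w < 0)) stop("modularity null test requires nonnegative weights")
  if (sum(w) <= 0) stop("total edge weight is zero")
  part <- leading_eigenvector_communities(mean_net)
  n <- nrow(w)
  ut <- upper.tri(w)
  set.seed(seed)
  q_perm <- vapply(seq_len(n_perm), function(i) {
    wp <- matrix(0, n, n)
    if (null == "shuffle") {
      wp[ut] <- sample(w[ut])
    } else {
      g <- igraph::graph_from_adjacency_matrix((w > 0) * 1, mode = "undirected",
                                               diag = FALSE)
      g <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
      a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
      pos <- which(a[ut] > 0)
      vals <- numeric(sum(ut))
      vals[pos] <- sample(w[ut][w[ut] > 0])
      wp[ut] <- vals
    }
    wp <- wp + t(wp)
    pn <- weighted_network(wp, mean_net$roi_labels, mean_net$modality,
                           mean_net$band)
    leading_eigenvector_communities(pn)$q
  }, numeric(1))
  thr <- quantile(q_perm, percentile / 100, names = FALSE)
  structure(list(q_observed = part$q, q_permuted = q_perm,
                 percentile = 100 * mean(q_perm < part$q),
                 significant = part$q > thr,
                 threshold = thr, n_perm = n_perm, seed = seed,
                 partition = part), class = "modularity_null")
}

#' @export
print.modularity_null <- function(x, ...) {
  cat(sprintf("<modularity_null> Q = %.4f vs %d shuffled networks (99.9%% threshold %.4f)\n",
              x$q_observed, x$n_perm, x$threshold))
  cat(sprintf("  observed Q above %.1f%% of permuted values: %ssignificant\n",
              x$percentile, if (x$significant) "" else "NOT "))
  invisible(x)
}
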