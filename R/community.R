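#' Community partition of a network
#'
#' A non-overlapping, exhaustive assignment of nodes to modules together with
#' its modularity Q.  Construct directly or obtain from
#' [leading_eigenvector_communities()].
#'
#' @param membership integer vector assigning every node to a module; module
#'   ids are relabelled 1..k in order of first appearance.
#' @param q the partition's modularity on its network.
#' @param roi_labels optional node labels.
#' @return An object of class `community_partition`.
#' @export
community_partition <- function(membership, q = NA_real_, roi_labels = NULL) {
  membership <- as.integer(factor(membership, levels = unique(membership)))
  if (anyNA(membership)) stop("every node must be assigned to a module")
  if (!is.na(q) && q > 1 + 1e-12) stop("modularity cannot exceed 1")
  if (!is.null(roi_labels)) names(membership) <- roi_labels
  structure(list(membership = membership, q = q,
                 n_modules = max(membership)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d nodes in %d modules, Q = %.4f\n",
              length(x$membership), x$n_modules, x$q))
  invisible(x)
}

as_membership <- function(partition, n) {
  memb <- if (inherits(partition, "community_partition"))
    partition$membership else as.integer(partition)
  if (length(memb) != n || anyNA(memb))
    stop("partition must assign each of the ", n, " nodes exactly once")
  memb
}

#' Newman modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[w_{ij} - \frac{k_i k_j}{2m}\right]
#'   \delta(c_i, c_j)}
#' with \eqn{m} the total edge weight and \eqn{k} the weighted degree.
#' Requires nonnegative weights (clip functional networks first).
#'
#' @param net a nonnegative [weighted_network] with positive total weight.
#' @param partition a [community_partition] or membership vector.
#' @return The scalar Q.
#' @export
modularity_q <- function(net, partition) {
  assert_network(net)
  w <- net$weights
  if (any(w < 0)) stop("modularity requires nonnegative weights")
  memb <- as_membership(partition, nrow(w))
  k <- rowSums(w)
  m2 <- sum(k)                       # 2m
  if (m2 <= 0) stop("modularity undefined: total edge weight is zero")
  same <- outer(memb, memb, "==")
  sum((w - outer(k, k) / m2) * same) / m2
}

# Generalized modularity matrix for a subgraph: B[g]_ij = B_ij - delta_ij sum_k B_ik
subgraph_modmat <- function(B, idx) {
  Bg <- B[idx, idx, drop = FALSE]
  d <- rowSums(Bg)
  diag(Bg) <- diag(Bg) - d
  Bg
}

# Kernighan-Lin style refinement of a bisection vector s on Bg: repeatedly
# sweep, moving each node exactly once in order of best gain (even negative),
# and keep the best intermediate configuration; iterate while it improves.
kl_refine <- function(Bg, s) {
  score <- as.numeric(t(s) %*% Bg %*% s)
  repeat {
    ng <- length(s)
    moved <- rep(FALSE, ng)
    s_try <- s
    bs <- Bg %*% s_try            # column vector of Bg . s
    best_score <- score
    best_s <- s
    cur <- score
    for (step in seq_len(ng)) {
      # gain of flipping node i: -4 s_i (Bg s)_i + 4 Bg_ii
      gains <- -4 * s_try * bs + 4 * diag(Bg)
      gains[moved] <- -Inf
      i <- which.max(gains)
      cur <- cur + gains[i]
      s_try[i] <- -s_try[i]
      moved[i] <- TRUE
      bs <- bs + 2 * s_try[i] * Bg[, i]
      if (cur > best_score + 1e-12) {
        best_score <- cur
        best_s <- s_try
      }
    }
    if (best_score > score + 1e-12) {
      s <- best_s
      score <- best_score
    } else {
      return(list(s = s, score = score))
    }
  }
}

#' Leading-eigenvector community detection
#'
#' Newman's spectral method: the modularity matrix
#' \eqn{B = W - k k^\top / 2m} is bisected along the sign pattern of its
#' leading eigenvector, recursively, using the generalized modularity matrix
#' for subgraphs so that each split is scored against the full network's Q.
#' A split is accepted only if it increases Q; recursion stops when the
#' leading eigenvalue is numerically non-positive (<= `tol`) or no improving
#' split exists.  Eigenvector entries that are exactly zero are assigned to
#' the positive side.  By default each spectral bisection is fine-tuned with
#' a Kernighan-Lin sweep (Newman's published refinement); set
#' `fine_tune = FALSE` for the strict spectral variant.
#'
#' The trivial single-module partition (Q = 0) is the fallback, so the
#' returned Q is never negative.
#'
#' @param net a nonnegative [weighted_network] with positive total weight.
#' @param fine_tune apply Kernighan-Lin refinement after each bisection.
#' @param tol threshold below which the leading eigenvalue counts as
#'   non-positive.
#' @return A [community_partition] whose `q` equals
#'   `modularity_q(net, membership)`.
#' @export
leading_eigenvector_communities <- function(net, fine_tune = TRUE,
                                            tol = 1e-10) {
  assert_network(net)
  w <- net$weights
  if (any(w < 0)) stop("community detection requires nonnegative weights")
  n <- nrow(w)
  k <- rowSums(w)
  m2 <- sum(k)
  if (m2 <= 0) stop("modularity undefined: total edge weight is zero")
  B <- w - outer(k, k) / m2
  membership <- rep(1L, n)
  next_label <- 2L
  queue <- list(seq_len(n))
  while (length(queue)) {
    idx <- queue[[1L]]
    queue <- queue[-1L]
    if (length(idx) < 2) next
    Bg <- subgraph_modmat(B, idx)
    es <- eigen(Bg, symmetric = TRUE)
    if (es$values[1L] <= tol) next
    v <- es$vectors[, 1L]
    s <- ifelse(v >= 0, 1, -1)      # zeros to the positive side
    if (fine_tune) s <- kl_refine(Bg, s)$s
    dq <- as.numeric(t(s) %*% Bg %*% s) / (2 * m2)
    if (dq <= 1e-12) next
    pos <- idx[s > 0]
    neg <- idx[s < 0]
    if (length(pos) == 0 || length(neg) == 0) next
    membership[neg] <- next_label
    next_label <- next_label + 1L
    queue <- c(queue, list(pos), list(neg))
  }
  part <- community_partition(membership, roi_labels = net$roi_labels)
  part$q <- modularity_q(net, part)
  part
}
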