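# Independent oracles, deliberately naive: direct double loops and exhaustive
# enumeration, no shared code with the package internals.

# modularity by the literal double sum
brute_modularity <- function(w, memb) {
  n <- nrow(w)
  k <- rowSums(w)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j]) q <- q + w[i, j] - k[i] * k[j] / m2
  q / m2
}

# all set partitions of n elements as restricted-growth strings
enumerate_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, kmax) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(kmax + 1L)) grow(c(prefix, v), max(kmax, v))
  }
  grow(1L, 1L)
  out
}

# exhaustive maximum modularity (n <= 8)
max_modularity_exhaustive <- function(w) {
  parts <- enumerate_partitions(nrow(w))
  max(vapply(parts, function(p) brute_modularity(w, p), numeric(1)))
}

# efficiency oracles via Floyd-Warshall on reciprocal lengths
brute_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

brute_global_efficiency <- function(w) {
  d <- brute_distances(w)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

brute_local_efficiency <- function(w) {
  n <- nrow(w)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    vals[i] <- if (length(nb) < 2) 0 else
      brute_global_efficiency(w[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# random symmetric nonnegative weight matrix with given edge density
random_weights <- function(n, p_edge = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- runif(sum(ut)) * (runif(sum(ut)) < p_edge)
  w[ut] <- vals
  w + t(w)
}

# planted block-structured weights with jitter
planted_block_weights <- function(n, k, intra = 1, inter = 0.05,
                                  jitter = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  memb <- sort(rep(seq_len(k), length.out = n))
  w <- ifelse(outer(memb, memb, "=="), intra, inter)
  noise <- matrix(runif(n * n, -jitter, jitter), n)
  noise <- (noise + t(noise)) / 2
  w <- pmax(w + noise, 0)
  diag(w) <- 0
  list(w = w, memb = memb)
}

snet <- function(w, labels = NULL) weighted_network(w, labels, "structural")
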