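#' Weighted undirected brain network
#'
#' The common currency of the pipeline: an n x n symmetric weight matrix with
#' ROI labels, a modality tag and (for functional networks) a frequency band.
#' The diagonal is stored as exactly zero; structural weights must be
#' nonnegative and functional weights (envelope Pearson correlations) must lie
#' in [-1, 1].
#'
#' @param weights n x n numeric matrix, symmetric to within 1e-10.
#' @param roi_labels character vector of n unique ROI labels; defaults to the
#'   matrix dimnames or `ROI1..ROIn`.
#' @param modality `"structural"` or `"functional"`.
#' @param band a [frequency_band] (functional networks) or `NULL`.
#' @return An object of class `weighted_network` with elements `weights`
#'   (with dimnames set to the labels), `roi_labels`, `modality`, `band`.
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2)
#' weighted_network(w, c("L", "R"), "structural")
#' @export
weighted_network <- function(weights, roi_labels = NULL,
                             modality = c("structural", "functional"),
                             band = NULL) {
  modality <- match.arg(modality)
  if (!is.matrix(weights) || !is.numeric(weights) || nrow(weights) != ncol(weights))
    stop("'weights' must be a square numeric matrix")
  n <- nrow(weights)
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("'weights' must be finite")
  asym <- max(abs(weights - t(weights)))
  if (asym > 1e-10)
    stop("'weights' is not symmetric (max |w - t(w)| = ", signif(asym, 3), ")")
  weights <- (weights + t(weights)) / 2   # kill roundoff asymmetry
  diag(weights) <- 0
  if (is.null(roi_labels)) {
    roi_labels <- rownames(weights)
    if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(n))
  }
  if (length(roi_labels) != n || anyDuplicated(roi_labels))
    stop("'roi_labels' must be ", n, " unique labels")
  if (modality == "structural" && any(weights < 0))
    stop("structural weights must be nonnegative")
  if (modality == "functional" && any(weights < -1 - 1e-12 | weights > 1 + 1e-12))
    stop("functional weights must lie in [-1, 1]")
  if (!is.null(band)) band <- as_band(band)
  dimnames(weights) <- list(roi_labels, roi_labels)
  structure(list(weights = weights, roi_labels = as.character(roi_labels),
                 modality = modality, band = band),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- length(x$roi_labels)
  e <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<weighted_network> %s%s, %d ROIs, %d nonzero edges, total weight %.4g\n",
              x$modality,
              if (!is.null(x$band)) paste0(" [", x$band$name, "]") else "",
              n, e, sum(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

n_rois <- function(net) length(net$roi_labels)

#' Clip negative weights to zero
#'
#' Envelope correlations can be negative, but the nonnegative-weight graph
#' measures (modularity, segregation, reciprocal-weight path metrics) are only
#' defined for nonnegative networks.  The pipeline clips negative functional
#' weights to zero before computing those measures, the standard convention in
#' envelope-correlation MEG work; structural networks are unaffected.
#'
#' @param net a [weighted_network].
#' @return A [weighted_network] with `pmax(weights, 0)`.
#' @export
clip_negative_weights <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  net$weights <- pmax(net$weights, 0)
  net
}

# upper-triangle edge weights as a vector (row-major over i < j)
upper_weights <- function(net) net$weights[upper.tri(net$weights)]

assert_network <- function(net) {
  if (!inherits(net, "weighted_network"))
    stop("expected a 'weighted_network' object")
  invisible(net)
}
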