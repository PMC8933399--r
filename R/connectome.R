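#' Per-subject tractography output
#'
#' Probabilistic tractography estimates each ordered pair of regions
#' independently, so the raw streamline-count matrix is in general asymmetric;
#' the diagonal is ignored.  ROI sizes are voxel counts and must be positive.
#'
#' @param counts n x n nonnegative numeric matrix of streamline counts
#'   (ordered pairs).
#' @param roi_sizes length-n vector of positive ROI sizes (voxels).
#' @param roi_labels optional n unique labels.
#' @return An object of class `tractography_sample`.
#' @export
tractography_sample <- function(counts, roi_sizes, roi_labels = NULL) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stop("'counts' must be a square matrix")
  if (anyNA(counts) || any(counts < 0))
    stop("streamline counts must be nonnegative")
  n <- nrow(counts)
  if (length(roi_sizes) != n || any(!is.finite(roi_sizes)) || any(roi_sizes <= 0))
    stop("'roi_sizes' must be ", n, " positive values")
  if (is.null(roi_labels)) {
    roi_labels <- rownames(counts)
    if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(n))
  }
  if (length(roi_labels) != n || anyDuplicated(roi_labels))
    stop("'roi_labels' must be ", n, " unique labels")
  dimnames(counts) <- list(roi_labels, roi_labels)
  structure(list(counts = counts, roi_sizes = as.numeric(roi_sizes),
                 roi_labels = as.character(roi_labels)),
            class = "tractography_sample")
}

#' Structural connectivity from streamline counts
#'
#' Averages the two tract directions and normalizes each connection by the
#' mean size of the two regions:
#' \deqn{w_{ab} = \frac{(c_{ab} + c_{ba})/2}{(s_a + s_b)/2}}
#' so that larger parcels are not credited with more connectivity merely
#' because they contain more seed voxels.  The diagonal is zeroed.
#'
#' @param sample a [tractography_sample].
#' @return A structural [weighted_network].
#' @examples
#' s <- tractography_sample(matrix(c(0, 14, 10, 0), 2, 2), c(4, 2))
#' build_structural_connectivity(s)$weights   # off-diagonal = 12/3 = 4
#' @export
build_structural_connectivity <- function(sample) {
  stopifnot(inherits(sample, "tractography_sample"))
  cc <- (sample$counts + t(sample$counts)) / 2
  ss <- outer(sample$roi_sizes, sample$roi_sizes, function(a, b) (a + b) / 2)
  w <- cc / ss
  diag(w) <- 0
  weighted_network(w, sample$roi_labels, "structural")
}

#' Region time series in a frequency band
#'
#' @param data n_regions x n_samples numeric matrix; all values finite.
#' @param fs sampling rate in Hz.
#' @param band the [frequency_band] the series belongs to (for broadband
#'   inputs, the band the series is destined for).
#' @param roi_labels optional region labels.
#' @param envelope logical: is this an amplitude envelope (nonnegative) rather
#'   than a raw oscillatory signal?
#' @return An object of class `band_timeseries`.
#' @export
band_timeseries <- function(data, fs, band, roi_labels = NULL,
                            envelope = FALSE) {
  if (!is.matrix(data) || !is.numeric(data)) stop("'data' must be a numeric matrix")
  if (anyNA(data) || any(!is.finite(data))) stop("time series must be finite")
  if (fs <= 0) stop("'fs' must be positive")
  if (ncol(data) <= 2 * fs)
    stop("need more than 2 s of signal (", ncol(data), " samples at ", fs, " Hz)")
  band <- as_band(band)
  n <- nrow(data)
  if (is.null(roi_labels)) {
    roi_labels <- rownames(data)
    if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(n))
  }
  rownames(data) <- roi_labels
  structure(list(data = data, fs = fs, band = band,
                 roi_labels = as.character(roi_labels), envelope = envelope),
            class = "band_timeseries")
}

#' @export
print.band_timeseries <- function(x, ...) {
  cat(sprintf("<band_timeseries>%s %d regions x %d samples @ %g Hz, band %s (%g-%g Hz)\n",
              if (x$envelope) " [envelope]" else "", nrow(x$data), ncol(x$data),
              x$fs, x$band$name, x$band$lo, x$band$hi))
  invisible(x)
}

# Windowed-sinc (Hamming) band-pass FIR, order = cycles of the low edge.
# Even order => symmetric taps with integer group delay order/2.
design_bandpass <- function(band, fs, cycles = 3) {
  band <- nyquist_cap(band, fs)
  ord <- ceiling(cycles * fs / band$lo)
  if (ord %% 2 == 1) ord <- ord + 1
  b <- signal::fir1(ord, c(band$lo, band$hi) / (fs / 2), type = "pass")
  list(b = as.numeric(b), order = ord, band = band)
}

# FFT-based linear convolution of x with kernel h (lengths nx + nh - 1).
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- 2^ceiling(log2(n))
  y <- Re(fft(fft(c(x, rep(0, nfft - length(x)))) *
              fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Zero-phase (forward-backward) FIR filtering.  For a symmetric FIR the
# forward-backward cascade equals one linear convolution with conv(b, rev(b))
# followed by removal of the order-sample delay; implemented that way with a
# single FFT convolution per series.  Edges are zero-padded; callers discard
# one filter length at each end.
fir_filtfilt <- function(b, x) {
  g <- fft_conv(b, rev(b))
  ord <- length(b) - 1L
  y <- fft_conv(x, g)
  y[(ord + 1L):(ord + length(x))]
}

# Analytic signal via the FFT half-spectrum construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Band-pass filter and Hilbert amplitude envelope
#'
#' Filters each region's signal into `band` with a zero-phase (forward -
#' backward) windowed-sinc FIR filter and returns the magnitude of the
#' analytic signal, i.e. the instantaneous amplitude envelope.  Zero-phase
#' filtering guarantees the envelopes are not time-shifted relative to one
#' another.  Because filter transients contaminate the ends, one filter
#' length is discarded at each edge before the envelopes are returned (set
#' `trim = FALSE` to keep full length, e.g. for visualisation).
#'
#' @param raw a broadband (or band-limited) [band_timeseries].
#' @param band target [frequency_band] or canonical band name; the upper edge
#'   is Nyquist-capped via [nyquist_cap()].
#' @param cycles filter order expressed in cycles of the band's low edge
#'   (default 3).  The delta band (low edge 0.1 Hz) therefore implies long
#'   filters; a minimum input duration of `30 / lo` seconds is enforced.
#' @param trim discard `order` samples at each edge (default `TRUE`).
#' @return A [band_timeseries] with `envelope = TRUE`.
#' @export
bandpass_and_envelope <- function(raw, band = raw$band, cycles = 3,
                                  trim = TRUE) {
  stopifnot(inherits(raw, "band_timeseries"))
  band <- as_band(band)
  fs <- raw$fs
  filt <- design_bandpass(band, fs, cycles)   # errors if band is outside Nyquist
  nsamp <- ncol(raw$data)
  if (nsamp < 3 * (filt$order + 1L))
    stop("signal too short for the ", band$name, " filter: need at least ",
         3 * (filt$order + 1L), " samples, got ", nsamp)
  if (nsamp / fs < 30 / band$lo)
    stop("signal shorter than the minimum duration for band '", band$name,
         "' (", 30 / band$lo, " s)")
  env <- t(apply(raw$data, 1L, function(x) Mod(analytic_signal(fir_filtfilt(filt$b, x)))))
  if (trim) {
    keep <- (filt$order + 1L):(nsamp - filt$order)
    env <- env[, keep, drop = FALSE]
  }
  band_timeseries(env, fs, filt$band, raw$roi_labels, envelope = TRUE)
}

#' Functional connectivity from amplitude envelopes
#'
#' The functional weight between two regions is the Pearson correlation of
#' their amplitude envelopes over the whole recording.  The diagonal is
#' stored as zero.
#'
#' @param envelopes a [band_timeseries] of envelopes (>= 2 regions,
#'   >= 3 samples).
#' @return A functional [weighted_network] with weights in [-1, 1].
#' @export
build_functional_connectivity <- function(envelopes) {
  stopifnot(inherits(envelopes, "band_timeseries"))
  x <- envelopes$data
  if (nrow(x) < 2) stop("need at least 2 regions")
  if (ncol(x) < 3) stop("need at least 3 samples")
  v <- apply(x, 1L, var)
  if (any(v == 0))
    stop("zero-variance envelope for region(s): ",
         paste(envelopes$roi_labels[v == 0], collapse = ", "))
  r <- cor(t(x))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 0
  weighted_network(r, envelopes$roi_labels, "functional", envelopes$band)
}
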