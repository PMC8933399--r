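#' Frequency band descriptor
#'
#' A frequency band is a named interval (lo, hi) in Hz.  The five canonical
#' bands used throughout resting-state MEG connectivity work are available via
#' [canonical_bands()].
#'
#' @param name band name, one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`, or any other label for custom bands.
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return An object of class `frequency_band`.
#' @examples
#' frequency_band("alpha", 8, 12)
#' @export
frequency_band <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo)
    stop("band edges must satisfy 0 < lo < hi (got lo=", lo, ", hi=", hi, ")")
  structure(list(name = name, lo = lo, hi = hi), class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' The five canonical frequency bands
#'
#' delta 0.1--2 Hz, theta 2--8 Hz, alpha 8--12 Hz, beta 12--32 Hz and
#' gamma 32--75 Hz.  At the usual 150 Hz effective sampling rate the nominal
#' gamma upper edge sits exactly at Nyquist; [nyquist_cap()] is applied before
#' any filtering or synthesis.
#'
#' @param names optional character vector selecting a subset (in the given
#'   order).
#' @return Named list of [frequency_band] objects.
#' @export
canonical_bands <- function(names = NULL) {
  bands <- list(
    delta = frequency_band("delta", 0.1, 2),
    theta = frequency_band("theta", 2, 8),
    alpha = frequency_band("alpha", 8, 12),
    beta  = frequency_band("beta", 12, 32),
    gamma = frequency_band("gamma", 32, 75)
  )
  if (is.null(names)) return(bands)
  unknown <- setdiff(names, names(bands))
  if (length(unknown))
    stop("unknown band(s): ", paste(unknown, collapse = ", "))
  bands[names]
}

#' Cap a band's upper edge below Nyquist
#'
#' Bands are defined independently of the sampling rate; when the upper edge
#' reaches or exceeds Nyquist it is capped at `cap * fs / 2` (default 0.95 of
#' Nyquist) so that filters remain realizable.  An error is raised if the lower
#' edge itself is not strictly below Nyquist.
#'
#' @param band a [frequency_band].
#' @param fs sampling rate in Hz.
#' @param cap fraction of Nyquist used as the ceiling for `hi`.
#' @return A [frequency_band] with `hi <= cap * fs/2`.
#' @export
nyquist_cap <- function(band, fs, cap = 0.95) {
  stopifnot(inherits(band, "frequency_band"), fs > 0)
  nyq <- fs / 2
  if (band$lo >= nyq)
    stop("band '", band$name, "' lower edge ", band$lo,
         " Hz is not below Nyquist (", nyq, " Hz)")
  hi <- min(band$hi, cap * nyq)
  if (hi <= band$lo)
    stop("band '", band$name, "' collapses after Nyquist capping")
  frequency_band(band$name, band$lo, hi)
}

as_band <- function(band) {
  if (inherits(band, "frequency_band")) return(band)
  if (is.character(band) && length(band) == 1L) return(canonical_bands(band)[[1L]])
  stop("'band' must be a frequency_band or a canonical band name")
}
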