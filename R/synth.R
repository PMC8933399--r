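#' Specification of a synthetic cohort
#'
#' Collects everything the generators need to emulate a two-group resting
#' state study: a planted module structure with intra- and inter-module
#' structural weights, optional group effects (an additive mean-weight shift
#' for the high group and a shift applied only to its inter-module weights),
#' planted envelope-correlation levels for the functional bands, WAIS-like Gf
#' score distributions, and acquisition constants.  Defaults mirror the study
#' design the package emulates: 90 ROIs, groups of 38 (high) and 31
#' (average), Gf 117.72 +/- 4.66 versus 102.98 +/- 6.09, five canonical bands
#' at a 150 Hz effective sampling rate, 600 s (10 min) of resting state.
#'
#' @param n_rois number of ROIs (default 90).
#' @param n_high,n_avg group sizes (each >= 2).
#' @param partition_true integer membership vector of length `n_rois`
#'   (default: five equal modules).
#' @param intra_weight_mean,inter_weight_mean mean structural weight for
#'   within- and between-module connections; `intra >= inter >= 0`.
#' @param group_degree_shift additive weight offset applied to every
#'   connection of high-group subjects.
#' @param group_inter_shift additive offset applied only to the inter-module
#'   connections of high-group subjects.
#' @param noise_sd SD of the streamline-count noise, on the normalized-weight
#'   scale.
#' @param bands named list of [frequency_band]s to synthesize.
#' @param fs sampling rate (Hz); must exceed twice the highest Nyquist-capped
#'   band edge.
#' @param duration_s recording duration in seconds.
#' @param gf_mean_high,gf_sd_high,gf_mean_avg,gf_sd_avg Gf score populations.
#' @param fc_intra_corr,fc_inter_corr planted envelope correlations within
#'   and between modules.
#' @param fc_group_shift named numeric vector (per band) added to all planted
#'   envelope correlations of high-group subjects; defaults to 0 everywhere.
#' @param roi_size_range range of ROI sizes in voxels, drawn uniformly.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rois = 90, n_high = 38, n_avg = 31,
                        partition_true = NULL,
                        intra_weight_mean = 1.0, inter_weight_mean = 0.2,
                        group_degree_shift = 0, group_inter_shift = 0,
                        noise_sd = 0.25,
                        bands = canonical_bands(), fs = 150,
                        duration_s = 600,
                        gf_mean_high = 117.72, gf_sd_high = 4.66,
                        gf_mean_avg = 102.98, gf_sd_avg = 6.09,
                        fc_intra_corr = 0.3, fc_inter_corr = 0.1,
                        fc_group_shift = NULL,
                        roi_size_range = c(200, 2000)) {
  if (n_high < 2 || n_avg < 2) stop("group sizes must be >= 2")
  if (!(intra_weight_mean >= inter_weight_mean && inter_weight_mean >= 0))
    stop("need intra_weight_mean >= inter_weight_mean >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (is.null(partition_true))
    partition_true <- sort(rep(seq_len(min(5, n_rois)), length.out = n_rois))
  if (length(partition_true) != n_rois || anyNA(partition_true))
    stop("'partition_true' must assign each of the ", n_rois, " ROIs")
  if (!length(bands)) stop("need at least one band")
  if (is.null(names(bands)))
    names(bands) <- vapply(bands, `[[`, character(1), "name")
  capped <- lapply(bands, nyquist_cap, fs = fs)   # errors if lo >= Nyquist
  hi_max <- max(vapply(capped, `[[`, numeric(1), "hi"))
  if (fs <= 2 * hi_max * 0.999)
    stop("fs must exceed twice the highest capped band edge")
  if (gf_sd_high <= 0 || gf_sd_avg <= 0) stop("Gf SDs must be positive")
  if (is.null(fc_group_shift)) fc_group_shift <- setNames(rep(0, length(bands)), names(bands))
  if (is.null(names(fc_group_shift)) && length(fc_group_shift) == length(bands))
    names(fc_group_shift) <- names(bands)
  structure(list(n_rois = n_rois, n_high = n_high, n_avg = n_avg,
                 partition_true = as.integer(partition_true),
                 intra_weight_mean = intra_weight_mean,
                 inter_weight_mean = inter_weight_mean,
                 group_degree_shift = group_degree_shift,
                 group_inter_shift = group_inter_shift,
                 noise_sd = noise_sd, bands = bands, fs = fs,
                 duration_s = duration_s,
                 gf_mean_high = gf_mean_high, gf_sd_high = gf_sd_high,
                 gf_mean_avg = gf_mean_avg, gf_sd_avg = gf_sd_avg,
                 fc_intra_corr = fc_intra_corr, fc_inter_corr = fc_inter_corr,
                 fc_group_shift = fc_group_shift,
                 roi_size_range = roi_size_range,
                 roi_labels = sprintf("ROI%03d", seq_len(n_rois))),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d ROIs (%d planted modules), groups %d/%d, %g s @ %g Hz, bands: %s\n",
              x$n_rois, length(unique(x$partition_true)), x$n_high, x$n_avg,
              x$duration_s, x$fs, paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Generate WAIS-like Gf scores for two groups
#'
#' Draws normally distributed standardized scores for the high and average
#' groups.  With the default population parameters of [cohort_spec()] the
#' groups reproduce, in expectation, a Welch t of about 11.1 on about 55 df
#' for n = 38 vs 31.
#'
#' @param n_high,n_avg group sizes (>= 2).
#' @param mean_high,sd_high,mean_avg,sd_avg population parameters
#'   (SDs positive).
#' @param seed integer seed.
#' @return Data frame with columns `subject_id`, `group`, `gf`.
#' @export
generate_gf_scores <- function(n_high, n_avg,
                               mean_high = 117.72, sd_high = 4.66,
                               mean_avg = 102.98, sd_avg = 6.09, seed = 1) {
  if (n_high < 2 || n_avg < 2) stop("group sizes must be >= 2")
  if (sd_high <= 0 || sd_avg <= 0) stop("standard deviations must be positive")
  set.seed(seed)
  data.frame(
    subject_id = sprintf("sub%03d", seq_len(n_high + n_avg)),
    group = factor(rep(c("high", "average"), c(n_high, n_avg)),
                   levels = c("high", "average")),
    gf = c(rnorm(n_high, mean_high, sd_high), rnorm(n_avg, mean_avg, sd_avg)),
    stringsAsFactors = FALSE)
}

#' Generate the full subject covariate table
#'
#' Adds age, sex and education to the Gf scores.  Group-wise distributions
#' follow the emulated study's demographics: age 25.86 +/- 4.89 (high) versus
#' 24.00 +/- 2.69 (average), education 14.73 +/- 4.25 versus 14.56 +/- 5.87
#' years, sex ratios 15F/23M versus 18F/13M.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed.
#' @return Data frame with columns `subject_id`, `group`, `gf`, `age`, `sex`,
#'   `education`.
#' @export
generate_subject_table <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  tab <- generate_gf_scores(spec$n_high, spec$n_avg,
                            spec$gf_mean_high, spec$gf_sd_high,
                            spec$gf_mean_avg, spec$gf_sd_avg, seed = seed)
  nh <- spec$n_high; na <- spec$n_avg
  # RNG state continues from the score draw; same seed => same table
  tab$age <- pmax(18, c(rnorm(nh, 25.86, 4.89), rnorm(na, 24.00, 2.69)))
  tab$sex <- factor(c(ifelse(runif(nh) < 15 / 38, "F", "M"),
                      ifelse(runif(na) < 18 / 31, "F", "M")),
                    levels = c("F", "M"))
  tab$education <- pmax(8, c(rnorm(nh, 14.73, 4.25), rnorm(na, 14.56, 5.87)))
  tab
}

# planted mean weight matrix for one group (diagonal zero)
planted_weights <- function(spec, group) {
  same <- outer(spec$partition_true, spec$partition_true, "==")
  w <- ifelse(same, spec$intra_weight_mean, spec$inter_weight_mean)
  if (group == "high") {
    w <- w + spec$group_degree_shift
    w <- w + spec$group_inter_shift * !same
  }
  w <- pmax(w, 0)
  diag(w) <- 0
  w
}

#' Generate one subject's tractography sample
#'
#' Streamline counts are drawn, independently for the two directions of each
#' region pair, as zero-truncated normal values whose mean is the planted
#' weight times the mean size of the two regions; the resulting matrix is
#' therefore deliberately asymmetric (the two directions differ by
#' independent noise), exactly as probabilistic tractography estimates them.
#' ROI sizes are drawn uniformly from `spec$roi_size_range` voxels.  With
#' `noise_sd = 0` the counts are exactly symmetric and
#' [build_structural_connectivity()] recovers the planted weights.
#'
#' @param spec a [cohort_spec].
#' @param group `"high"` or `"average"`; selects the planted group effects.
#' @param seed integer seed.
#' @return A [tractography_sample].
#' @export
generate_tractography_sample <- function(spec, group = c("average", "high"),
                                         seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  n <- spec$n_rois
  set.seed(seed)
  sizes <- round(runif(n, spec$roi_size_range[1], spec$roi_size_range[2]))
  w <- planted_weights(spec, group)
  pair_size <- outer(sizes, sizes, function(a, b) (a + b) / 2)
  mu <- w * pair_size
  counts <- matrix(pmax(0, rnorm(n * n, mu, spec$noise_sd * pair_size)), n, n)
  diag(counts) <- 0
  if (spec$noise_sd == 0) counts <- mu   # exact planted means, symmetric
  diag(counts) <- 0
  tractography_sample(counts, sizes, spec$roi_labels)
}

# exact lognormal mapping between Gaussian-process correlation rho and the
# Pearson correlation r of the exponentiated envelopes exp(sigma * z):
#   r = (exp(sigma^2 rho) - 1) / (exp(sigma^2) - 1)
# inverted below; monotone in rho, identity at 0 and 1.
gp_corr_for_target <- function(r, sigma) log1p(r * expm1(sigma^2)) / sigma^2

# clip to PSD and restore the unit diagonal
make_psd <- function(m, tol = 1e-10) {
  es <- eigen(m, symmetric = TRUE)
  if (min(es$values) >= tol) return(m)
  vals <- pmax(es$values, tol)
  m2 <- es$vectors %*% (vals * t(es$vectors))
  d <- sqrt(diag(m2))
  m2 / outer(d, d)
}

lowpass_taps <- function(fc, fs, cycles = 3) {
  ord <- ceiling(cycles * fs / fc)
  if (ord %% 2 == 1) ord <- ord + 1
  as.numeric(signal::fir1(ord, fc / (fs / 2), type = "low"))
}

#' Generate band-limited time series with planted envelope correlations
#'
#' Each region's signal is a constant-amplitude band-limited carrier (the
#' cosine of the instantaneous phase of band-pass-filtered white noise)
#' multiplied by a strictly positive slow envelope.  Envelopes are
#' exponentiated low-pass Gaussian processes: positivity is guaranteed, and
#' the Gaussian-process correlation is chosen through the exact lognormal
#' moment mapping so that the population Pearson correlation matrix of the
#' envelopes equals `envelope_corr_target`.  Running the generated signal
#' through [bandpass_and_envelope()] and [build_functional_connectivity()]
#' recovers the target correlations up to sampling error, which shrinks as
#' the duration grows.
#'
#' @param n_rois number of regions.
#' @param band a [frequency_band] (Nyquist-capped internally).
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param envelope_corr_target n x n symmetric positive-semidefinite matrix
#'   with unit diagonal.
#' @param seed integer seed.
#' @param sigma_log log-scale SD of the lognormal envelopes (modulation
#'   depth; default 0.4 gives a realistic envelope coefficient of variation
#'   of about 0.42).
#' @param env_cutoff_hz low-pass cutoff of the envelope process; default
#'   `min(1, lo/2)` Hz so that the modulation stays well below the carrier
#'   band.
#' @return A [band_timeseries] with attribute `"envelopes"` holding the true
#'   planted envelopes (regions x samples).
#' @export
generate_band_timeseries <- function(n_rois, band, fs, duration_s,
                                     envelope_corr_target = diag(n_rois),
                                     seed = 1, sigma_log = 0.4,
                                     env_cutoff_hz = NULL) {
  band <- nyquist_cap(as_band(band), fs)   # errors outside Nyquist
  tgt <- envelope_corr_target
  if (!is.matrix(tgt) || nrow(tgt) != n_rois || ncol(tgt) != n_rois)
    stop("'envelope_corr_target' must be ", n_rois, " x ", n_rois)
  if (max(abs(tgt - t(tgt))) > 1e-10 || max(abs(diag(tgt) - 1)) > 1e-10)
    stop("'envelope_corr_target' must be symmetric with unit diagonal")
  ev <- eigen(tgt, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("'envelope_corr_target' is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")")
  nsamp <- round(duration_s * fs)
  if (nsamp < 8) stop("duration too short")
  if (is.null(env_cutoff_hz)) env_cutoff_hz <- min(1, band$lo / 2)

  set.seed(seed)
  # correlated lognormal envelopes
  rho <- gp_corr_for_target(tgt, sigma_log)
  diag(rho) <- 1
  rho <- make_psd(rho)
  L <- t(chol(rho + diag(1e-12, n_rois)))
  h <- lowpass_taps(env_cutoff_hz, fs)
  pad <- length(h)
  gain <- sqrt(sum(fft_conv(h, rev(h))^2))   # filtfilt amplitude gain on white noise
  z <- matrix(rnorm(n_rois * (nsamp + 2 * pad)), n_rois)
  z <- t(apply(z, 1L, function(x) fir_filtfilt(h, x)))
  z <- z[, pad + seq_len(nsamp), drop = FALSE] / gain
  z <- L %*% z
  env <- exp(sigma_log * z)

  # constant-amplitude FM carriers, independent across regions: the cosine of
  # an integrated random instantaneous frequency confined well inside the
  # band.  Because the carrier amplitude is constant and the envelope spectrum
  # sits below the band, the Hilbert envelope of envelope * carrier is the
  # planted envelope (Bedrosian's theorem), so the analysis path recovers the
  # target correlations without carrier-induced dilution.
  halfw <- (band$hi - band$lo) / 2
  center <- (band$hi + band$lo) / 2
  f_mod <- min(halfw / 4, 2)
  hf <- lowpass_taps(f_mod, fs)
  fpad <- length(hf)
  fgain <- sqrt(sum(fft_conv(hf, rev(hf))^2))
  carrier <- t(vapply(seq_len(n_rois), function(i) {
    zf <- fir_filtfilt(hf, rnorm(nsamp + 2 * fpad))[fpad + seq_len(nsamp)] / fgain
    finst <- center + 0.3 * halfw * pmin(pmax(zf, -2.5), 2.5)
    cos(2 * pi * cumsum(finst) / fs + runif(1, 0, 2 * pi))
  }, numeric(nsamp)))

  out <- band_timeseries(env * carrier, fs, band,
                         roi_labels = sprintf("ROI%03d", seq_len(n_rois)))
  attr(out, "envelopes") <- env
  out
}

# planted envelope-correlation target for one group and band
fc_target_matrix <- function(spec, group, band_name) {
  same <- outer(spec$partition_true, spec$partition_true, "==")
  r <- ifelse(same, spec$fc_intra_corr, spec$fc_inter_corr)
  if (group == "high") {
    shift <- spec$fc_group_shift[[band_name]]
    if (is.null(shift) || is.na(shift)) shift <- 0
    r <- r + shift
  }
  r <- pmin(pmax(r, 0), 0.95)
  diag(r) <- 1
  r
}

#' Generate a full synthetic cohort in memory
#'
#' Produces the subject table, one tractography sample per subject and one
#' band-limited time series per subject and band, with deterministic
#' per-subject seeds derived from the master seed.  Memory grows with
#' `n_rois * duration_s * fs * n_subjects * n_bands`; for large cohorts use
#' [write_synthetic_cohort()] (streams to disk) or [run_pipeline()] in
#' synthetic mode (streams through the analysis).
#'
#' @param spec a [cohort_spec].
#' @param seed master integer seed.
#' @return An object of class `gf_cohort`: `spec`, `subjects`,
#'   `tractography` (list per subject), `timeseries` (list per subject of
#'   lists per band).
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- generate_subject_table(spec, stage_seed(seed, STAGE$covariates))
  ns <- nrow(subjects)
  tract <- vector("list", ns)
  ts <- vector("list", ns)
  for (i in seq_len(ns)) {
    g <- as.character(subjects$group[i])
    tract[[i]] <- generate_tractography_sample(
      spec, g, stage_seed(seed, STAGE$tractography, i))
    ts[[i]] <- lapply(seq_along(spec$bands), function(b) {
      generate_band_timeseries(
        spec$n_rois, spec$bands[[b]], spec$fs, spec$duration_s,
        fc_target_matrix(spec, g, names(spec$bands)[b]),
        seed = stage_seed(seed, STAGE$timeseries, (i - 1L) * length(spec$bands) + b))
    })
    names(ts[[i]]) <- names(spec$bands)
  }
  names(tract) <- names(ts) <- subjects$subject_id
  structure(list(spec = spec, subjects = subjects, tractography = tract,
                 timeseries = ts, seed = seed), class = "gf_cohort")
}

#' Write a synthetic cohort to disk in the pipeline's file formats
#'
#' Streams subject by subject: `cohort.csv`, per-subject
#' `<id>_counts.csv` / `<id>_sizes.csv`, and per-subject per-band
#' `<id>_ts_<band>.csv` with its JSON sidecar.  Seeds match
#' [generate_cohort()], so reading the files back reproduces the in-memory
#' cohort bit-exactly.
#'
#' @param spec a [cohort_spec].
#' @param dir output directory (created if needed).
#' @param seed master integer seed.
#' @return Invisibly, `dir`.
#' @export
write_synthetic_cohort <- function(spec, dir, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- generate_subject_table(spec, stage_seed(seed, STAGE$covariates))
  write_cohort_csv(subjects, file.path(dir, "cohort.csv"))
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    g <- as.character(subjects$group[i])
    smp <- generate_tractography_sample(spec, g,
                                        stage_seed(seed, STAGE$tractography, i))
    write_square_csv(smp$counts, file.path(dir, paste0(id, "_counts.csv")))
    writeLines(c("roi_label,size",
                 paste(smp$roi_labels, fmt_num(smp$roi_sizes), sep = ",")),
               file.path(dir, paste0(id, "_sizes.csv")))
    for (b in seq_along(spec$bands)) {
      tsb <- generate_band_timeseries(
        spec$n_rois, spec$bands[[b]], spec$fs, spec$duration_s,
        fc_target_matrix(spec, g, names(spec$bands)[b]),
        seed = stage_seed(seed, STAGE$timeseries, (i - 1L) * length(spec$bands) + b))
      write_timeseries_csv(tsb, file.path(dir, paste0(id, "_ts_",
                                                      names(spec$bands)[b], ".csv")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_synthetic_cohort()]
#'
#' @param dir directory containing `cohort.csv` and the per-subject files.
#' @param bands band names to load (default: all found on disk for the first
#'   subject).
#' @return A `gf_cohort` (without a `spec`).
#' @export
read_cohort_dir <- function(dir, bands = NULL) {
  subjects <- read_cohort_csv(file.path(dir, "cohort.csv"))
  ids <- subjects$subject_id
  if (is.null(bands)) {
    hits <- list.files(dir, pattern = paste0("^", ids[1], "_ts_.*\\.csv$"))
    bands <- sub("\\.csv$", "", sub(paste0("^", ids[1], "_ts_"), "", hits))
  }
  tract <- lapply(ids, function(id) {
    counts <- read_square_csv(file.path(dir, paste0(id, "_counts.csv")))
    sz <- utils::read.csv(file.path(dir, paste0(id, "_sizes.csv")),
                          stringsAsFactors = FALSE)
    tractography_sample(counts, sz$size, rownames(counts))
  })
  ts <- lapply(ids, function(id) {
    out <- lapply(bands, function(b)
      read_timeseries_csv(file.path(dir, paste0(id, "_ts_", b, ".csv"))))
    names(out) <- bands
    out
  })
  names(tract) <- names(ts) <- ids
  structure(list(spec = NULL, subjects = subjects, tractography = tract,
                 timeseries = ts, seed = NA_integer_), class = "gf_cohort")
}
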