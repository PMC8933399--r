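test_that("Gf score generation is deterministic and converges to its targets", {
  a <- generate_gf_scores(38, 31, seed = 4)
  b <- generate_gf_scores(38, 31, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, generate_gf_scores(38, 31, seed = 5)))
  expect_error(generate_gf_scores(10, 10, sd_high = -1), "positive")
  expect_error(generate_gf_scores(1, 10), ">= 2")

  # law-of-large-numbers bound at n = 10,000 per group
  big <- generate_gf_scores(10000, 10000, seed = 19)
  hi <- big$gf[big$group == "high"]; av <- big$gf[big$group == "average"]
  expect_lt(abs(mean(hi) - 117.72), 3 * 4.66 / sqrt(10000))
  expect_lt(abs(mean(av) - 102.98), 3 * 6.09 / sqrt(10000))
})

test_that("zero-noise tractography is symmetric and recovers the planted weights", {
  spec <- cohort_spec(n_rois = 12, n_high = 4, n_avg = 4,
                      partition_true = rep(1:3, each = 4), noise_sd = 0,
                      duration_s = 20, bands = canonical_bands("alpha"),
                      roi_size_range = c(500, 500))   # equal ROI sizes
  smp <- generate_tractography_sample(spec, "average", seed = 2)
  expect_identical(smp$counts, t(smp$counts))
  net <- build_structural_connectivity(smp)
  expected <- gfnet:::planted_weights(spec, "average")
  expect_equal(unname(net$weights), expected, tolerance = 1e-12)

  # with noise the two directions differ
  spec2 <- cohort_spec(n_rois = 12, n_high = 4, n_avg = 4, noise_sd = 0.3,
                       duration_s = 20, bands = canonical_bands("alpha"))
  smp2 <- generate_tractography_sample(spec2, "average", seed = 2)
  expect_gt(max(abs(smp2$counts - t(smp2$counts))), 0)
  expect_true(all(smp2$counts >= 0))
  expect_identical(smp2$counts,
                   generate_tractography_sample(spec2, "average", seed = 2)$counts)
})

test_that("planted group shifts are recovered from the built structural networks", {
  spec <- cohort_spec(n_rois = 20, n_high = 25, n_avg = 25,
                      partition_true = rep(1:4, each = 5),
                      group_inter_shift = 0.3, noise_sd = 0.15,
                      duration_s = 20, bands = canonical_bands("alpha"))
  same <- outer(spec$partition_true, spec$partition_true, "==")
  inter <- !same & upper.tri(same)
  mean_inter <- function(group, offs) {
    vals <- vapply(seq_len(25), function(i) {
      net <- build_structural_connectivity(
        generate_tractography_sample(spec, group, seed = 1000 + offs + i))
      mean(net$weights[inter])
    }, numeric(1))
    mean(vals)
  }
  hi <- mean_inter("high", 0)
  av <- mean_inter("average", 100)
  expect_equal(hi - av, 0.3, tolerance = 0.05)

  # intra-module counts exceed inter-module counts in expectation
  net <- build_structural_connectivity(
    generate_tractography_sample(spec, "average", seed = 7))
  expect_gt(mean(net$weights[same & upper.tri(same)]), mean(net$weights[inter]))
})

test_that("band time series carry the planted envelope correlations", {
  band <- canonical_bands("alpha")[[1]]
  tgt <- diag(6); tgt[1:3, 1:3] <- 0.8; diag(tgt) <- 1

  ts <- generate_band_timeseries(6, band, 150, 60, tgt, seed = 3)
  expect_identical(ts$data,
                   generate_band_timeseries(6, band, 150, 60, tgt, seed = 3)$data)
  env <- attr(ts, "envelopes")
  expect_true(all(env > 0))

  # true planted envelopes correlate at the target level (sampling error only)
  long <- generate_band_timeseries(6, band, 150, 300, tgt, seed = 4)
  cc <- cor(t(attr(long, "envelopes")))
  blk <- cc[1:3, 1:3][upper.tri(diag(3))]
  expect_lt(max(abs(blk - 0.8)), 0.15)
  expect_lt(max(abs(cc[1:3, 4:6])), 0.35)

  # identical envelopes for two regions -> recovered r ~ 1
  tgt2 <- diag(4); tgt2[1, 2] <- tgt2[2, 1] <- 1 - 1e-9; diag(tgt2) <- 1
  ts2 <- generate_band_timeseries(4, band, 150, 60, tgt2, seed = 5)
  fc <- build_functional_connectivity(bandpass_and_envelope(ts2, band))
  expect_gt(fc$weights[1, 2], 0.95)

  # parameter validation
  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(generate_band_timeseries(3, band, 150, 20, bad),
               "positive semidefinite")
  expect_error(generate_band_timeseries(3, frequency_band("x", 80, 90), 150, 20,
                                        diag(3)), "Nyquist")
})

test_that("identity-target recovery error shrinks within the sampling bound", {
  band <- canonical_bands("beta")[[1]]
  ts <- generate_band_timeseries(8, band, 150, 120, diag(8), seed = 6)
  fc <- build_functional_connectivity(bandpass_and_envelope(ts, band))
  # effective envelope samples ~ 2 * cutoff * T with cutoff 1 Hz
  t_eff <- 2 * 1 * 120
  expect_lt(max(abs(upper_tri <- fc$weights[upper.tri(fc$weights)])),
            4 / sqrt(t_eff))
})

test_that("cohort specification enforces its invariants", {
  expect_error(cohort_spec(n_high = 1), ">= 2")
  expect_error(cohort_spec(intra_weight_mean = 0.1, inter_weight_mean = 0.5),
               "intra_weight_mean >= inter_weight_mean")
  expect_error(cohort_spec(noise_sd = -0.1), "nonnegative")
  expect_error(cohort_spec(n_rois = 10, partition_true = rep(1, 9)), "assign")
  # gamma upper edge is Nyquist-capped rather than rejected at fs = 150
  sp <- cohort_spec(n_rois = 6, n_high = 3, n_avg = 3)
  expect_equal(nyquist_cap(sp$bands$gamma, sp$fs)$hi, 0.95 * 75)
})

test_that("subject tables include plausible covariates and both sexes", {
  spec <- cohort_spec(n_rois = 6, n_high = 30, n_avg = 30,
                      duration_s = 20, bands = canonical_bands("alpha"))
  tab <- generate_subject_table(spec, seed = 8)
  expect_equal(nrow(tab), 60)
  expect_true(all(tab$age > 0))
  expect_true(all(tab$education >= 0))
  expect_equal(nlevels(tab$sex), 2)
  expect_setequal(levels(tab$group), c("high", "average"))
})
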