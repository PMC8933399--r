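test_that("group assignment splits at the cohort mean and reports separation", {
  rec <- data.frame(subject_id = paste0("s", 1:4), gf = c(120, 118, 101, 100))
  sp <- assign_gf_groups(rec)
  expect_setequal(sp$high_ids, c("s1", "s2"))
  expect_equal(sp$mean_high - sp$mean_avg, 18.5)
  expect_equal(sp$separation_sd_units, 18.5 / 15)
  expect_false(sp$warning_low_separation)

  # symmetric scores -> equal group sizes
  rec2 <- data.frame(subject_id = paste0("s", 1:6),
                     gf = c(90, 95, 100, 110, 115, 120))
  sp2 <- suppressWarnings(assign_gf_groups(rec2))
  expect_equal(length(sp2$high_ids), 3)

  expect_error(assign_gf_groups(data.frame(subject_id = 1:4, gf = rep(5, 4))),
               "identical")
  expect_warning(assign_gf_groups(
    data.frame(subject_id = 1:4, gf = c(101, 102, 99, 98))), "SDs apart")
})

test_that("simulated populations at the published sizes give ~0.98 SD group separation", {
  # separation of the generated groups themselves: |117.72 - 102.98| / 15
  seps <- vapply(1:40, function(s) {
    tab <- generate_gf_scores(38, 31, seed = 3000 + s)
    abs(mean(tab$gf[tab$group == "high"]) -
          mean(tab$gf[tab$group == "average"])) / 15
  }, numeric(1))
  expect_lt(abs(mean(seps) - 14.74 / 15), 0.05)
  # re-splitting at the cohort mean can only push the group means apart
  resplit <- suppressWarnings(
    assign_gf_groups(generate_gf_scores(38, 31, seed = 3001)))
  expect_gte(resplit$separation_sd_units, 14.74 / 15 - 0.2)
})

test_that("Welch t from summaries matches published values and raw-data t-tests", {
  w <- welch_t_from_summary(117.72, 4.66, 38, 102.98, 6.09, 31)
  expect_equal(w$t, 11.08, tolerance = 0.005)
  expect_equal(floor(w$df), 55)
  expect_lt(w$p, 1e-7)

  expect_equal(welch_t_from_summary(10, 2, 9, 10, 3, 14)$t, 0)
  # equal sds and ns: df reduces to n1 + n2 - 2 exactly
  expect_equal(welch_t_from_summary(5, 2, 12, 4, 2, 12)$df, 22)

  # agreement with t.test on raw data whose summaries match, to 1e-9
  set.seed(99)
  for (i in 1:5) {
    x <- rnorm(15); y <- rnorm(12)
    ref <- t.test(x, y)
    got <- welch_t_from_summary(mean(x), sd(x), length(x),
                                mean(y), sd(y), length(y))
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
  }
  expect_error(welch_t_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("Bartlett pre-check behaves at the boundaries and under the null", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  b <- bartlett_test(x, x)
  expect_equal(b$statistic, 0)
  expect_equal(b$p, 1)

  set.seed(42)
  b2 <- bartlett_test(rnorm(20, sd = 1), rnorm(20, sd = 4))
  expect_lt(b2$p, 0.01)

  # calibration at nominal alpha under equal variances
  rej <- vapply(1:1000, function(i) {
    set.seed(i)
    bartlett_test(rnorm(15), rnorm(15))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)

  expect_error(bartlett_test(rep(1, 5), rnorm(5)), "variance")
})

test_that("MCS on exchangeable data gives null counts and unit p-values", {
  set.seed(10)
  m <- matrix(rnorm(20 * 30), 20, 30)
  # both "groups" hold the same values: duplicate subjects, shifted labels
  m2 <- rbind(m[1:10, ], m[1:10, ])
  groups <- rep(c("high", "average"), each = 10)
  r <- mcs_node_metric_test(m2, groups, n_perm = 300, seed = 1)
  expect_equal(r$n_pos, 0)
  expect_equal(r$n_neg, 0)
  expect_equal(r$p_pos, 1)
  expect_equal(r$p_neg, 1)
  expect_true(all(r$median_diff == 0))
})

test_that("MCS results are reproducible, bounded and label-swap symmetric", {
  set.seed(11)
  m <- matrix(rnorm(24 * 40), 24, 40)
  m[1:12, 1:10] <- m[1:12, 1:10] + 1.5
  groups <- rep(c("high", "average"), each = 12)
  r1 <- mcs_node_metric_test(m, groups, n_perm = 500, seed = 9)
  r2 <- mcs_node_metric_test(m, groups, n_perm = 500, seed = 9)
  expect_identical(r1[names(r1) != "fit"], r2[names(r2) != "fit"])
  expect_gte(r1$p_pos, 1 / 501)
  expect_gte(r1$p_neg, 1 / 501)
  expect_lte(r1$n_pos + r1$n_neg, 40)

  swapped <- ifelse(groups == "high", "average", "high")
  r3 <- mcs_node_metric_test(m, swapped, n_perm = 500, seed = 9)
  expect_identical(r3$n_pos, r1$n_neg)
  expect_identical(r3$n_neg, r1$n_pos)
  expect_identical(r3$p_pos, r1$p_neg)
  expect_identical(r3$p_neg, r1$p_pos)
})

test_that("MCS drops undefined ROIs listwise and reports them", {
  set.seed(12)
  m <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(NULL, paste0("R", 1:8)))
  m[3, 2] <- NA
  m[7, 5] <- Inf
  groups <- rep(c("high", "average"), each = 6)
  r <- mcs_node_metric_test(m, groups, n_perm = 100, seed = 2)
  expect_setequal(r$dropped_rois, c("R2", "R5"))
  expect_equal(length(r$median_diff), 6)
})

test_that("the identical MCS engine serves degree and segregation matrices", {
  spec <- cohort_spec(n_rois = 12, n_high = 6, n_avg = 6,
                      partition_true = rep(1:3, each = 4), noise_sd = 0.2,
                      duration_s = 20, bands = canonical_bands("alpha"))
  nets <- lapply(1:12, function(i) build_structural_connectivity(
    generate_tractography_sample(spec, if (i <= 6) "high" else "average",
                                 seed = 5000 + i)))
  groups <- rep(c("high", "average"), each = 6)
  deg <- t(sapply(nets, weighted_degree))
  part <- leading_eigenvector_communities(nets[[1]])
  seg <- t(sapply(nets, segregation_coefficient, partition = part))
  for (metric in list(deg, seg)) {
    r <- mcs_node_metric_test(metric, groups, n_perm = 200, seed = 3,
                              n_tests_for_bonferroni = 2)
    expect_s3_class(r, "mcs_result")
    expect_equal(r$alpha_corrected, 0.025)
    expect_gte(r$p_pos, 1 / 201)
  }
})

test_that("modularity null flags planted structure and never flags uniform networks", {
  pb <- planted_block_weights(30, 3, intra = 1, inter = 0.01, seed = 13)
  r <- modularity_null_test(snet(pb$w), n_perm = 100, seed = 4)
  expect_true(r$significant)
  expect_gt(r$q_observed, max(r$q_permuted))

  wu <- matrix(0.7, 20, 20); diag(wu) <- 0
  ru <- modularity_null_test(snet(wu), n_perm = 50, seed = 5)
  expect_false(ru$significant)
  expect_true(all(abs(ru$q_permuted - ru$q_observed) < 1e-12))

  expect_error(modularity_null_test(snet(matrix(0, 4, 4))), "zero")
  r2 <- modularity_null_test(snet(pb$w), n_perm = 100, seed = 4)
  expect_identical(r$q_permuted, r2$q_permuted)
})

test_that("ANCOVA recovers planted group effects and rejects degenerate designs", {
  set.seed(14)
  n <- 60
  group <- factor(rep(c("high", "average"), each = n / 2))
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  age <- rnorm(n, 25, 4)
  edu <- rnorm(n, 14, 3)
  y <- 0.1 * age + rnorm(n)
  y[group == "high"] <- y[group == "high"] + 2   # 2 residual SDs
  a <- ancova_global_metric(y, group, sex, age, edu)
  expect_equal(a$alpha_corrected, 0.05 / 24)
  expect_lt(a$p_values[a$term_names == "group"], 0.002)
  expect_setequal(a$term_names, c("group", "sex", "age", "education"))

  # agreement with an independent OLS F-test oracle for the group term
  full <- lm(y ~ group + sex + age + edu)
  red <- lm(y ~ sex + age + edu)
  f_oracle <- anova(red, full)$F[2]
  expect_equal(a$f_stats[a$term_names == "group"], f_oracle, tolerance = 1e-9)

  expect_error(ancova_global_metric(rep(1, n), group, sex, age, edu),
               "identical")
  expect_error(ancova_global_metric(y, group, sex, age, 2 * age), "collinear")
})

test_that("ANCOVA group-term p-values are calibrated under the null", {
  set.seed(15)
  n <- 40
  group <- factor(rep(c("high", "average"), each = n / 2))
  sex <- factor(rep(c("F", "M"), n / 2))
  p <- vapply(1:400, function(i) {
    age <- rnorm(n, 25, 4); edu <- rnorm(n, 14, 3)
    y <- rnorm(n) + 0.05 * age
    a <- ancova_global_metric(y, group, sex, age, edu)
    a$p_values[a$term_names == "group"]
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("SC-FC similarity per subject feeds the group ANCOVA correctly", {
  set.seed(16)
  n_sub <- 24
  groups <- rep(c("high", "average"), each = n_sub / 2)
  cov <- data.frame(sex = factor(rep(c("F", "M"), n_sub / 2)),
                    age = rnorm(n_sub, 25, 3), education = rnorm(n_sub, 14, 2))
  sc <- lapply(1:n_sub, function(i) snet(random_weights(10, 0.8, 6000 + i)))
  # high group FC tracks SC, average group FC is independent noise
  fc <- lapply(1:n_sub, function(i) {
    base <- if (i <= n_sub / 2) 0.5 * sc[[i]]$weights else 0
    w <- base + random_weights(10, 1, 7000 + i) * 0.2
    w <- w / max(w)
    weighted_network(w, sc[[i]]$roi_labels, "functional", "alpha")
  })
  res <- sc_fc_similarity_test(sc, list(alpha = fc), groups, cov,
                               n_comparisons = 1)
  expect_named(res, "alpha")
  r <- res$alpha$r
  expect_gt(mean(r[1:12]), mean(r[13:24]))
  expect_lt(res$alpha$ancova$p_values[res$alpha$ancova$term_names == "group"],
            0.05)

  # FC == SC -> all r = 1 -> degenerate response flagged
  fc_same <- lapply(sc, function(s)
    weighted_network(s$weights / max(s$weights), s$roi_labels, "functional",
                     "alpha"))
  sc_unit <- lapply(sc, function(s)
    weighted_network(s$weights / max(s$weights), s$roi_labels, "structural"))
  expect_error(sc_fc_similarity_test(sc_unit, list(alpha = fc_same), groups,
                                     cov), "identical|degenerate")
})
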