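#' Configuration of an end-to-end pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort from `spec`) or `"files"`
#'   (read a cohort directory written by [write_synthetic_cohort()] or by
#'   upstream tooling in the same formats).
#' @param spec a [cohort_spec] (synthetic mode).
#' @param dir cohort directory (files mode).
#' @param bands band names to analyse (default: the spec's bands, or all
#'   bands found on disk).
#' @param n_perm_node permutations for the node-metric tests (default 10000).
#' @param n_perm_modularity permutations for the modularity null (default
#'   1000).
#' @param alpha nominal significance level.
#' @param bonferroni_structural,bonferroni_functional,bonferroni_global
#'   Bonferroni denominators: 2 (one structural network, two tails), 10
#'   (five bands x two tails) and 24 (four global measures x five bands + 4
#'   structural) by default.
#' @param prune_fraction weakest-edge fraction removed before density.
#' @param group_by `"gf_split"` derives the groups by splitting at the cohort
#'   mean Gf (the study procedure); `"label"` trusts the cohort table's group
#'   column.
#' @param seed master seed; every stage derives its own stream from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), spec = NULL,
                       dir = NULL, bands = NULL,
                       n_perm_node = 10000, n_perm_modularity = 1000,
                       alpha = 0.05, bonferroni_structural = 2,
                       bonferroni_functional = 10, bonferroni_global = 24,
                       prune_fraction = 0.01,
                       group_by = c("gf_split", "label"), seed = 1) {
  mode <- match.arg(mode)
  group_by <- match.arg(group_by)
  if (mode == "synthetic" && !inherits(spec, "cohort_spec"))
    stop("synthetic mode requires a cohort_spec")
  if (mode == "files" && (is.null(dir) || !dir.exists(dir)))
    stop("files mode requires an existing cohort directory")
  if (bonferroni_structural < 1 || bonferroni_functional < 1 ||
      bonferroni_global < 1) stop("Bonferroni denominators must be positive")
  if (is.null(bands) && mode == "synthetic") bands <- names(spec$bands)
  structure(list(mode = mode, spec = spec, dir = dir, bands = bands,
                 n_perm_node = n_perm_node,
                 n_perm_modularity = n_perm_modularity, alpha = alpha,
                 bonferroni_structural = bonferroni_structural,
                 bonferroni_functional = bonferroni_functional,
                 bonferroni_global = bonferroni_global,
                 prune_fraction = prune_fraction, group_by = group_by,
                 seed = seed), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `spec:` block
#' mirrors [cohort_spec()] (with `bands:` as a list of canonical band names).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$spec)) {
    sp <- y$spec
    if (!is.null(sp$bands)) sp$bands <- canonical_bands(unlist(sp$bands))
    if (!is.null(sp$partition_true)) sp$partition_true <- unlist(sp$partition_true)
    y$spec <- do.call(cohort_spec, sp)
  }
  do.call(run_config, y)
}

# build per-subject networks, streaming subject by subject
cohort_networks <- function(config) {
  seed <- config$seed
  if (config$mode == "synthetic") {
    spec <- config$spec
    subjects <- generate_subject_table(spec, stage_seed(seed, STAGE$covariates))
    bands <- config$bands
    band_objs <- spec$bands[bands]
    ns <- nrow(subjects)
    sc <- vector("list", ns)
    fc <- lapply(bands, function(b) vector("list", ns))
    names(fc) <- bands
    for (i in seq_len(ns)) {
      g <- as.character(subjects$group[i])
      smp <- generate_tractography_sample(spec, g,
                                          stage_seed(seed, STAGE$tractography, i))
      sc[[i]] <- build_structural_connectivity(smp)
      for (b in seq_along(spec$bands)) {
        bname <- names(spec$bands)[b]
        if (!bname %in% bands) next
        tsb <- generate_band_timeseries(
          spec$n_rois, spec$bands[[b]], spec$fs, spec$duration_s,
          fc_target_matrix(spec, g, bname),
          seed = stage_seed(seed, STAGE$timeseries,
                            (i - 1L) * length(spec$bands) + b))
        fc[[bname]][[i]] <- build_functional_connectivity(
          bandpass_and_envelope(tsb, spec$bands[[b]]))
      }
    }
  } else {
    subjects <- read_cohort_csv(file.path(config$dir, "cohort.csv"))
    ids <- subjects$subject_id
    bands <- config$bands
    if (is.null(bands)) {
      hits <- list.files(config$dir, pattern = paste0("^", ids[1], "_ts_.*\\.csv$"))
      bands <- sub("\\.csv$", "", sub(paste0("^", ids[1], "_ts_"), "", hits))
    }
    ns <- length(ids)
    sc <- vector("list", ns)
    fc <- lapply(bands, function(b) vector("list", ns))
    names(fc) <- bands
    for (i in seq_len(ns)) {
      id <- ids[i]
      counts <- read_square_csv(file.path(config$dir, paste0(id, "_counts.csv")))
      sz <- utils::read.csv(file.path(config$dir, paste0(id, "_sizes.csv")),
                            stringsAsFactors = FALSE)
      sc[[i]] <- build_structural_connectivity(
        tractography_sample(counts, sz$size, rownames(counts)))
      for (bname in bands) {
        tsb <- read_timeseries_csv(file.path(config$dir,
                                             paste0(id, "_ts_", bname, ".csv")))
        fc[[bname]][[i]] <- build_functional_connectivity(
          bandpass_and_envelope(tsb, tsb$band))
      }
    }
  }
  names(sc) <- subjects$subject_id
  for (b in names(fc)) names(fc[[b]]) <- subjects$subject_id
  list(subjects = subjects, sc = sc, fc = fc, bands = bands)
}

mean_network <- function(nets) {
  w <- Reduce(`+`, lapply(nets, function(n) clip_negative_weights(n)$weights)) /
    length(nets)
  tmpl <- nets[[1]]
  weighted_network(w, tmpl$roi_labels, tmpl$modality, tmpl$band)
}

metric_matrix <- function(nets, fun, ...) {
  m <- t(vapply(nets, function(net) fun(clip_negative_weights(net), ...),
                numeric(n_rois(nets[[1]]))))
  rownames(m) <- names(nets)
  m
}

analyse_modality <- function(nets, groups, config, n_tests, stage_offset) {
  seed <- config$seed
  deg <- metric_matrix(nets, weighted_degree)
  deg_subject_mean <- rowMeans(deg)
  bartlett <- bartlett_test(deg_subject_mean[groups == "high"],
                            deg_subject_mean[groups != "high"])
  mcs_deg <- mcs_node_metric_test(deg, groups, config$n_perm_node,
                                  config$alpha, n_tests,
                                  seed = stage_seed(seed, STAGE$mcs_degree,
                                                    stage_offset))
  mnet <- mean_network(nets)
  mod_null <- modularity_null_test(mnet, config$n_perm_modularity,
                                   seed = stage_seed(seed, STAGE$modularity_null,
                                                     stage_offset))
  part <- mod_null$partition
  seg <- t(vapply(nets, function(net)
    segregation_coefficient(clip_negative_weights(net), part),
    numeric(n_rois(nets[[1]]))))
  rownames(seg) <- names(nets)
  mcs_seg <- mcs_node_metric_test(seg, groups, config$n_perm_node,
                                  config$alpha, n_tests,
                                  seed = stage_seed(seed, STAGE$mcs_segregation,
                                                    stage_offset))
  glob <- lapply(nets, function(net)
    global_metrics(clip_negative_weights(net), config$prune_fraction))
  glob <- do.call(rbind, lapply(glob, function(g)
    data.frame(char_path_length = g$char_path_length,
               global_efficiency = g$global_efficiency,
               local_efficiency = g$local_efficiency, density = g$density)))
  list(bartlett_degree = bartlett, degree_mcs = mcs_deg,
       modularity_null = mod_null, partition = part,
       segregation_mcs = mcs_seg, global = glob)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in analysis order for every modality: connectivity
#' construction, Bartlett variance pre-check and whole-brain degree MCS,
#' group-level community structure with the edge-shuffle modularity null,
#' segregation-coefficient MCS (using the grand-mean network's partition
#' applied to every subject), global graph measures compared by ANCOVA with
#' group and sex as factors and age and education as covariates, and the
#' per-subject SC-FC similarity ANCOVA.  Identical config and seed give an
#' identical report; synthetic mode and files mode on a directory written by
#' [write_synthetic_cohort()] with the same seed give identical reports.
#'
#' @param config a [run_config].
#' @return An object of class `gf_run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  nets <- cohort_networks(config)
  subjects <- nets$subjects

  if (config$group_by == "gf_split") {
    split <- suppressWarnings(assign_gf_groups(subjects))
    groups <- ifelse(subjects$subject_id %in% split$high_ids, "high", "average")
  } else {
    split <- suppressWarnings(assign_gf_groups(subjects))
    groups <- as.character(subjects$group)
  }
  welch <- welch_t_from_summary(split$mean_high, split$sd_high,
                                length(split$high_ids),
                                split$mean_avg, split$sd_avg,
                                length(split$avg_ids))

  structural <- analyse_modality(nets$sc, groups, config,
                                 config$bonferroni_structural, 0L)
  functional <- lapply(seq_along(nets$bands), function(b)
    analyse_modality(nets$fc[[b]], groups, config,
                     config$bonferroni_functional, b))
  names(functional) <- nets$bands

  # ANCOVA on each global measure, each network, at alpha / bonferroni_global
  global_ancova <- list()
  all_mod <- c(list(structural = structural), functional)
  for (mname in names(all_mod)) {
    gl <- all_mod[[mname]]$global
    for (metric in colnames(gl)) {
      key <- paste(mname, metric, sep = ".")
      global_ancova[[key]] <- tryCatch(
        ancova_global_metric(gl[[metric]], groups, subjects$sex,
                             subjects$age, subjects$education,
                             config$alpha, config$bonferroni_global),
        error = function(e) e$message)
    }
  }

  scfc <- tryCatch(
    sc_fc_similarity_test(nets$sc, nets$fc, groups,
                          subjects[, c("sex", "age", "education")],
                          config$alpha),
    error = function(e) e$message)

  structure(list(
    config = config, subjects = subjects, groups = groups,
    group_split = split, welch = welch,
    structural = structural, functional = functional,
    global_ancova = global_ancova, sc_fc = scfc,
    provenance = list(seed = config$seed,
                      package_version = as.character(utils::packageVersion("gfnet")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "gf_run_report")
}

#' @export
print.gf_run_report <- function(x, ...) {
  cat("<gf_run_report>\n")
  cat(sprintf("  cohort: %d subjects (%d high / %d average), separation %.2f SDs\n",
              nrow(x$subjects), sum(x$groups == "high"),
              sum(x$groups != "high"), x$group_split$separation_sd_units))
  cat(sprintf("  Gf Welch t = %.2f (df = %.1f)\n", x$welch$t, x$welch$df))
  show <- function(name, mod) {
    cat(sprintf("  %-10s degree MCS: +%d/-%d ROIs (p = %.3g / %.3g); segregation MCS: +%d/-%d (p = %.3g / %.3g); Q = %.3f%s\n",
                name, mod$degree_mcs$n_pos, mod$degree_mcs$n_neg,
                mod$degree_mcs$p_pos, mod$degree_mcs$p_neg,
                mod$segregation_mcs$n_pos, mod$segregation_mcs$n_neg,
                mod$segregation_mcs$p_pos, mod$segregation_mcs$p_neg,
                mod$modularity_null$q_observed,
                if (mod$modularity_null$significant) "*" else ""))
  }
  show("structural", x$structural)
  for (b in names(x$functional)) show(b, x$functional[[b]])
  invisible(x)
}

#' @export
summary.gf_run_report <- function(object, ...) {
  x <- object
  mods <- c(list(structural = x$structural), x$functional)
  tab <- do.call(rbind, lapply(names(mods), function(m) {
    md <- mods[[m]]
    data.frame(network = m,
               degree_n_pos = md$degree_mcs$n_pos,
               degree_n_neg = md$degree_mcs$n_neg,
               degree_p_pos = md$degree_mcs$p_pos,
               degree_p_neg = md$degree_mcs$p_neg,
               seg_n_pos = md$segregation_mcs$n_pos,
               seg_n_neg = md$segregation_mcs$n_neg,
               seg_p_pos = md$segregation_mcs$p_pos,
               seg_p_neg = md$segregation_mcs$p_neg,
               q = md$modularity_null$q_observed,
               q_significant = md$modularity_null$significant)
  }))
  structure(list(table = tab, welch = x$welch, split = x$group_split),
            class = "summary.gf_run_report")
}

#' @export
print.summary.gf_run_report <- function(x, ...) {
  cat("Group split:\n"); print(x$split)
  cat(sprintf("Gf Welch t = %.2f, df = %.2f, p = %.3g\n\n",
              x$welch$t, x$welch$df, x$welch$p))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the headline numbers (counts, p-values, modularity, ANCOVA F/p
#' tables) with full precision; permutation distributions are included only
#' if `full = TRUE`.
#'
#' @param report a `gf_run_report`.
#' @param path output file.
#' @param full include permutation distributions.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path, full = FALSE) {
  stopifnot(inherits(report, "gf_run_report"))
  strip <- function(mod) {
    list(degree_mcs = unclass(mod$degree_mcs)[if (full)
      TRUE else !names(unclass(mod$degree_mcs)) %in%
        c("perm_counts_pos", "perm_counts_neg")],
      modularity = list(q = mod$modularity_null$q_observed,
                        significant = mod$modularity_null$significant,
                        percentile = mod$modularity_null$percentile),
      segregation_mcs = unclass(mod$segregation_mcs)[if (full)
        TRUE else !names(unclass(mod$segregation_mcs)) %in%
          c("perm_counts_pos", "perm_counts_neg")],
      global = mod$global)
  }
  out <- list(
    seed = report$provenance$seed,
    package_version = report$provenance$package_version,
    n_subjects = nrow(report$subjects),
    welch = report$welch,
    separation_sd_units = report$group_split$separation_sd_units,
    structural = strip(report$structural),
    functional = lapply(report$functional, strip),
    global_ancova = lapply(report$global_ancova, function(a)
      if (is.character(a)) a else
        list(terms = a$term_names, f = a$f_stats, p = a$p_values)),
    sc_fc = if (is.character(report$sc_fc)) report$sc_fc else
      lapply(report$sc_fc, function(b)
        list(r_mean = mean(b$r),
             group_p = b$ancova$p_values[b$ancova$term_names == "group"])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
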