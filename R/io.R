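#' Read and write labelled square matrices as CSV
#'
#' The on-disk dialect is plain CSV, UTF-8, '.' decimal: first row = ROI
#' labels, first column = ROI labels, cells = weights.  Values are written
#' with 17 significant digits so that a write/read round trip reproduces the
#' doubles bit-exactly.  `read_matrix_csv` validates squareness and (for
#' networks) symmetry.
#'
#' @param x a [weighted_network], a [tractography_sample] count matrix, or a
#'   labelled square numeric matrix.
#' @param path file path.
#' @name matrix_csv
NULL

fmt_num <- function(v) sprintf("%.17g", v)

write_square_csv <- function(mat, path) {
  labels <- rownames(mat)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(mat)))
  if (any(grepl("[,\"\n]", labels)))
    stop("ROI labels must not contain commas, quotes or newlines")
  header <- paste(c("", labels), collapse = ",")
  rows <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(labels[i], fmt_num(mat[i, ])), collapse = ","), character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

read_square_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (nrow(mat) != ncol(mat))
    stop("matrix in '", path, "' is not square")
  if (!identical(labels, colnames(mat)))
    stop("row and column labels disagree in '", path, "'")
  rownames(mat) <- labels
  mat
}

#' @rdname matrix_csv
#' @param modality,band passed to [weighted_network()] when reading a network.
#' @return `read_matrix_csv` returns a [weighted_network];
#'   `write_matrix_csv` invisibly returns `path`.
#' @export
write_matrix_csv <- function(x, path) {
  mat <- if (inherits(x, "weighted_network")) x$weights else x
  write_square_csv(mat, path)
}

#' @rdname matrix_csv
#' @export
read_matrix_csv <- function(path, modality = c("structural", "functional"),
                            band = NULL) {
  mat <- read_square_csv(path)
  weighted_network(mat, rownames(mat), match.arg(modality), band)
}

#' Read and write region time series as CSV plus a JSON sidecar
#'
#' Rows are labelled regions, columns are samples.  The sampling rate and band
#' tag are carried in a sidecar JSON file (same path with extension `.json`),
#' e.g. `{"fs": 150, "band": "alpha", "lo": 8, "hi": 12}`.
#'
#' @param ts a [band_timeseries].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `read_timeseries_csv` returns a [band_timeseries];
#'   `write_timeseries_csv` invisibly returns `path`.
#' @name timeseries_csv
NULL

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' @rdname timeseries_csv
#' @export
write_timeseries_csv <- function(ts, path) {
  stopifnot(inherits(ts, "band_timeseries"))
  labels <- ts$roi_labels
  rows <- vapply(seq_len(nrow(ts$data)), function(i)
    paste(c(labels[i], fmt_num(ts$data[i, ])), collapse = ","), character(1))
  writeLines(c(paste(c("region", paste0("s", seq_len(ncol(ts$data)))), collapse = ","),
               rows), path, useBytes = TRUE)
  meta <- list(fs = ts$fs, band = ts$band$name, lo = ts$band$lo, hi = ts$band$hi)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  data <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(data) <- "double"
  dimnames(data) <- list(labels, NULL)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  band_timeseries(data, fs = meta$fs,
                  band = frequency_band(meta$band, meta$lo, meta$hi),
                  roi_labels = labels)
}

#' Read and write the cohort table
#'
#' Columns: `subject_id, group, gf, age, sex, education`.
#'
#' @param subjects data frame with the columns above.
#' @param path CSV file path.
#' @return `read_cohort_csv` returns the data frame with `group` and `sex`
#'   as factors.
#' @export
write_cohort_csv <- function(subjects, path) {
  need <- c("subject_id", "group", "gf", "age", "sex", "education")
  if (!all(need %in% names(subjects)))
    stop("cohort table must have columns ", paste(need, collapse = ", "))
  out <- subjects[, need]
  for (col in c("gf", "age", "education")) out[[col]] <- fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$group <- factor(df$group, levels = c("high", "average"))
  df$sex <- factor(df$sex)
  df
}
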