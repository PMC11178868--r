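# File formats: FASTQ in, sample sheets and category counts as CSV/TSV,
# fits and flows as JSON. All coordinates in files are 0-based half-open.

#' Read consensus reads from a FASTQ file
#'
#' @param path FASTQ file, optionally gzipped.
#' @return Named character vector of read sequences (qualities, when present,
#'   attached as attribute `"qualities"`).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  out <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  q <- S4Vectors::mcols(x)$qualities
  if (!is.null(q)) attr(out, "qualities") <- as.character(q)
  out
}

#' Write reads to a FASTQ file
#'
#' @param reads Named character vector of sequences.
#' @param path Output path; a `.gz` suffix writes gzip-compressed.
#' @param qualities Optional quality strings (constant "I" when missing).
#' @export
write_fastq <- function(reads, path, qualities = NULL) {
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  if (is.null(qualities))
    qualities <- vapply(nchar(reads), function(n)
      paste(rep("I", n), collapse = ""), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qualities), con)
  invisible(path)
}

#' Read a sample sheet of CRISPR targets
#'
#' Plain-text (CSV, or TSV for `.tsv`/`.txt` extensions) sheet with one row
#' per target. Required columns: `name`, `sgrna`, `primer`, `amplicon`.
#' Optional: `cut_index` (0-based; derived from the sgRNA by the 3-bp-from-
#' PAM rule when absent), `pam_side`, `direct_positions` (semicolon-
#' separated offsets, e.g. `"0;-1"`), `mh_min_len`.
#'
#' @param path Sample sheet file.
#' @return Named list of [target_spec()] objects.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  req <- c("name", "sgrna", "primer", "amplicon")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("sample sheet lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate target names in sample sheet: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  targets <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    dp <- if ("direct_positions" %in% names(df) &&
              nzchar(trimws(as.character(row$direct_positions) %||% ""))) {
      as.integer(strsplit(as.character(row$direct_positions), ";")[[1]])
    } else 0L
    target_spec(
      name = row$name, sgrna = row$sgrna, primer = row$primer,
      amplicon = row$amplicon,
      cut_index = if ("cut_index" %in% names(df) && !is.na(row$cut_index))
        as.integer(row$cut_index) else NULL,
      pam_side = if ("pam_side" %in% names(df) && !is.na(row$pam_side) &&
                     nzchar(row$pam_side)) row$pam_side else NULL,
      direct_positions = dp,
      mh_min_len = if ("mh_min_len" %in% names(df) && !is.na(row$mh_min_len))
        as.integer(row$mh_min_len) else 2L)
  })
  setNames(targets, df$name)
}

#' Read / write category-count tables
#'
#' CSV with columns `sample_id`, `time_h`, `replicate`, `is_control`,
#' `intact`, `indel`, `dsb_direct`, `dsb_processed`, `n_na`.
#'
#' @param path CSV file.
#' @return `category_counts` data.frame.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "time_h", "replicate", "is_control",
           dsb_categories(), "n_na")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("counts file lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df[dsb_categories()] < 0)) stop("negative counts")
  df$is_control <- as.logical(df$is_control)
  class(df) <- c("category_counts", "data.frame")
  df
}

#' @rdname read_counts
#' @param counts `category_counts` data.frame.
#' @export
write_counts <- function(counts, path) {
  write.csv(as.data.frame(counts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

DSBFLOW_SCHEMA_VERSION <- "1.0"

#' Write a fit (or flows) to JSON
#'
#' JSON output carries a `schema_version` field and is byte-stable for fixed
#' inputs and seeds.
#'
#' @param fit A [fit_kinetics()] result.
#' @param path Output path.
#' @param bootstrap Optional [stratified_bootstrap()] result to embed
#'   (CIs and p-values; the raw draws belong in a CSV, see
#'   [write_bootstrap_csv()]).
#' @export
write_fit_json <- function(fit, path, bootstrap = NULL) {
  obj <- list(
    schema_version = DSBFLOW_SCHEMA_VERSION,
    model = fit$model,
    estimates = fit$estimates,
    loglik = fit$loglik, aic = fit$aic, n_params = fit$n_params,
    converged = fit$converged, start_count = fit$start_count)
  if (!is.null(bootstrap)) {
    obj$ci_low <- as.list(bootstrap$ci["ci_low", ])
    obj$ci_high <- as.list(bootstrap$ci["ci_high", ])
    obj$p_values <- as.list(bootstrap$p_labels)
    obj$bootstrap_B <- bootstrap$B
    obj$bootstrap_failures <- bootstrap$failures
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_fit_json
#' @param flows A [compute_flows()] result.
#' @export
write_flows_json <- function(flows, path) {
  obj <- c(list(schema_version = DSBFLOW_SCHEMA_VERSION),
           flows[setdiff(names(flows), "end_state")],
           list(end_state = as.list(flows$end_state)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write bootstrap parameter draws as CSV
#'
#' @param boot A [stratified_bootstrap()] result.
#' @param path Output path.
#' @export
write_bootstrap_csv <- function(boot, path) {
  write.csv(as.data.frame(boot$estimates), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
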