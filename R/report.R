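#' Append per-nucleus results to a cumulative batch file
#'
#' The batch CSV accumulates one row per nucleus across samples
#' (`sample_id, nucleus_id, cell_type, count_<channel>...`).  Appending never
#' rewrites existing rows; re-submitting a `(sample_id, nucleus_id)` already
#' present is a conflict, not a silent duplicate.  The CSV schema is the
#' canonical interchange format; it loads directly into any spreadsheet.
#'
#' @param results Tibble of new rows (must contain `sample_id` and
#'   `nucleus_id`).
#' @param batch_path Path of the batch CSV (created on first write).
#' @return Invisibly, `batch_path`.
#' @export
write_batch_results <- function(results, batch_path) {
  results <- tibble::as_tibble(results)
  if (!all(c("sample_id", "nucleus_id") %in% names(results))) {
    abort("batch rows need `sample_id` and `nucleus_id` columns")
  }
  if (anyDuplicated(results[c("sample_id", "nucleus_id")])) {
    abort("duplicate (sample_id, nucleus_id) among the new rows")
  }
  if (file.exists(batch_path)) {
    existing <- tryCatch(
      readr::read_csv(batch_path, show_col_types = FALSE, progress = FALSE),
      error = function(e) abort(sprintf("corrupt batch file %s: %s",
                                        batch_path, conditionMessage(e))))
    if (!all(c("sample_id", "nucleus_id") %in% names(existing))) {
      abort(sprintf("corrupt batch file %s: missing key columns", batch_path))
    }
    if (!identical(names(existing), names(results))) {
      abort(sprintf("batch file %s has columns [%s], new rows have [%s]",
                    batch_path, paste(names(existing), collapse = ", "),
                    paste(names(results), collapse = ", ")))
    }
    key_new <- paste(results$sample_id, results$nucleus_id)
    key_old <- paste(existing$sample_id, existing$nucleus_id)
    clash <- intersect(key_new, key_old)
    if (length(clash)) {
      abort(sprintf("batch file already contains rows for: %s",
                    paste(clash, collapse = "; ")))
    }
    readr::write_csv(results, batch_path, append = TRUE, progress = FALSE)
  } else {
    readr::write_csv(results, batch_path, progress = FALSE)
  }
  invisible(batch_path)
}

#' Read a cumulative batch file
#'
#' @param batch_path Batch CSV written by [write_batch_results()].
#' @return Tibble of all accumulated rows.
#' @export
read_batch_results <- function(batch_path) {
  if (!file.exists(batch_path)) abort(sprintf("batch file not found: %s", batch_path))
  readr::read_csv(batch_path, show_col_types = FALSE, progress = FALSE)
}

required_metadata_keys <- c("sample_id", "version", "config")

#' Save or load run metadata
#'
#' Every parameter consumed by a run is serialized to one human-readable
#' YAML file per sample, including any segmentation correction edits, so a
#' run can be re-established exactly later: re-running from a loaded
#' metadata file reproduces the original output tables bit-for-bit on the
#' same inputs.  `load_metadata()` accepts per-key overrides (dotted paths
#' into the config) so individual parameters can be changed while keeping
#' the rest.
#'
#' @param meta A `RunMetadata`-like list: `sample_id`, `version`, `config`
#'   (full parameter tree), optional `corrections`, `seed`, `created`.
#' @param path YAML file path.
#' @return `save_metadata()` returns `path` invisibly; `load_metadata()`
#'   returns the metadata list.
#' @export
save_metadata <- function(meta, path) {
  missing <- setdiff(required_metadata_keys, names(meta))
  if (length(missing)) {
    abort(sprintf("metadata incomplete: missing %s", paste(missing, collapse = ", ")))
  }
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' @rdname save_metadata
#' @param overrides Named list; names are dotted paths into the config
#'   (e.g. `"segmentation.min_depth"`), values replace the stored ones.
#' @export
load_metadata <- function(path, overrides = list()) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  meta <- yaml::read_yaml(path)
  missing <- setdiff(required_metadata_keys, names(meta))
  if (length(missing)) {
    abort(sprintf("metadata schema error: missing key(s) %s",
                  paste(missing, collapse = ", ")))
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    meta$config[[parts]] <- overrides[[key]]
  }
  meta
}

#' Save the per-step QC images of a run
#'
#' One PNG per completed stage (filtering, detection, segmentation,
#' assignment, quantification) plus a final pseudocolour composite; file
#' names are deterministic functions of the sample id and step name, and the
#' files themselves are deterministic functions of the run artifacts.
#' A partial run produces images only for its completed stages.
#'
#' @param run A `fish_run` from [run_pipeline()] (possibly partial).
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
save_step_images <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- run$experiment
  id <- run$sample_id
  paths <- character(0)
  pth <- function(step) file.path(out_dir, sprintf("%s_%s.png", id, step))
  tc <- channel_names(exp, "transcript")[1]
  if (!is.null(run$filtered)) {
    p <- pth("1_filtering")
    render_filter_qc(max_project(exp$channels[[tc]]),
                     max_project(run$filtered[[tc]]), p)
    paths <- c(paths, p)
  }
  if (!is.null(run$spots) && !is.null(run$filtered)) {
    p <- pth("2_detection")
    rep <- categorize_spots(run$spots[run$spots$channel == tc | is.na(run$spots$channel), ],
                            run$report_bounds[1], run$report_bounds[2])
    render_detection_overlay(run$filtered[[tc]], rep, p)
    paths <- c(paths, p)
  }
  if (!is.null(run$labelmap)) {
    p <- pth("3_segmentation")
    render_segmentation(run$labelmap,
                        max_project(exp$channels[[channel_names(exp, "nuclei")]]), p)
    paths <- c(paths, p)
  }
  if (!is.null(run$assignments)) {
    p <- pth("4_assignment")
    render_assignment(exp, run$labelmap, run$assignments, p)
    paths <- c(paths, p)
  }
  if (!is.null(run$counts)) {
    p <- pth("5_quantification")
    rep5 <- categorize_spots(run$spots, -Inf, Inf)
    render_detection_overlay(run$filtered[[tc]], rep5, p)
    paths <- c(paths, p)
    p <- pth("composite")
    render_composite(exp, run$labelmap, run$counts, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
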