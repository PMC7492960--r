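#' Readers and writers for the trial CSV schemas
#'
#' All files are comma-separated, UTF-8, header row, `.` decimal point,
#' ISO-8601 timestamps. Schemas:
#'
#' * annotations: `neonate_id, annotator_id, start_s, end_s` (one row per
#'   raw expert event);
#' * clinical: `neonate_id, hour_index, form_marked, asm_given`
#'   (+ optional `asm_therapeutic`, default 1);
#' * metadata: `neonate_id, hospital, group, recording_duration_h`
#'   (+ optional `start_datetime`, required only for weekday/shift
#'   stratification).
#'
#' @name trial-io
NULL

read_schema <- function(path, required, col_types) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  x
}

#' @rdname trial-io
#' @param path file path. For annotations, `path` may be a character vector
#'   of several files (one per annotator), concatenated.
#' @export
read_annotations <- function(path) {
  dplyr::bind_rows(lapply(path, read_schema,
                          required = c("neonate_id", "annotator_id",
                                       "start_s", "end_s")))
}

#' @rdname trial-io
#' @export
read_clinical <- function(path) {
  read_schema(path, c("neonate_id", "hour_index", "form_marked", "asm_given"))
}

#' @rdname trial-io
#' @export
read_metadata <- function(path) {
  x <- read_schema(path, c("neonate_id", "hospital", "group",
                           "recording_duration_h"))
  if ("start_datetime" %in% names(x) && inherits(x$start_datetime, "POSIXt")) {
    x$start_datetime <- format(x$start_datetime, "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC")
  }
  x
}

#' @rdname trial-io
#' @param cohort a cohort list as produced by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `write_cohort` returns the written paths invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    annotations_expert1 = file.path(dir, "annotations_expert1.csv"),
    annotations_expert2 = file.path(dir, "annotations_expert2.csv"),
    clinical = file.path(dir, "clinical.csv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.json")
  )
  ann <- cohort$annotations
  readr::write_csv(ann[ann$annotator_id == "E1", ], paths["annotations_expert1"])
  readr::write_csv(ann[ann$annotator_id == "E2", ], paths["annotations_expert2"])
  readr::write_csv(cohort$clinical, paths["clinical"])
  readr::write_csv(cohort$metadata, paths["metadata"])
  jsonlite::write_json(cohort$truth, paths["truth"], digits = NA,
                       auto_unbox = TRUE, pretty = FALSE)
  invisible(paths)
}

#' Validate trial input tables
#'
#' Checks interval sanity (end > start; events at least 10 s, the
#' electrographic seizure definition), hour contiguity, duplicate ids,
#' group labels, and reconciliation between annotations and metadata.
#' Problems are split into errors (the pipeline refuses to run) and
#' warnings (handled with documented fallbacks, e.g. missing hour rows are
#' treated as blank).
#'
#' @param annotations,clinical,metadata data frames (see [trial-io]).
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(annotations, clinical, metadata) {
  errors <- character(0)
  warnings <- character(0)
  bad <- which(!(annotations$end_s > annotations$start_s))
  for (r in utils::head(bad, 10)) {
    errors <- c(errors, sprintf(
      "annotations row %d (neonate %s): end_s <= start_s", r,
      annotations$neonate_id[r]))
  }
  short <- which(annotations$end_s - annotations$start_s < 10 - 1e-9 &
                   annotations$end_s > annotations$start_s)
  if (length(short) > 0) {
    warnings <- c(warnings, sprintf(
      "%d annotated event(s) shorter than the 10 s seizure definition",
      length(short)))
  }
  if (any(annotations$start_s < 0)) {
    errors <- c(errors, "annotations: negative start_s")
  }
  n_ann <- length(unique(annotations$annotator_id))
  if (n_ann != 2) {
    errors <- c(errors, sprintf("expected exactly 2 annotators, found %d", n_ann))
  }
  if (anyDuplicated(metadata$neonate_id)) {
    errors <- c(errors, "metadata: duplicate neonate_id")
  }
  if (!all(metadata$group %in% c("algorithm", "non_algorithm"))) {
    errors <- c(errors, "metadata: group must be algorithm/non_algorithm")
  }
  if (any(metadata$recording_duration_h <= 0)) {
    errors <- c(errors, "metadata: non-positive recording_duration_h")
  }
  extra <- setdiff(unique(annotations$neonate_id), metadata$neonate_id)
  if (length(extra) > 0) {
    errors <- c(errors, sprintf(
      "annotations contain neonate(s) absent from metadata: %s",
      paste(utils::head(extra, 5), collapse = ", ")))
  }
  extra_c <- setdiff(unique(clinical$neonate_id), metadata$neonate_id)
  if (length(extra_c) > 0) {
    errors <- c(errors, sprintf(
      "clinical records contain neonate(s) absent from metadata: %s",
      paste(utils::head(extra_c, 5), collapse = ", ")))
  }
  for (id in intersect(unique(clinical$neonate_id), metadata$neonate_id)) {
    h <- sort(clinical$hour_index[clinical$neonate_id == id])
    if (anyDuplicated(h)) {
      errors <- c(errors, sprintf("clinical: duplicate hour_index for %s", id))
    } else if (length(h) > 0 &&
               !identical(as.integer(h), seq.int(0L, as.integer(max(h))))) {
      warnings <- c(warnings, sprintf(
        "clinical: hour gap(s) for %s treated as blank hours", id))
    }
  }
  list(errors = errors, warnings = warnings)
}
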