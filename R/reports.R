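REPORT_SCHEMA_VERSION <- "1.0"
INDEX_NAMES <- c("RV_LV", "PA_AA", "SA")

#' Build a table of index measurements
#'
#' Measurement tables are plain data frames with one row per (subject, index,
#' source) and columns `subject_id`, `index_name`, `source`, `value`,
#' `slice_index`. They are the interchange format between the geometry
#' pipeline (source `"auto"`), human raters (source `"manual"`) and the
#' agreement statistics.
#'
#' @param subject_id Character vector of subject identifiers.
#' @param index_name One of `"RV_LV"`, `"PA_AA"`, `"SA"` (recycled).
#' @param value Measured value; ratios are unitless and must be positive, SA
#'   is in degrees within \[0, 90\].
#' @param source `"auto"` or `"manual"` (recycled).
#' @param slice_index Optional 1-based axial slice the value was measured on.
#' @return A `data.frame` of validated measurement records.
#' @export
measurement_records <- function(subject_id, index_name, value,
                                source = "auto", slice_index = NA_integer_) {
  df <- data.frame(
    subject_id = as.character(subject_id),
    index_name = as.character(index_name),
    source = as.character(source),
    value = as.numeric(value),
    slice_index = as.integer(slice_index),
    stringsAsFactors = FALSE)
  validate_measurements(df)
}

#' @rdname measurement_records
#' @param records A data frame to validate (columns as above).
#' @export
validate_measurements <- function(records) {
  need <- c("subject_id", "index_name", "source", "value")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    abort_ctpa(sprintf("measurement table lacks column(s): %s",
                       paste(missing_cols, collapse = ", ")), "ctpa_value_error")
  if (!"slice_index" %in% names(records)) records$slice_index <- NA_integer_
  bad_idx <- setdiff(unique(records$index_name), INDEX_NAMES)
  if (length(bad_idx))
    abort_ctpa(sprintf("unknown index_name(s): %s", paste(bad_idx, collapse = ", ")),
               "ctpa_value_error")
  bad_src <- setdiff(unique(records$source), c("auto", "manual"))
  if (length(bad_src))
    abort_ctpa(sprintf("source must be 'auto' or 'manual', got: %s",
                       paste(bad_src, collapse = ", ")), "ctpa_value_error")
  ratio <- records$index_name %in% c("RV_LV", "PA_AA")
  if (any(!is.finite(records$value)))
    abort_ctpa("non-finite measurement value", "ctpa_value_error")
  if (any(records$value[ratio] <= 0))
    abort_ctpa("ratio measurements must be > 0", "ctpa_value_error")
  sa <- records$index_name == "SA"
  if (any(records$value[sa] < 0 | records$value[sa] > 90))
    abort_ctpa("SA measurements must lie in [0, 90] degrees", "ctpa_value_error")
  records[c("subject_id", "index_name", "source", "value", "slice_index")]
}

#' Write a measurement / agreement report
#'
#' Writes measurement records (and, optionally, the per-index agreement
#' statistics from [evaluate_agreement()]) to CSV or JSON. Column order is
#' fixed to `subject_id, index_name, source, value, slice_index`; JSON output
#' carries a `schema_version` field.
#'
#' @param records Measurement data frame (see [measurement_records()]).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`. CSV holds records only; JSON holds
#'   records plus, when given, the agreement report.
#' @param agreement Optional result of [evaluate_agreement()].
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("csv", "json"),
                         agreement = NULL) {
  format <- match.arg(format)
  records <- validate_measurements(records)
  if (nrow(records) == 0L)
    abort_ctpa("no measurement records to write", "ctpa_value_error")
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    payload <- list(schema_version = REPORT_SCHEMA_VERSION, records = records)
    if (!is.null(agreement)) {
      payload$agreement <- lapply(agreement, function(a) list(
        icc = a$icc, icc_ci95 = a$icc_ci95,
        accuracy = a$accuracy, accuracy_se = a$accuracy_se,
        bland_altman = a$bland_altman[c("bias", "loa_low", "loa_high")],
        n = a$n))
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read a measurement CSV written by [write_report()]
#'
#' @param path CSV file path.
#' @return A validated measurement data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    abort_ctpa(sprintf("file not found: %s", path), "ctpa_io_error")
  validate_measurements(utils::read.csv(path, stringsAsFactors = FALSE))
}
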