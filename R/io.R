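# Tabular I/O: tidy long CSV for raw screens (one well per row), binary event
# matrices, and response tables. All CSV is RFC-4180, UTF-8, '.' decimal; NaN
# serialises to an empty field.

#' Column-mapping dialect for raw screen CSVs
#'
#' External releases use varying headers; the dialect maps them onto the
#' canonical columns \code{cell_line_id, drug_id, batch_id, well_type,
#' dose_uM, intensity}.
#'
#' @param cell_line_id,drug_id,batch_id,well_type,dose_uM,intensity header
#'   names in the file.
#' @return named list of header names.
#' @export
raw_screen_dialect <- function(cell_line_id = "cell_line_id", drug_id = "drug_id",
                               batch_id = "batch_id", well_type = "well_type",
                               dose_uM = "dose_uM", intensity = "intensity") {
  list(cell_line_id = cell_line_id, drug_id = drug_id, batch_id = batch_id,
       well_type = well_type, dose_uM = dose_uM, intensity = intensity)
}

#' Read and validate a raw screen table
#'
#' One well per row. Treated wells carry a dose; blank and negative-control
#' wells leave the dose field empty and are matched to treated wells by
#' (cell line, batch) plate group. Validation is total: any malformed input
#' raises a classed error (never a partial table) listing offending rows.
#'
#' @param path CSV file path.
#' @param dialect a [raw_screen_dialect()].
#' @return data.frame with canonical columns, class \code{"raw_screen_table"}.
#' @export
read_raw_screen <- function(path, dialect = raw_screen_dialect()) {
  if (!file.exists(path))
    stop_gpdrc("gpdrc_io_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        check.names = FALSE)
  missing_cols <- setdiff(unlist(dialect), names(df))
  if (length(missing_cols))
    stop_gpdrc("gpdrc_format_error", sprintf(
      "missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")))
  out <- data.frame(
    cell_line_id = as.character(df[[dialect$cell_line_id]]),
    drug_id      = as.character(df[[dialect$drug_id]]),
    batch_id     = as.character(df[[dialect$batch_id]]),
    well_type    = as.character(df[[dialect$well_type]]),
    dose_uM      = suppressWarnings(as.numeric(df[[dialect$dose_uM]])),
    intensity    = suppressWarnings(as.numeric(as.character(df[[dialect$intensity]]))),
    stringsAsFactors = FALSE
  )
  bad_type <- which(!out$well_type %in% c("treated", "blank", "neg_control"))
  if (length(bad_type))
    stop_gpdrc("gpdrc_validation_error", sprintf(
      "invalid well_type at row(s): %s", paste(bad_type, collapse = ", ")))
  bad_int <- which(!is.finite(out$intensity))
  if (length(bad_int))
    stop_gpdrc("gpdrc_validation_error", sprintf(
      "%d row(s) with non-numeric or non-finite intensity: rows %s",
      length(bad_int), paste(bad_int, collapse = ", ")))
  treated <- out$well_type == "treated"
  bad_dose <- which(treated & (is.na(out$dose_uM) | out$dose_uM <= 0))
  if (length(bad_dose))
    stop_gpdrc("gpdrc_validation_error", sprintf(
      "treated row(s) with missing or non-positive dose_uM: rows %s",
      paste(bad_dose, collapse = ", ")))
  # every treated plate group needs controls
  grp <- unique(out[treated, c("cell_line_id", "batch_id")])
  for (i in seq_len(nrow(grp))) {
    plate <- out$cell_line_id == grp$cell_line_id[i] & out$batch_id == grp$batch_id[i]
    if (!any(plate & out$well_type == "blank") ||
        !any(plate & out$well_type == "neg_control"))
      stop_gpdrc("gpdrc_validation_error", sprintf(
        "plate group (%s, %s) lacks blank and/or neg_control wells",
        grp$cell_line_id[i], grp$batch_id[i]))
  }
  class(out) <- c("raw_screen_table", "data.frame")
  out
}

#' Write a raw screen table (dose for control wells left empty)
#' @param raw a raw screen table.
#' @param path output CSV path.
#' @export
write_raw_screen <- function(raw, path) {
  utils::write.csv(raw, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(NULL)
}

#' Read a binary event matrix (cell line x genetic feature)
#'
#' First column holds cell-line ids; an optional \code{cancer_type} column
#' holds the tissue label; remaining columns are 0/1 event indicators.
#'
#' @param path CSV path.
#' @return object of class \code{"binary_event_matrix"}: list with
#'   \code{cell_line_ids}, \code{feature_ids}, \code{values} (0/1 matrix) and
#'   \code{cancer_type}.
#' @export
read_bem <- function(path) {
  if (!file.exists(path))
    stop_gpdrc("gpdrc_io_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop_gpdrc("gpdrc_validation_error", sprintf(
      "duplicate cell line id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  cancer_type <- if ("cancer_type" %in% names(df)) as.character(df$cancer_type)
                 else rep(NA_character_, length(ids))
  feat_cols <- setdiff(names(df)[-1L], "cancer_type")
  values <- as.matrix(df[, feat_cols, drop = FALSE])
  mode(values) <- "numeric"
  bad <- which(!(values %in% c(0, 1)) | is.na(values))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop_gpdrc("gpdrc_validation_error", sprintf(
      "BEM value outside {0,1} at (%d,%d) [%d offending cell(s)]",
      rc[1L], rc[2L], length(bad)))
  }
  dimnames(values) <- list(ids, feat_cols)
  structure(list(cell_line_ids = ids, feature_ids = feat_cols,
                 values = values, cancer_type = cancer_type),
            class = "binary_event_matrix")
}

#' @export
print.binary_event_matrix <- function(x, ...) {
  cat(sprintf("<binary_event_matrix> %d cell lines x %d features, %d events\n",
              length(x$cell_line_ids), length(x$feature_ids), sum(x$values)))
  invisible(x)
}

response_table_columns <- c(
  "cell_line_id", "drug_id", "ic50_mean_log10uM", "ic50_sd", "auc_mean",
  "auc_sd", "crossing_fraction", "within_range", "qc_spearman", "method")

validate_response_table <- function(tab) {
  missing_cols <- setdiff(response_table_columns, names(tab))
  if (length(missing_cols))
    stop_gpdrc("gpdrc_format_error", sprintf(
      "response table missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (nrow(tab)) {
    if (any(tab$auc_mean < 0 | tab$auc_mean > 1, na.rm = TRUE))
      stop_gpdrc("gpdrc_validation_error", "auc_mean must lie in [0, 1]")
    none <- tab$crossing_fraction == 0
    if (any(none & is.finite(tab$ic50_mean_log10uM)) ||
        any(!none & !is.finite(tab$ic50_mean_log10uM)))
      stop_gpdrc("gpdrc_validation_error",
                 "ic50 mean must be NaN exactly when crossing_fraction is 0")
    if (!all(tab$method %in% c("gp", "sigmoid")))
      stop_gpdrc("gpdrc_validation_error", "method must be 'gp' or 'sigmoid'")
  }
  tab[, response_table_columns, drop = FALSE]
}

#' Write a response table with fixed column order
#'
#' NaN/NA numeric fields serialise to empty fields; [read_response_table()]
#' restores them as NaN. A write/read round trip reproduces the table exactly
#' for string and logical fields and to float precision for numerics.
#'
#' @param tab response table (one row per experiment).
#' @param path output CSV path.
#' @export
write_response_table <- function(tab, path) {
  tab <- validate_response_table(as.data.frame(tab))
  num <- vapply(tab, is.numeric, logical(1L))
  out <- tab
  out[num] <- lapply(tab[num], function(x) {
    s <- vapply(x, function(v) {
      if (!is.finite(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1L))
    s
  })
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_gpdrc("gpdrc_io_error", sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(NULL)
}

#' Read a response table written by [write_response_table()]
#' @param path CSV path.
#' @return validated response table data.frame.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path))
    stop_gpdrc("gpdrc_io_error", sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  numcols <- c("ic50_mean_log10uM", "ic50_sd", "auc_mean", "auc_sd",
               "crossing_fraction", "qc_spearman")
  for (cc in numcols) {
    df[[cc]] <- as.numeric(df[[cc]])
    df[[cc]][is.na(df[[cc]])] <- NaN
  }
  df$within_range <- as.logical(df$within_range)
  for (cc in c("cell_line_id", "drug_id", "method"))
    df[[cc]] <- as.character(df[[cc]])
  validate_response_table(df)
}
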