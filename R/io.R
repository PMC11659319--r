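# File formats: the canonical cohort CSV, epoch matrices with JSON sidecar
# metadata, and the mapped reader for externally deposited per-participant
# source data.

# canonical cohort schema: column -> (unit, soft plausibility range)
cohort_schema <- function() {
  list(
    id = list(unit = "", range = NULL, required = TRUE, numeric = FALSE),
    age = list(unit = "years", range = c(18, 120), required = TRUE, numeric = TRUE),
    sex = list(unit = "", range = NULL, required = FALSE, numeric = FALSE),
    pta = list(unit = "dB HL", range = c(-10, 120), required = FALSE, numeric = TRUE),
    wave_i_latency = list(unit = "ms", range = c(1.3, 2.3), required = FALSE, numeric = TRUE),
    wave_i_amplitude = list(unit = "uV", range = c(0, 2), required = FALSE, numeric = TRUE),
    wave_v_latency = list(unit = "ms", range = c(5.1, 6.4), required = FALSE, numeric = TRUE),
    wave_v_amplitude = list(unit = "uV", range = c(0, 2), required = FALSE, numeric = TRUE)
  )
}

#' Read a canonical cohort CSV
#'
#' Reads and validates a delimited cohort table. Mandatory columns (`id`,
#' `age`) must exist; numeric columns must parse; values outside each
#' column's plausibility range (e.g. wave V latency outside the 5.1-6.4 ms
#' analysis window) produce warnings with row/column coordinates, collected
#' in the `validation` attribute. Unknown columns are preserved.
#'
#' @param path CSV file path.
#' @param warn emit range warnings as R warnings (always recorded in the
#'   attribute).
#' @return data.frame with a `validation` attribute (data.frame: row, column,
#'   issue).
#' @export
read_cohort <- function(path, warn = TRUE) {
  if (!file.exists(path)) stop_input("cohort file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  schema <- cohort_schema()
  required <- names(schema)[vapply(schema, `[[`, logical(1), "required")]
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop_input("missing mandatory column(s): ", paste(miss, collapse = ", "))
  issues <- list()
  for (col in intersect(names(schema), names(raw))) {
    sc <- schema[[col]]
    if (!sc$numeric) next
    x <- raw[[col]]
    if (!is.numeric(x)) {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(parsed))
      if (length(bad))
        stop_input(sprintf("unparsable number in column '%s', row(s) %s (e.g. \"%s\")",
                           col, paste(head(bad, 5), collapse = ", "), x[bad[1]]))
      raw[[col]] <- parsed
      x <- parsed
    }
    if (!is.null(sc$range)) {
      out <- which(!is.na(x) & (x < sc$range[1] | x > sc$range[2]))
      for (i in out) {
        issues[[length(issues) + 1L]] <- data.frame(
          row = i, column = col,
          issue = sprintf("value %g outside plausible range [%g, %g] %s",
                          x[i], sc$range[1], sc$range[2], sc$unit),
          stringsAsFactors = FALSE)
      }
    }
  }
  val <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(0), column = character(0), issue = character(0))
  if (warn && nrow(val))
    warning(sprintf("%d range issue(s); first: row %d, %s: %s",
                    nrow(val), val$row[1], val$column[1], val$issue[1]))
  attr(raw, "validation") <- val
  raw
}

#' Write the canonical cohort CSV
#'
#' @param cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write an epoch set as delimited text plus sidecar metadata
#'
#' The sweeps x samples matrix goes to a tab-delimited text file; sampling
#' rate, onset, seed and the masks go to a JSON sidecar (`<path>.json`).
#'
#' @param epochs an `epoch_set`.
#' @param path matrix file path (e.g. `epochs.tsv`).
#' @return `path`, invisibly.
#' @export
write_epoch_set <- function(epochs, path) {
  utils::write.table(epochs$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(sampling_rate = epochs$sampling_rate,
               onset_time = epochs$onset_time,
               n_sweeps = nrow(epochs$data),
               n_samples = ncol(epochs$data),
               seed = epochs$seed %||% NA,
               accepted_mask = epochs$accepted_mask,
               artifact_mask = epochs$artifact_mask %||% NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epoch_set()]
#'
#' @param path matrix file path; `<path>.json` must exist alongside.
#' @return an `epoch_set`.
#' @export
read_epoch_set <- function(path) {
  if (!file.exists(path)) stop_input("epoch matrix not found: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop_input("sidecar metadata not found: ", side)
  data <- as.matrix(read.table(path, sep = "\t"))
  dimnames(data) <- NULL
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate) || meta$sampling_rate <= 0)
    stop_input("sidecar must record a positive sampling_rate")
  structure(list(data = data, sampling_rate = meta$sampling_rate,
                 onset_time = meta$onset_time %||% 0,
                 times = (seq_len(ncol(data)) - 1) / meta$sampling_rate * 1000,
                 accepted_mask = as.logical(meta$accepted_mask %||% rep(TRUE, nrow(data))),
                 artifact_mask = if (!is.null(meta$artifact_mask)) as.logical(meta$artifact_mask) else NULL,
                 seed = meta$seed),
            class = "epoch_set")
}

# canonical column -> whether it is required for a reproduction run
source_data_required <- c("id", "age", "pta", "wave_v_latency",
                          "wave_v_amplitude")

#' Load deposited per-participant source data via a column map
#'
#' Reads an externally deposited per-participant workbook (Excel via
#' \pkg{readxl}, or a CSV export of the relevant sheet) and maps its columns
#' onto the canonical cohort schema through an explicit, user-editable column
#' map. Nothing is guessed: canonical columns whose source column is unmapped
#' or absent raise an error naming them.
#'
#' @param path `.xlsx`/`.xls` or `.csv` file.
#' @param column_map named character vector: canonical name -> source column
#'   name. May be produced by [read_column_map()].
#' @param sheet sheet name or index for Excel input.
#' @param required canonical columns that must be mapped.
#' @return canonical cohort data.frame.
#' @export
load_source_data <- function(path, column_map, sheet = 1,
                             required = source_data_required) {
  if (!file.exists(path))
    stop_input("reproduction input not found: ", path,
               " (the pipeline runs on synthetic data without it)")
  ext <- tolower(tools::file_ext(path))
  src <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_input("reading Excel requires the 'readxl' package; ",
                 "export the sheet to CSV instead")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  unmapped <- setdiff(required, names(column_map))
  if (length(unmapped))
    stop_input("column map lacks required canonical column(s): ",
               paste(unmapped, collapse = ", "))
  absent <- setdiff(unname(column_map), names(src))
  if (length(absent))
    stop_input("mapped source column(s) absent from ", basename(path), ": ",
               paste(absent, collapse = ", "))
  out <- as.data.frame(src[, unname(column_map), drop = FALSE])
  names(out) <- names(column_map)
  out
}

#' Read / write a column map
#'
#' A column map is a two-column CSV (`canonical`, `source`) mapping canonical
#' cohort columns to the source workbook's column headers.
#'
#' @param path CSV path.
#' @return named character vector (canonical -> source).
#' @export
read_column_map <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("canonical", "source") %in% names(m)))
    stop_input("column map must have 'canonical' and 'source' columns")
  setNames(m$source, m$canonical)
}

#' @rdname read_column_map
#' @param column_map named character vector to write.
#' @export
write_column_map <- function(column_map, path) {
  write.csv(data.frame(canonical = names(column_map),
                       source = unname(column_map)),
            path, row.names = FALSE)
  invisible(path)
}
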