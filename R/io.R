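#' Write a cell recording to the fixture JSON format
#'
#' The fixture format is a plain JSON object holding the cell metadata and
#' one entry per sweep (step description plus the raw voltage array at full
#' double precision), so that a write/read round trip reproduces every sample
#' bit-exactly. It is the package's interchange format; all analyses run on
#' it without any binary dependency.
#'
#' @param record A [cell_record()].
#' @param path Output file path (UTF-8).
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_fixture <- function(record, path) {
  stopifnot(inherits(record, "cell_record"))
  x <- list(
    format = "lifespanephys-fixture",
    version = 1L,
    cell_id = record$cell_id,
    age = record$age, sex = record$sex, region = record$region,
    pathology = record$pathology, soma_depth_um = record$soma_depth_um,
    series_resistance = record$series_resistance,
    sweeps = lapply(record$sweeps, function(s) {
      list(current_amplitude = s$current_amplitude,
           step_onset = s$step_onset, step_duration = s$step_duration,
           sampling_interval = s$sampling_interval,
           holding_current = s$holding_current,
           voltage = s$voltage)
    }))
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a cell recording
#'
#' Reads one cell's sweep set. `format = "fixture-json"` reads the package's
#' JSON fixture format (see [write_fixture()]). `format = "nwb"` is reserved
#' for NWB intracellular-electrophysiology files and raises an informative
#' error in this build, which carries no HDF5 reader; convert NWB sweeps to
#' the fixture format upstream.
#'
#' @param path File path.
#' @param format `"fixture-json"` or `"nwb"`.
#' @return A [cell_record()] with sweeps sorted by step amplitude.
#' @export
read_recording <- function(path, format = c("fixture-json", "nwb")) {
  format <- match.arg(format)
  if (format == "nwb")
    stop("NWB reading is not available in this build; ",
         "export the recording to the fixture JSON format instead")
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e)
                  stop(sprintf("'%s' is not valid fixture JSON: %s",
                               path, conditionMessage(e))))
  if (is.null(x$format) || !identical(x$format, "lifespanephys-fixture"))
    stop(sprintf("'%s': missing or unknown `format` field", path))
  for (f in c("cell_id", "sweeps"))
    if (is.null(x[[f]]))
      stop(sprintf("'%s': required field `%s` absent", path, f))
  sw <- x$sweeps
  if (is.data.frame(sw)) sw <- split(sw, seq_len(nrow(sw)))
  sweeps <- lapply(seq_along(sw), function(i) {
    s <- as.list(sw[[i]])
    for (f in c("current_amplitude", "step_onset", "step_duration",
                "sampling_interval", "voltage"))
      if (is.null(s[[f]]))
        stop(sprintf("'%s': sweep %d lacks field `%s`", path, i, f))
    new_sweep(as.numeric(unlist(s$voltage)), as.numeric(s$current_amplitude),
              as.numeric(s$step_onset), as.numeric(s$step_duration),
              as.numeric(s$sampling_interval),
              if (is.null(s$holding_current)) 0
              else as.numeric(s$holding_current))
  })
  scalar_or_na <- function(v, na) {
    if (is.null(v) || !length(v) || (length(v) == 1 && is.na(v))) return(na)
    if (is.numeric(na)) as.numeric(v) else as.character(v)
  }
  cell_record(
    sweeps, cell_id = x$cell_id,
    age = scalar_or_na(x$age, NA_real_),
    sex = scalar_or_na(x$sex, NA_character_),
    region = scalar_or_na(x$region, NA_character_),
    pathology = scalar_or_na(x$pathology, NA_character_),
    soma_depth_um = scalar_or_na(x$soma_depth_um, NA_real_),
    series_resistance = scalar_or_na(x$series_resistance, NA_real_))
}

#' Write / read a per-cell feature table
#'
#' One row per cell: the metadata columns first, then the 32 features of
#' [ephys_feature_names()] in stable order. Missing features are written as
#' the explicit `NA` marker, never as zero.
#'
#' @param features Tibble as returned by [extract_features()].
#' @param path CSV file path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: a tibble.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features), nrow(features) > 0)
  if (anyDuplicated(features$cell_id))
    stop("duplicate cell_id in feature table: ",
         paste(unique(features$cell_id[duplicated(features$cell_id)]),
               collapse = ", "))
  keep <- intersect(c(record_metadata_names(), "age_group",
                      ephys_feature_names()),
                    names(features))
  readr::write_csv(features[, keep], path, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
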