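#' Current-step stimulation protocol
#'
#' Describes a family of square current steps delivered from a common holding
#' level: amplitudes form the arithmetic sequence
#' `start_amplitude + k * increment`, k = 0 .. n_steps - 1. The default is the
#' protocol used throughout the package: 800 ms steps from -100 pA in +20 pA
#' increments, sampled at 20 kHz, with a 200 ms pre-step baseline and a
#' 300 ms post-step window.
#'
#' @param start_amplitude First step amplitude (pA).
#' @param increment Amplitude increment between consecutive steps (pA, > 0).
#' @param n_steps Number of steps.
#' @param step_onset Time of step onset within each sweep (ms); everything
#'   before it is the pre-step baseline (at least 100 ms is required by the
#'   analysis windows).
#' @param step_duration Step duration (ms).
#' @param post_window Recorded time after step offset (ms); rebound analysis
#'   needs at least 200 ms.
#' @param sampling_interval Sample spacing (ms).
#' @return An object of class `step_protocol`.
#' @examples
#' p <- step_protocol(n_steps = 5)
#' protocol_amplitudes(p)
#' @export
step_protocol <- function(start_amplitude = -100, increment = 20,
                          n_steps = 26, step_onset = 200,
                          step_duration = 800, post_window = 300,
                          sampling_interval = 0.05) {
  stopifnot(increment > 0, step_duration > 0, sampling_interval > 0,
            n_steps >= 1, step_onset >= 100, post_window >= 0)
  structure(
    list(start_amplitude = start_amplitude, increment = increment,
         n_steps = as.integer(n_steps), step_onset = step_onset,
         step_duration = step_duration, post_window = post_window,
         sampling_interval = sampling_interval),
    class = "step_protocol")
}

#' @rdname step_protocol
#' @param protocol A `step_protocol`.
#' @export
protocol_amplitudes <- function(protocol) {
  protocol$start_amplitude +
    (seq_len(protocol$n_steps) - 1) * protocol$increment
}

#' @export
print.step_protocol <- function(x, ...) {
  amps <- protocol_amplitudes(x)
  cat(sprintf(
    "<step_protocol> %d steps, %g..%g pA by %g pA, %g ms @ %g kHz\n",
    x$n_steps, amps[1], amps[length(amps)], x$increment,
    x$step_duration, 1 / x$sampling_interval))
  invisible(x)
}

#' Single current-clamp sweep
#'
#' One membrane-potential trace together with the square current step that
#' elicited it. Times are in ms, voltages in mV, currents in pA.
#'
#' @param voltage Numeric vector of membrane-potential samples (mV), all
#'   finite.
#' @param current_amplitude Step amplitude (pA).
#' @param step_onset,step_duration Step timing within the sweep (ms).
#' @param sampling_interval Sample spacing (ms).
#' @param holding_current Constant holding current (pA).
#' @return An object of class `sweep`.
#' @export
new_sweep <- function(voltage, current_amplitude, step_onset = 200,
                      step_duration = 800, sampling_interval = 0.05,
                      holding_current = 0) {
  voltage <- as.numeric(voltage)
  if (any(!is.finite(voltage)))
    stop("sweep voltage contains non-finite samples")
  need <- (step_onset + step_duration) / sampling_interval
  if (length(voltage) < need)
    stop(sprintf(
      "sweep too short: %d samples, step needs at least %d",
      length(voltage), ceiling(need)))
  structure(
    list(voltage = voltage, current_amplitude = current_amplitude,
         step_onset = step_onset, step_duration = step_duration,
         sampling_interval = sampling_interval,
         holding_current = holding_current),
    class = "sweep")
}

#' @rdname new_sweep
#' @param sweep A `sweep`.
#' @return `sweep_times()`: sample times (ms), starting at 0.
#' @export
sweep_times <- function(sweep) {
  (seq_along(sweep$voltage) - 1) * sweep$sampling_interval
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %g pA step, %d samples @ %g kHz\n",
              x$current_amplitude, length(x$voltage),
              1 / x$sampling_interval))
  invisible(x)
}

#' A recorded cell: sweep set plus metadata
#'
#' Bundles the sweeps of one cell with the metadata used downstream
#' (age in years, sex, cortical region, pathology, soma depth below the
#' L1/2 border, pipette series resistance). Sweeps are stored sorted by
#' step amplitude and must share one sampling interval.
#'
#' @param sweeps List of [new_sweep()] objects.
#' @param cell_id Unique identifier.
#' @param age Age in years (fractional allowed, >= 0) or `NA`.
#' @param sex `"male"`, `"female"` or `NA`.
#' @param region Cortical lobe (`"frontal"`, `"temporal"`, `"parietal"`,
#'   `"occipital"`) or `NA`.
#' @param pathology `"tumor"`, `"hydrocephalus"`, `"other"` or `NA`.
#' @param soma_depth_um Distance of the soma from the L1/2 border (um) or
#'   `NA`.
#' @param series_resistance Pipette series resistance (MOhm, > 0) or `NA`.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(sweeps, cell_id, age = NA_real_, sex = NA_character_,
                        region = NA_character_, pathology = NA_character_,
                        soma_depth_um = NA_real_,
                        series_resistance = NA_real_) {
  if (!length(sweeps)) stop("cell_record needs at least one sweep")
  ok <- vapply(sweeps, inherits, logical(1), "sweep")
  if (!all(ok)) stop("all elements of `sweeps` must be sweep objects")
  dts <- vapply(sweeps, function(s) s$sampling_interval, numeric(1))
  if (length(unique(dts)) > 1L)
    stop(sprintf("cell '%s': sweeps mix sampling intervals (%s ms)",
                 cell_id, paste(sort(unique(dts)), collapse = ", ")))
  if (!is.na(age) && age < 0) stop("age must be >= 0")
  if (!is.na(series_resistance) && series_resistance <= 0)
    stop("series_resistance must be > 0")
  amps <- vapply(sweeps, function(s) s$current_amplitude, numeric(1))
  structure(
    list(sweeps = sweeps[order(amps)], cell_id = as.character(cell_id),
         age = age, sex = sex, region = region, pathology = pathology,
         soma_depth_um = soma_depth_um,
         series_resistance = series_resistance),
    class = "cell_record")
}

#' @rdname cell_record
#' @param record A `cell_record`.
#' @return `record_amplitudes()`: step amplitudes (pA) in stored (ascending)
#'   order.
#' @export
record_amplitudes <- function(record) {
  vapply(record$sweeps, function(s) s$current_amplitude, numeric(1))
}

#' @export
print.cell_record <- function(x, ...) {
  amps <- record_amplitudes(x)
  cat(sprintf("<cell_record> '%s': %d sweeps (%g..%g pA), age %s y\n",
              x$cell_id, length(x$sweeps), min(amps), max(amps),
              format(x$age)))
  invisible(x)
}

#' Canonical electrophysiological feature names
#'
#' The 32 per-cell intrinsic features computed by
#' [extract_cell_features()], in stable column order.
#'
#' @return Character vector of length 32.
#' @export
ephys_feature_names <- function() {
  c("resting_vm", "input_resistance", "tau", "sag_ratio", "rheobase",
    "ap_half_width", "ap_up_stroke", "ap_amplitude", "fi_slope",
    "first_ap_latency", "adaptation", "rebound", "rebound_sag_ratio",
    "avg_ap_number", "ap_threshold", "ap_rise_time", "ahp_amplitude",
    "ahp_length", "voltage_at_max_dvdt", "velocity_at_min_dvdt",
    "voltage_at_min_dvdt", "ap_peak", "isi_mean",
    "ap_amplitude_accommodation", "ap_half_width_accommodation",
    "ap_threshold_accommodation", "average_isi",
    "ap_amplitude_adaptation", "ap_half_width_adaptation",
    "ap_threshold_adaptation", "ahp_area", "adp_amplitude")
}

# metadata columns written ahead of the features in feature tables
record_metadata_names <- function() {
  c("cell_id", "age", "sex", "region", "pathology", "soma_depth_um",
    "series_resistance")
}

record_metadata <- function(record) {
  tibble::tibble(
    cell_id = record$cell_id, age = record$age, sex = record$sex,
    region = record$region, pathology = record$pathology,
    soma_depth_um = record$soma_depth_um,
    series_resistance = record$series_resistance)
}
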