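# events restricted to the current step (APs must start within the step)
step_events <- function(sweep, ...) {
  ev <- detect_aps(sweep, ...)
  on <- sweep$step_onset
  off <- sweep$step_onset + sweep$step_duration
  ev[ev$threshold_time >= on & ev$threshold_time < off, , drop = FALSE]
}

positive_sweeps <- function(record) {
  Filter(function(s) s$current_amplitude > 0, record$sweeps)
}

#' Rheobase
#'
#' The smallest positive step amplitude whose sweep contains at least one
#' detected AP within the step window.
#'
#' @param record A [cell_record()].
#' @param ... Passed to [detect_aps()].
#' @return Rheobase (pA); `NA` with a reason when no positive sweep spikes.
#' @export
rheobase <- function(record, ...) {
  ps <- positive_sweeps(record)
  if (!length(ps)) return(na_reason("no positive-amplitude sweeps"))
  for (s in ps) {  # sweeps are stored in ascending amplitude order
    if (nrow(step_events(s, ...)) > 0) return(s$current_amplitude)
  }
  na_reason("no sweep elicited an AP")
}

#' F-I slope
#'
#' Firing frequency per sweep is the AP count divided by the step duration
#' (Hz); the F-I slope is the ordinary least-squares slope of frequency
#' versus step amplitude over the sweeps at or above rheobase. Sweeps above
#' rheobase in which spiking ceased are excluded by default (treated as
#' depolarization block), controllable via `include_silent`.
#'
#' @inheritParams rheobase
#' @param include_silent Keep zero-frequency sweeps above rheobase in the
#'   fit (default `FALSE`).
#' @return Slope (Hz/pA); `NA` with a reason when fewer than two sweeps
#'   qualify.
#' @export
f_i_slope <- function(record, include_silent = FALSE, ...) {
  ps <- positive_sweeps(record)
  if (!length(ps)) return(na_reason("no positive-amplitude sweeps"))
  counts <- vapply(ps, function(s) nrow(step_events(s, ...)), numeric(1))
  amps <- vapply(ps, function(s) s$current_amplitude, numeric(1))
  spiking <- which(counts > 0)
  if (!length(spiking)) return(na_reason("no spiking sweeps"))
  keep <- seq(spiking[1], length(ps))
  if (!include_silent) keep <- keep[counts[keep] > 0]
  if (length(keep) < 2) return(na_reason("fewer than 2 spiking sweeps"))
  freq <- counts[keep] / (ps[[1]]$step_duration / 1000)
  unname(stats::coef(stats::lm(freq ~ amps[keep]))[2])
}

#' Latency of the first AP at rheobase
#'
#' Threshold time of the first AP in the rheobase sweep, measured from step
#' onset.
#'
#' @inheritParams rheobase
#' @return Latency (ms); `NA` with a reason when rheobase is undefined.
#' @export
first_ap_latency <- function(record, ...) {
  rb <- rheobase(record, ...)
  if (is.na(rb)) return(na_reason("rheobase undefined"))
  s <- record$sweeps[[which(record_amplitudes(record) == rb)[1]]]
  ev <- step_events(s, ...)
  ev$threshold_time[1] - s$step_onset
}

#' Normalized consecutive-difference adaptation index
#'
#' For an ordered sequence x, the mean over consecutive pairs of
#' `(x[i+1] - x[i]) / (x[i+1] + x[i])`. Applied to interspike intervals it
#' is the cell's "adaptation"; the same operator applied to per-AP
#' amplitude / half-width / threshold sequences gives the per-feature
#' adaptation indices. Positive values mean the quantity grows along the
#' train. Scale-invariant: multiplying all values by c > 0 leaves it
#' unchanged.
#'
#' @param values Ordered numeric vector (length >= 2).
#' @return Unitless index; `NA` with a reason for degenerate input.
#' @export
adaptation_index <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) return(na_reason("fewer than 2 values"))
  a <- values[-length(values)]
  b <- values[-1]
  if (any(a + b == 0)) return(na_reason("consecutive pair sums to zero"))
  mean((b - a) / (b + a))
}

#' First-minus-last accommodation
#'
#' The difference between the first and the last value of a per-AP feature
#' sequence within one sweep (positive when the feature decreases along the
#' train).
#'
#' @param values Ordered numeric vector (length >= 2).
#' @return Difference in the input's units; `NA` with a reason when fewer
#'   than two values are given.
#' @export
accommodation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) return(na_reason("fewer than 2 values"))
  values[1] - values[length(values)]
}

#' Interspike-interval statistics of a cell
#'
#' `isi_mean` pools the ISIs of every sweep with at least three APs and
#' averages them at the cell level; `average_isi` first takes each
#' qualifying sweep's mean ISI and then averages across sweeps;
#' `avg_ap_number` is the mean AP count over all positive-current sweeps
#' (zero counts included). ISIs are measured between consecutive AP peaks.
#'
#' @inheritParams rheobase
#' @return One-row tibble: `isi_mean` (ms), `average_isi` (ms),
#'   `avg_ap_number`.
#' @export
isi_features <- function(record, ...) {
  ps <- positive_sweeps(record)
  if (!length(ps))
    return(tibble::tibble(isi_mean = NA_real_, average_isi = NA_real_,
                          avg_ap_number = NA_real_))
  evs <- lapply(ps, step_events, ...)
  counts <- vapply(evs, nrow, numeric(1))
  isis <- lapply(evs[counts >= 3], function(ev) diff(ev$peak_time))
  tibble::tibble(
    isi_mean = if (length(isis)) mean(unlist(isis)) else NA_real_,
    average_isi = if (length(isis))
      mean(vapply(isis, mean, numeric(1))) else NA_real_,
    avg_ap_number = mean(counts))
}

#' Extract the full 32-feature vector of one cell
#'
#' Populates every intrinsic-feature slot of [ephys_feature_names()] by
#' delegating to the subthreshold, spike-waveform, afterpotential and
#' firing-pattern operations. Per-AP features are averaged over all accepted
#' APs of all positive sweeps; the accommodation and adaptation variants are
#' computed per sweep (on sweeps with enough APs) and averaged across
#' sweeps. Features that are undefined for the cell (e.g. spiking features
#' of a passive cell) are `NA`; the reasons are collected in the
#' `missing_reasons` attribute rather than aborting the extraction.
#'
#' @param record A [cell_record()].
#' @param sag_amplitude Sag sweep amplitude (pA).
#' @param baseline_ms,steady_ms Subthreshold analysis windows (ms).
#' @param ... Passed to [detect_aps()].
#' @return One-row tibble: the cell metadata columns followed by the 32
#'   features in stable order.
#' @export
extract_cell_features <- function(record, sag_amplitude = -100,
                                  baseline_ms = 100, steady_ms = 100, ...) {
  sub <- subthreshold_features(record, sag_amplitude, baseline_ms,
                               steady_ms)
  ps <- positive_sweeps(record)
  evs <- lapply(ps, step_events, ...)

  # per-sweep AP tables
  wf <- purrr::map2(ps, evs, function(s, ev) ap_waveform_features(s, ev))
  ah <- purrr::map2(ps, evs, function(s, ev) ahp_adp_features(s, ev))
  all_wf <- dplyr::bind_rows(empty_waveform_table(), wf)
  all_wf <- all_wf[!all_wf$clipped & !is.na(all_wf$amplitude), ,
                   drop = FALSE]
  all_ah <- dplyr::bind_rows(empty_ahp_table(), ah)

  mean_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  # per-sweep sequence statistic averaged over qualifying sweeps
  sweep_stat <- function(col, fn, min_ap = 2) {
    vals <- purrr::map_dbl(wf, function(tb) {
      tb <- tb[!tb$clipped, , drop = FALSE]
      if (nrow(tb) < min_ap) return(NA_real_)
      as.numeric(fn(tb[[col]]))
    })
    mean_or_na(vals)
  }
  isi_adaptation <- mean_or_na(purrr::map_dbl(evs, function(ev) {
    if (nrow(ev) < 3) return(NA_real_)
    as.numeric(adaptation_index(diff(ev$peak_time)))
  }))

  isi <- isi_features(record, ...)
  rb <- rheobase(record, ...)

  feats <- tibble::tibble(
    resting_vm = sub$resting_vm,
    input_resistance = sub$input_resistance,
    tau = sub$tau,
    sag_ratio = sub$sag_ratio,
    rheobase = as.numeric(rb),
    ap_half_width = mean_or_na(all_wf$half_width),
    ap_up_stroke = mean_or_na(all_wf$max_dvdt),
    ap_amplitude = mean_or_na(all_wf$amplitude),
    fi_slope = as.numeric(f_i_slope(record, ...)),
    first_ap_latency = as.numeric(first_ap_latency(record, ...)),
    adaptation = isi_adaptation,
    rebound = sub$rebound,
    rebound_sag_ratio = sub$rebound_sag_ratio,
    avg_ap_number = isi$avg_ap_number,
    ap_threshold = mean_or_na(all_wf$threshold_voltage),
    ap_rise_time = mean_or_na(all_wf$rise_time),
    ahp_amplitude = mean_or_na(all_ah$ahp_amplitude),
    ahp_length = mean_or_na(all_ah$ahp_length),
    voltage_at_max_dvdt = mean_or_na(all_wf$voltage_at_max_dvdt),
    velocity_at_min_dvdt = mean_or_na(all_wf$min_dvdt),
    voltage_at_min_dvdt = mean_or_na(all_wf$voltage_at_min_dvdt),
    ap_peak = mean_or_na(all_wf$peak_voltage),
    isi_mean = isi$isi_mean,
    ap_amplitude_accommodation = sweep_stat("amplitude", accommodation),
    ap_half_width_accommodation = sweep_stat("half_width", accommodation),
    ap_threshold_accommodation = sweep_stat("threshold_voltage",
                                            accommodation),
    average_isi = isi$average_isi,
    ap_amplitude_adaptation = sweep_stat("amplitude", adaptation_index),
    ap_half_width_adaptation = sweep_stat("half_width", adaptation_index),
    ap_threshold_adaptation = sweep_stat("threshold_voltage",
                                         adaptation_index),
    ahp_area = mean_or_na(all_ah$ahp_area),
    adp_amplitude = mean_or_na(all_ah$adp_amplitude))

  out <- dplyr::bind_cols(record_metadata(record), feats)
  missing <- names(feats)[vapply(feats, is.na, logical(1))]
  attr(out, "missing_reasons") <-
    stats::setNames(as.list(rep("undefined for this cell",
                                length(missing))), missing)
  out
}

#' Extract features for a set of cells
#'
#' Maps [extract_cell_features()] over a list of records and binds the rows
#' into one feature table (one row per cell, metadata columns then the 32
#' features). When ages are present an `age_group` column is added via
#' [assign_age_group()].
#'
#' @param records List of [cell_record()] objects.
#' @param ... Passed to [extract_cell_features()].
#' @return Tibble with one row per cell.
#' @export
extract_features <- function(records, ...) {
  out <- purrr::map_dfr(records, extract_cell_features, ...)
  if (any(!is.na(out$age)))
    out <- dplyr::mutate(out,
                         age_group = assign_age_group(.data$age),
                         .after = "age")
  out
}
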