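central_dvdt <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  if (n >= 2) {
    d[1] <- (v[2] - v[1]) / dt
    d[n] <- (v[n] - v[n - 1]) / dt
  }
  d
}

# 5-point moving-average smoothing, optional for noisy recordings
smooth5 <- function(v) {
  as.numeric(stats::filter(v, rep(1 / 5, 5), sides = 2)) |>
    (\(s) { s[is.na(s)] <- v[is.na(s)]; s })()
}

#' Detect action potentials in a sweep
#'
#' An AP is a voltage maximum preceded by an upward crossing of the
#' dV/dt onset criterion. The threshold (onset) point of each AP is the
#' first sample of the contiguous run of samples with
#' `dV/dt >= dvdt_threshold` that leads up to the peak — a fixed-slope
#' criterion, the standard reproducible choice for cortical neurons.
#' Candidate maxima failing the acceptance rules (amplitude below
#' `min_amplitude` above threshold, or peak below `min_peak`) are rejected
#' as noise bumps.
#'
#' @param sweep A [new_sweep()].
#' @param dvdt_threshold Onset slope criterion (mV/ms, default 20).
#' @param min_amplitude Minimum threshold-to-peak amplitude (mV, default 20).
#' @param min_peak Minimum absolute peak voltage (mV, default -20).
#' @param smooth Apply 5-point smoothing to the derivative trace before
#'   thresholding (for noisy data; default `FALSE`).
#' @return Tibble of AP events ordered in time: `ap` (index within sweep),
#'   `threshold_index`, `threshold_time` (ms), `threshold_voltage` (mV),
#'   `peak_index`, `peak_time`, `peak_voltage`. Zero rows when the sweep has
#'   no APs.
#' @export
detect_aps <- function(sweep, dvdt_threshold = 20, min_amplitude = 20,
                       min_peak = -20, smooth = FALSE) {
  v <- sweep$voltage
  dt <- sweep$sampling_interval
  empty <- tibble::tibble(
    ap = integer(), threshold_index = integer(), threshold_time = numeric(),
    threshold_voltage = numeric(), peak_index = integer(),
    peak_time = numeric(), peak_voltage = numeric())
  if (length(v) < 2) return(empty)
  dv <- central_dvdt(v, dt)
  if (smooth) dv <- smooth5(dv)
  above <- dv >= dvdt_threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_next <- c(run_start[-1] - 1L, length(v))
  n <- length(v)
  # local maxima (trace end counts when the voltage is still rising into it,
  # i.e. a clipped spike)
  is_max <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
              v[n] >= v[n - 1])
  rows <- list()
  for (k in seq_along(run_start)) {
    s <- run_start[k]
    e <- run_next[k]
    # peak = first local maximum after onset that passes acceptance; taking
    # the first (not the tallest) keeps one event per spike even when the
    # up-stroke only grazes the slope criterion
    seg <- s:e
    cand <- seg[is_max[seg] & v[seg] - v[s] >= min_amplitude &
                  v[seg] >= min_peak]
    if (!length(cand)) next
    pk <- cand[1]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      threshold_index = s, threshold_time = (s - 1L) * dt,
      threshold_voltage = v[s], peak_index = pk,
      peak_time = (pk - 1L) * dt, peak_voltage = v[pk])
  }
  if (!length(rows)) return(empty)
  out <- dplyr::bind_rows(rows)
  out <- out[!duplicated(out$peak_index), ]
  out <- out[order(out$threshold_index), ]
  dplyr::bind_cols(tibble::tibble(ap = seq_len(nrow(out))), out)
}

# linear-interpolated time where v crosses `level` between samples i and i+1,
# scanning indices `idx`; direction: "up" or "down"
cross_time <- function(v, dt, idx, level, direction) {
  if (length(idx) < 2) return(NA_real_)
  a <- v[idx[-length(idx)]]
  b <- v[idx[-1]]
  hit <- if (direction == "up") which(a < level & b >= level)
         else which(a >= level & b < level)
  if (!length(hit)) return(NA_real_)
  j <- hit[1]
  frac <- (level - a[j]) / (b[j] - a[j])
  (idx[j] - 1L + frac) * dt
}

#' Per-AP waveform features
#'
#' For every detected AP: amplitude (threshold to peak), half-width (time
#' between the two half-amplitude crossings, sub-sample by linear
#' interpolation), rise time (threshold to peak), and the extrema of the
#' central-difference dV/dt with the voltages at which they occur. The
#' derivative window runs from the AP threshold to the next AP's threshold
#' or `peak + post_ms`, whichever is first. A clipped spike (peak at the
#' trace end) yields `NA` features.
#'
#' @param sweep A [new_sweep()].
#' @param events Event table from [detect_aps()]; detected on `sweep`.
#' @param post_ms Window after the peak for the falling phase (ms).
#' @return Tibble, one row per AP: `ap`, `amplitude`, `half_width`,
#'   `rise_time`, `max_dvdt`, `voltage_at_max_dvdt`, `min_dvdt`,
#'   `voltage_at_min_dvdt`, `peak_voltage`, `threshold_voltage`, `clipped`.
#' @export
ap_waveform_features <- function(sweep, events = detect_aps(sweep),
                                 post_ms = 5) {
  v <- sweep$voltage
  dt <- sweep$sampling_interval
  dv <- central_dvdt(v, dt)
  n <- nrow(events)
  if (n == 0) return(empty_waveform_table())
  purrr::map_dfr(seq_len(n), function(i) {
    thr <- events$threshold_index[i]
    pk <- events$peak_index[i]
    clipped <- pk >= length(v)
    win_end <- if (i < n) events$threshold_index[i + 1] - 1L
               else min(length(v), pk + round(post_ms / dt))
    if (clipped)
      return(tibble::tibble(
        ap = events$ap[i], amplitude = NA_real_, half_width = NA_real_,
        rise_time = NA_real_, max_dvdt = NA_real_,
        voltage_at_max_dvdt = NA_real_, min_dvdt = NA_real_,
        voltage_at_min_dvdt = NA_real_,
        peak_voltage = events$peak_voltage[i],
        threshold_voltage = events$threshold_voltage[i], clipped = TRUE))
    amp <- events$peak_voltage[i] - events$threshold_voltage[i]
    half <- events$threshold_voltage[i] + amp / 2
    t_up <- cross_time(v, dt, thr:pk, half, "up")
    t_dn <- cross_time(v, dt, pk:win_end, half, "down")
    dwin <- thr:win_end
    jmax <- dwin[which.max(dv[dwin])]
    jmin <- dwin[which.min(dv[dwin])]
    tibble::tibble(
      ap = events$ap[i],
      amplitude = amp,
      half_width = if (is.na(t_up) || is.na(t_dn)) NA_real_ else t_dn - t_up,
      rise_time = events$peak_time[i] - events$threshold_time[i],
      max_dvdt = dv[jmax], voltage_at_max_dvdt = v[jmax],
      min_dvdt = dv[jmin], voltage_at_min_dvdt = v[jmin],
      peak_voltage = events$peak_voltage[i],
      threshold_voltage = events$threshold_voltage[i],
      clipped = FALSE)
  })
}

#' Afterhyperpolarization and afterdepolarization features
#'
#' The AHP window of an AP runs from its peak to the next AP's threshold,
#' or — for the last AP of a sweep — to the step end or `peak + cap_ms`,
#' whichever comes first. With `V_min` the window minimum:
#' `ahp_amplitude = threshold_voltage - V_min` (positive when the voltage
#' dips below threshold); `ahp_length` is the time from `V_min` to the first
#' recovery to the 90% level (`threshold - 0.1 * ahp_amplitude`);
#' `ahp_area` is the trapezoidal integral of `(90% level - V)` between those
#' two points; and `adp_amplitude = next threshold - V_min` when a next AP
#' exists. When the voltage never dips below threshold the AHP features are
#' 0 and `ahp_absent` is flagged.
#'
#' @inheritParams ap_waveform_features
#' @param cap_ms Window cap after the last AP's peak (ms, default 100).
#' @return Tibble, one row per AP: `ap`, `ahp_amplitude`, `ahp_length`,
#'   `ahp_area`, `adp_amplitude`, `ahp_absent`.
#' @export
ahp_adp_features <- function(sweep, events = detect_aps(sweep),
                             cap_ms = 100) {
  v <- sweep$voltage
  dt <- sweep$sampling_interval
  step_end <- floor((sweep$step_onset + sweep$step_duration) / dt) + 1L
  n <- nrow(events)
  if (n == 0) return(empty_ahp_table())
  purrr::map_dfr(seq_len(n), function(i) {
    pk <- events$peak_index[i]
    thr_v <- events$threshold_voltage[i]
    has_next <- i < n
    w1 <- if (has_next) events$threshold_index[i + 1]
          else min(max(step_end, pk), pk + round(cap_ms / dt), length(v))
    out <- tibble::tibble(ap = events$ap[i], ahp_amplitude = 0,
                          ahp_length = NA_real_, ahp_area = NA_real_,
                          adp_amplitude = NA_real_, ahp_absent = TRUE)
    if (w1 <= pk) return(out)
    win <- pk:w1
    jmin <- win[which.min(v[win])]
    vmin <- v[jmin]
    if (vmin >= thr_v) return(out)  # no dip below threshold
    amp <- thr_v - vmin
    level90 <- thr_v - 0.1 * amp
    t_min <- (jmin - 1L) * dt
    t90 <- cross_time(v, dt, jmin:w1, level90, "up")
    area <- NA_real_
    if (!is.na(t90)) {
      # trapezoid of (level90 - V) from the minimum to the 90% crossing,
      # with the interpolated crossing as final node (depth 0 there)
      js <- jmin:floor(t90 / dt + 1L)
      tt <- c((js - 1L) * dt, t90)
      yy <- c(level90 - v[js], 0)
      area <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
    }
    out$ahp_amplitude <- amp
    out$ahp_length <- if (is.na(t90)) NA_real_ else t90 - t_min
    out$ahp_area <- area
    out$ahp_absent <- FALSE
    if (has_next)
      out$adp_amplitude <- events$threshold_voltage[i + 1] - vmin
    out
  })
}

#' Phase-plane trajectory of one AP
#'
#' Returns the (V, dV/dt) pairs over the window from 1 ms before the AP
#' threshold to 10 ms after it, with the derivative by central differences.
#' The maximum of the dV/dt column equals the `max_dvdt` waveform feature by
#' construction. Windows reaching past the trace are truncated and flagged.
#'
#' @param sweep A [new_sweep()].
#' @param event One row of the [detect_aps()] table.
#' @param pre_ms,post_ms Window around the threshold (ms).
#' @return Tibble with columns `time`, `voltage`, `dvdt`; attribute
#'   `truncated`.
#' @export
phase_plot <- function(sweep, event, pre_ms = 1, post_ms = 10) {
  stopifnot(nrow(event) == 1)
  v <- sweep$voltage
  dt <- sweep$sampling_interval
  i0 <- event$threshold_index - round(pre_ms / dt)
  i1 <- event$threshold_index + round(post_ms / dt)
  truncated <- i0 < 1 || i1 > length(v)
  i0 <- max(1L, i0)
  i1 <- min(length(v), i1)
  dv <- central_dvdt(v, dt)
  out <- tibble::tibble(time = (i0:i1 - 1L) * dt, voltage = v[i0:i1],
                        dvdt = dv[i0:i1])
  attr(out, "truncated") <- truncated
  out
}

empty_waveform_table <- function() {
  tibble::tibble(
    ap = integer(), amplitude = numeric(), half_width = numeric(),
    rise_time = numeric(), max_dvdt = numeric(),
    voltage_at_max_dvdt = numeric(), min_dvdt = numeric(),
    voltage_at_min_dvdt = numeric(), peak_voltage = numeric(),
    threshold_voltage = numeric(), clipped = logical())
}

empty_ahp_table <- function() {
  tibble::tibble(
    ap = integer(), ahp_amplitude = numeric(), ahp_length = numeric(),
    ahp_area = numeric(), adp_amplitude = numeric(), ahp_absent = logical())
}
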