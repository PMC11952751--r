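# Analysis windows: baseline = mean over the `baseline_ms` before step onset,
# steady state = mean over the last `steady_ms` of the step. Conventional and
# robust to noise; both are configurable on every entry point.

sweep_window_mean <- function(sweep, t0, t1) {
  dt <- sweep$sampling_interval
  i0 <- max(1L, floor(t0 / dt) + 1L)
  i1 <- min(length(sweep$voltage), floor(t1 / dt) + 1L)
  if (i1 < i0) return(NA_real_)
  mean(sweep$voltage[i0:i1])
}

sweep_baseline <- function(sweep, baseline_ms = 100) {
  sweep_window_mean(sweep, sweep$step_onset - baseline_ms,
                    sweep$step_onset - sweep$sampling_interval)
}

sweep_steady_state <- function(sweep, steady_ms = 100) {
  end <- sweep$step_onset + sweep$step_duration
  sweep_window_mean(sweep, end - steady_ms, end - sweep$sampling_interval)
}

sweep_step_min <- function(sweep) {
  dt <- sweep$sampling_interval
  i0 <- floor(sweep$step_onset / dt) + 1L
  i1 <- min(length(sweep$voltage),
            floor((sweep$step_onset + sweep$step_duration) / dt) + 1L)
  v <- sweep$voltage[i0:i1]
  j <- which.min(v)
  list(value = v[j], time = (i0 + j - 2L) * dt)
}

hyperpolarizing_sweeps <- function(record) {
  Filter(function(s) s$current_amplitude < 0, record$sweeps)
}

na_reason <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' Input resistance from hyperpolarizing steps
#'
#' For every hyperpolarizing sweep the steady-state deflection
#' `dV = V_ss - V_baseline` is divided by the injected current; the cell's
#' input resistance is the mean of `dV / I` over those sweeps, in MOhm
#' (mV / pA * 1000).
#'
#' @param record A [cell_record()].
#' @param baseline_ms,steady_ms Analysis window lengths (ms).
#' @return Input resistance (MOhm), or `NA` with a `reason` attribute when
#'   no hyperpolarizing sweep exists.
#' @export
input_resistance <- function(record, baseline_ms = 100, steady_ms = 100) {
  hs <- hyperpolarizing_sweeps(record)
  if (!length(hs)) return(na_reason("no hyperpolarizing sweeps"))
  r <- vapply(hs, function(s) {
    dv <- sweep_steady_state(s, steady_ms) - sweep_baseline(s, baseline_ms)
    1000 * dv / s$current_amplitude
  }, numeric(1))
  mean(r)
}

#' Resting membrane potential
#'
#' Mean pre-step baseline voltage over all sweeps. When a holding current
#' was applied, the ohmic offset `holding * Rin` is subtracted
#' (compensation uses the cell's own [input_resistance()]).
#'
#' @inheritParams input_resistance
#' @return Resting potential (mV), or `NA` with a reason.
#' @export
resting_vm <- function(record, baseline_ms = 100, steady_ms = 100) {
  base <- vapply(record$sweeps, sweep_baseline, numeric(1),
                 baseline_ms = baseline_ms)
  if (all(is.na(base))) return(na_reason("no baseline window"))
  hold <- vapply(record$sweeps, function(s) s$holding_current, numeric(1))
  v <- mean(base, na.rm = TRUE)
  h <- mean(hold)
  if (h != 0) {
    rin <- input_resistance(record, baseline_ms, steady_ms)
    if (is.na(rin))
      return(na_reason("holding current set but input resistance undefined"))
    v <- v - h * rin / 1000
  }
  v
}

#' Membrane time constant by 63.2% crossing
#'
#' Per hyperpolarizing sweep, the time from step onset until the voltage
#' deflection first reaches 63.2% of its steady-state value, located by
#' linear interpolation between samples; the cell value is the mean across
#' sweeps. Sweeps whose deflection never reaches the 63.2% level are
#' skipped. An exponential-fit cross-check is available from
#' [subthreshold_features()] diagnostics.
#'
#' @inheritParams input_resistance
#' @return Time constant (ms), or `NA` with a reason.
#' @export
membrane_tau <- function(record, baseline_ms = 100, steady_ms = 100) {
  hs <- hyperpolarizing_sweeps(record)
  if (!length(hs)) return(na_reason("no hyperpolarizing sweeps"))
  taus <- vapply(hs, function(s) {
    b <- sweep_baseline(s, baseline_ms)
    ss <- sweep_steady_state(s, steady_ms)
    target <- b + 0.632 * (ss - b)
    dt <- s$sampling_interval
    i0 <- floor(s$step_onset / dt) + 1L
    i1 <- min(length(s$voltage),
              floor((s$step_onset + s$step_duration) / dt) + 1L)
    v <- s$voltage[i0:i1]
    # hyperpolarizing: first sample at or below the 63.2% level
    hit <- which(v <= target)
    if (!length(hit)) return(NA_real_)
    j <- hit[1]
    if (j == 1L) return(0)
    frac <- (target - v[j - 1]) / (v[j] - v[j - 1])
    ((j - 2L) + frac) * dt
  }, numeric(1))
  if (all(is.na(taus)))
    return(na_reason("deflection never reached 63.2% in any sweep"))
  mean(taus, na.rm = TRUE)
}

#' Sag ratio of the -100 pA sweep
#'
#' With baseline `V_b`, in-step minimum `V_min` and in-step steady state
#' `V_ss`, the sag ratio is `(V_ss - V_min) / (V_b - V_min)`: the fraction
#' of the peak hyperpolarizing deflection that relaxes back by the end of
#' the step. A passive membrane gives 0; an h-current gives values > 0.
#' The result is clamped to \[0, 1\] (noise can push the raw ratio
#' marginally outside).
#'
#' @inheritParams input_resistance
#' @param sag_amplitude Amplitude of the sag sweep (pA, default -100).
#' @return Sag ratio (unitless), or `NA` with a reason when the sag sweep is
#'   absent.
#' @export
sag_ratio <- function(record, sag_amplitude = -100, baseline_ms = 100,
                      steady_ms = 100) {
  amps <- record_amplitudes(record)
  i <- which(abs(amps - sag_amplitude) < 1e-9)
  if (!length(i))
    return(na_reason(sprintf("no %g pA sweep", sag_amplitude)))
  s <- record$sweeps[[i[1]]]
  b <- sweep_baseline(s, baseline_ms)
  ss <- sweep_steady_state(s, steady_ms)
  vmin <- sweep_step_min(s)$value
  if (b - vmin <= 0)
    return(na_reason("no hyperpolarizing deflection in sag sweep"))
  min(max((ss - vmin) / (b - vmin), 0), 1)
}

#' Rebound after the hyperpolarizing step
#'
#' The rebound is the maximum voltage in the 200 ms after step offset minus
#' the pre-step baseline, clamped at >= 0 (a trace that returns to baseline
#' without overshoot rebounds by 0). The rebound-sag ratio divides the
#' rebound by the sag amplitude `V_ss - V_min` of the same sweep. A
#' steady-state-referenced rebound is also reported for comparison, since
#' the two references differ by the residual steady-state offset.
#'
#' @inheritParams sag_ratio
#' @param window_ms Post-offset search window (ms, default 200).
#' @return Tibble with columns `rebound` (mV), `rebound_sag_ratio`,
#'   `rebound_from_steady` (mV).
#' @export
rebound_features <- function(record, sag_amplitude = -100,
                             baseline_ms = 100, steady_ms = 100,
                             window_ms = 200) {
  empty <- tibble::tibble(rebound = NA_real_,
                          rebound_sag_ratio = NA_real_,
                          rebound_from_steady = NA_real_)
  amps <- record_amplitudes(record)
  i <- which(abs(amps - sag_amplitude) < 1e-9)
  if (!length(i)) return(empty)
  s <- record$sweeps[[i[1]]]
  dt <- s$sampling_interval
  off <- s$step_onset + s$step_duration
  i0 <- floor(off / dt) + 1L
  i1 <- floor((off + window_ms) / dt) + 1L
  if (i1 > length(s$voltage)) return(empty)  # insufficient post-step window
  b <- sweep_baseline(s, baseline_ms)
  ss <- sweep_steady_state(s, steady_ms)
  vmin <- sweep_step_min(s)$value
  vmax <- max(s$voltage[i0:i1])
  reb <- max(vmax - b, 0)
  sag_amp <- ss - vmin
  tibble::tibble(
    rebound = reb,
    rebound_sag_ratio = if (sag_amp > 0) reb / sag_amp else NA_real_,
    rebound_from_steady = max(vmax - ss, 0))
}

#' All subthreshold features of a cell
#'
#' Convenience wrapper computing resting Vm, input resistance, tau, sag
#' ratio and the rebound features in one tibble row. Per-sweep diagnostics
#' (baseline, in-step minimum, steady state, interpolated tau and a
#' single-exponential-fit tau per hyperpolarizing sweep) are attached as the
#' `diagnostics` attribute.
#'
#' @inheritParams sag_ratio
#' @return One-row tibble.
#' @export
subthreshold_features <- function(record, sag_amplitude = -100,
                                  baseline_ms = 100, steady_ms = 100) {
  out <- tibble::tibble(
    resting_vm = as.numeric(resting_vm(record, baseline_ms, steady_ms)),
    input_resistance = as.numeric(
      input_resistance(record, baseline_ms, steady_ms)),
    tau = as.numeric(membrane_tau(record, baseline_ms, steady_ms)),
    sag_ratio = as.numeric(
      sag_ratio(record, sag_amplitude, baseline_ms, steady_ms)))
  out <- dplyr::bind_cols(
    out, rebound_features(record, sag_amplitude, baseline_ms, steady_ms))
  diag <- purrr::map_dfr(hyperpolarizing_sweeps(record), function(s) {
    tibble::tibble(
      current_amplitude = s$current_amplitude,
      baseline = sweep_baseline(s, baseline_ms),
      step_min = sweep_step_min(s)$value,
      steady_state = sweep_steady_state(s, steady_ms),
      tau_fit = fit_exponential_tau(s, baseline_ms))
  })
  attr(out, "diagnostics") <- diag
  out
}

# least-squares single-exponential fit of the onset transient; diagnostic
# cross-check for the interpolated 63.2% tau
fit_exponential_tau <- function(sweep, baseline_ms = 100, fit_ms = 150) {
  dt <- sweep$sampling_interval
  b <- sweep_baseline(sweep, baseline_ms)
  ss <- sweep_steady_state(sweep)   # end-of-step plateau, outside the fit
  i0 <- floor(sweep$step_onset / dt) + 1L
  i1 <- min(length(sweep$voltage), i0 + floor(fit_ms / dt))
  t <- (seq(i0, i1) - i0) * dt
  v <- sweep$voltage[i0:i1]
  z <- (v - ss) / (b - ss)
  ok <- z > 0.02 & t > 0
  if (sum(ok) < 5) return(NA_real_)
  # log-linear fit of z ~ exp(-t/tau)
  fit <- stats::lm.fit(cbind(1, t[ok]), log(z[ok]))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  -1 / slope
}
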