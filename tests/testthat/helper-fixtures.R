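# Fixture builders used across the suite. Everything is constructed in code;
# no binary fixtures.

# analytic RC response to a square step: V = E + I*R*(1 - exp(-t/tau)) during
# the step, discharging back afterwards
make_rc_sweep <- function(R_mohm = 100, tau_ms = 20, E_mv = -70,
                          I_pa = -100, dt = 0.05, onset = 200, dur = 800,
                          post = 300, holding = 0) {
  t <- seq(0, onset + dur + post, by = dt)
  defl <- I_pa * R_mohm / 1000   # mV
  base <- E_mv + holding * R_mohm / 1000
  v <- rep(base, length(t))
  during <- t >= onset & t < onset + dur
  v[during] <- base + defl * (1 - exp(-(t[during] - onset) / tau_ms))
  after <- t >= onset + dur
  v_end <- base + defl * (1 - exp(-dur / tau_ms))
  v[after] <- base + (v_end - base) * exp(-(t[after] - onset - dur) / tau_ms)
  new_sweep(v, I_pa, onset, dur, dt, holding)
}

make_rc_record <- function(R_mohm = 100, tau_ms = 20, E_mv = -70,
                           amps = seq(-100, -20, by = 20), dt = 0.05,
                           holding = 0, cell_id = "rc", ...) {
  sweeps <- lapply(amps, function(a)
    make_rc_sweep(R_mohm, tau_ms, E_mv, a, dt = dt, holding = holding))
  cell_record(sweeps, cell_id = cell_id, ...)
}

# a sweep of constant baseline with triangular spikes (linear up/down)
# embedded at the given times
make_spike_sweep <- function(spike_times_ms, baseline = -50, peak = 30,
                             rise_ms = 1, fall_ms = 1, dt = 0.05,
                             onset = 200, dur = 800, post = 300,
                             amplitude_pa = 100) {
  t <- seq(0, onset + dur + post, by = dt)
  v <- rep(baseline, length(t))
  for (ts in spike_times_ms) {
    up <- t >= ts & t < ts + rise_ms
    v[up] <- baseline + (peak - baseline) * (t[up] - ts) / rise_ms
    dn <- t >= ts + rise_ms & t <= ts + rise_ms + fall_ms
    v[dn] <- peak - (peak - baseline) * (t[dn] - ts - rise_ms) / fall_ms
  }
  new_sweep(v, amplitude_pa, onset, dur, dt, 0)
}

# piecewise-linear trace from (time, voltage) anchor points
make_piecewise_sweep <- function(times, voltages, dt = 0.05, onset = 200,
                                 dur = 800, post = 300,
                                 amplitude_pa = 100) {
  t <- seq(0, onset + dur + post, by = dt)
  v <- stats::approx(times, voltages, xout = t, rule = 2)$y
  new_sweep(v, amplitude_pa, onset, dur, dt, 0)
}

# the worked toy morphology: apical trunk (0,0)->(0,100) with children to
# (-30,140) and (30,140); one basal branch (0,0)->(0,-80)
toy_morphology <- function() {
  nodes <- tibble::tibble(
    id = 1:5,
    parent_id = c(-1L, 1L, 2L, 2L, 1L),
    compartment = c("soma", "apical", "apical", "apical", "basal"),
    x = c(0, 0, -30, 30, 0),
    y = c(0, 100, 140, 140, -80),
    z = 0,
    radius = c(6, 1, 1, 1, 1))
  morphology(nodes)
}

shift_record <- function(record, offset) {
  sweeps <- lapply(record$sweeps, function(s) {
    s$voltage <- s$voltage + offset
    s
  })
  cell_record(sweeps, cell_id = record$cell_id, age = record$age)
}
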