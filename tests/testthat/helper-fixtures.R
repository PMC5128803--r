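# Synthetic trace/window fixtures built in code.

# a torsim_trace with the documented public fields
synth_trace <- function(time_ms, V_mV, stimulus_times = 0,
                        stim_duration_ms = 1, frequency_hz = 0.5) {
  structure(
    list(time_ms = time_ms, V_mV = V_mV, states = NULL,
         stimulus_times = stimulus_times,
         stim_duration_ms = stim_duration_ms,
         stimulus_amplitude = 50, frequency_hz = frequency_hz,
         model_kind = "endocardial", final_state = NULL),
    class = "torsim_trace"
  )
}

# single-beat window via the public segmentation path
synth_window <- function(time_ms, V_mV, stim_duration_ms = 1) {
  tr <- synth_trace(time_ms, V_mV, stimulus_times = time_ms[1],
                    stim_duration_ms = stim_duration_ms)
  segment_beats(tr)$windows[[1]]
}

# rectangular AP: rest, instant upstroke, plateau of `dur_ms`, instant return
square_ap_window <- function(dur_ms = 200, rest = -80, peak = 20,
                             total_ms = 600, dt = 0.5) {
  t <- seq(0, total_ms, by = dt)
  v <- ifelse(t > 1 & t <= 1 + dur_ms, peak, rest)
  v[1] <- rest
  synth_window(t, v)
}

# instant upstroke then strictly linear repolarization over `ramp_ms`
linear_repol_window <- function(rest = -80, peak = 20, ramp_ms = 300,
                                total_ms = 600, dt = 0.5) {
  t <- seq(0, total_ms, by = dt)
  v <- numeric(length(t))
  for (i in seq_along(t)) {
    v[i] <- if (t[i] <= 1) {
      rest
    } else if (t[i] <= 1 + ramp_ms) {
      peak - (peak - rest) * (t[i] - 1) / ramp_ms
    } else {
      rest
    }
  }
  synth_window(t, v)
}

# randomized strictly monotone repolarization (no EAD by construction)
monotone_ap_window <- function() {
  rest <- runif(1, -90, -75)
  peak <- runif(1, 10, 45)
  ramp <- runif(1, 150, 500)
  total <- ramp + runif(1, 50, 300)
  dt <- 0.5
  t <- seq(0, total + 2, by = dt)
  shape <- runif(1, 0.5, 3) # convexity of the decay
  v <- vapply(t, function(tt) {
    if (tt <= 1) return(rest)
    x <- min((tt - 1) / ramp, 1)
    peak - (peak - rest) * x^shape
  }, 0)
  synth_window(t, v)
}

# repolarization interrupted by a secondary depolarization of `hump_mv`
# (piecewise linear: decline to -30 mV, bump up and back over 50 ms, then
# complete repolarization); hump_mv = 0 gives a monotone control
ead_ap_window <- function(hump_mv = 10, rest = -80, peak = 20) {
  t <- seq(0, 500, by = 0.5)
  v <- vapply(t, function(tt) {
    if (tt <= 1) return(rest)
    if (tt <= 200) return(peak - (peak - (-30)) * (tt - 1) / 199)
    if (tt <= 225) return(-30 + hump_mv * (tt - 200) / 25)
    if (tt <= 250) return(-30 + hump_mv * (250 - tt) / 25)
    if (tt <= 420) return(-30 - (rest + 30) * -((tt - 250) / 170))
    rest
  }, 0)
  synth_window(t, v)
}

# fast protocols for unit tests that don't probe the steady state
quick_protocol <- function(model, pre = 10, record = 2, ...) {
  default_protocol(model, pre_pacing_beats = pre, record_beats = record, ...)
}

# the deep-I_Kr-block multichannel torsadogen used in step-protocol tests
torsadogen_profile <- function() {
  drug_profile("torsadogen", ic50_na = 1e-5, ic50_cal = 3e-5,
               ic50_kr = 1e-8, ik1_block_pct = 0,
               concentration = 1.4e-7, known_group = "A1")
}

# moderate pure-I_Kr blocker at its IC50 (half-maximal block)
sotalol_like_profile <- function() {
  drug_profile("sotalol_like", ic50_kr = 1e-4, concentration = 1e-4,
               known_group = "A1")
}

# independent truth table for the pD2 decision tree, written directly from
# the triage rules (kept separate from the implementation on purpose)
tree_oracle <- function(pd2_kr, pd2_cal, other_blocked) {
  if (is.na(pd2_kr)) return("SAFE_LIKELY")
  if (pd2_kr < 6) {
    if (!other_blocked && is.na(pd2_cal)) return("A1_CANDIDATE")
    return("NEEDS_FULL_PANEL")
  }
  if (!is.na(pd2_cal) && pd2_cal > pd2_kr) return("GROUP_C")
  "NEEDS_SIMULATION"
}
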