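## Pacing protocols and simulation drivers.
##
## All protocols integrate the stiff model ODEs with deSolve::lsoda,
## beat-segmented so the stimulus is an exact square current pulse (the
## segment boundaries fall on the pulse edges). Pre-pacing beats are
## integrated with sparse output; recorded beats on a dense grid
## (0.5 ms default) for biomarker extraction.

.torsim_cache <- new.env(parent = emptyenv())

# gating variables live in [0, 1]; the solver may overshoot by O(rtol)
# during the upstroke. Project back, refusing violations beyond tolerance.
.GATE_TOL <- 1e-5
.clamp_gates <- function(kind, m) {
  gi <- if (kind == "purkinje") c(2:7, 9) else 2:7
  g <- m[, gi, drop = FALSE]
  if (any(g < -.GATE_TOL) || any(g > 1 + .GATE_TOL)) {
    stop("gating variable escaped [0, 1] beyond solver tolerance",
         call. = FALSE)
  }
  m[, gi] <- pmin(pmax(g, 0), 1)
  m
}

.RTOL <- 1e-6
.ATOL <- 1e-8

#' Pacing protocol definition
#'
#' @param frequency_hz pacing rate; the standard protocols use 0.5 Hz for
#'   the endocardial model and 0.3 Hz for the Purkinje model (slow pacing
#'   exposes bradycardia-dependent repolarization failure).
#' @param stimulus_amplitude depolarizing stimulus amplitude in A/F
#'   (positive magnitude); `NULL` means 1.5 x the model's diastolic
#'   threshold, found once per model by bisection.
#' @param stimulus_duration_ms square-pulse duration (ms).
#' @param pre_pacing_beats beats discarded before measurement (90 beats at
#'   0.5 Hz = 3 min).
#' @param record_beats number of final beats recorded densely.
#' @return Object of class `torsim_protocol`.
#' @export
pacing_protocol <- function(frequency_hz = 0.5, stimulus_amplitude = NULL,
                            stimulus_duration_ms = 1, pre_pacing_beats = 90,
                            record_beats = 3) {
  if (!is.numeric(frequency_hz) || frequency_hz <= 0) {
    stop("frequency_hz must be > 0", call. = FALSE)
  }
  period <- 1000 / frequency_hz
  if (stimulus_duration_ms <= 0 || stimulus_duration_ms >= period) {
    stop("stimulus_duration_ms must be in (0, pacing period)", call. = FALSE)
  }
  if (!is.null(stimulus_amplitude) &&
      (!is.numeric(stimulus_amplitude) || stimulus_amplitude < 0)) {
    stop("stimulus_amplitude must be >= 0 (A/F, depolarizing magnitude)",
         call. = FALSE)
  }
  if (pre_pacing_beats < 0 || record_beats < 1) {
    stop("need pre_pacing_beats >= 0 and record_beats >= 1", call. = FALSE)
  }
  structure(
    list(frequency_hz = frequency_hz, stimulus_amplitude = stimulus_amplitude,
         stimulus_duration_ms = stimulus_duration_ms,
         pre_pacing_beats = pre_pacing_beats, record_beats = record_beats),
    class = "torsim_protocol"
  )
}

#' Default protocol for a model
#'
#' 0.5 Hz with 90 pre-pacing beats (3 min) for the endocardial model;
#' 0.3 Hz with 54 pre-pacing beats (3 min) for the Purkinje model.
#'
#' @param model a [make_model()] object.
#' @param ... overrides passed to [pacing_protocol()].
#' @export
default_protocol <- function(model, ...) {
  stopifnot(inherits(model, "torsim_model"))
  args <- if (model$kind == "endocardial") {
    list(frequency_hz = 0.5, pre_pacing_beats = 90)
  } else {
    list(frequency_hz = 0.3, pre_pacing_beats = 54)
  }
  do.call(pacing_protocol, utils::modifyList(args, list(...)))
}

#' Diastolic stimulus threshold of a model
#'
#' Minimum amplitude of a 1 ms square pulse, applied from the diastolic
#' equilibrium, that elicits an action potential (peak above 0 mV), found
#' by bisection to ~1% and cached per model kind.
#'
#' @param model a [make_model()] object.
#' @param stimulus_duration_ms pulse duration used for the search.
#' @return Threshold amplitude (A/F, positive magnitude).
#' @export
find_diastolic_threshold <- function(model, stimulus_duration_ms = 1) {
  stopifnot(inherits(model, "torsim_model"))
  key <- paste0("thr_", model$kind, "_", stimulus_duration_ms)
  if (!is.null(.torsim_cache[[key]])) return(.torsim_cache[[key]])
  p <- model$nominal_params
  fn <- .make_ode_fn(model$kind, p)
  y0 <- model$initial_state
  elicits <- function(amp) {
    o1 <- deSolve::lsoda(y0, c(0, stimulus_duration_ms),
                         function(t, y, q) fn(t, y, -amp), NULL,
                         rtol = .RTOL, atol = .ATOL)
    o2 <- deSolve::lsoda(o1[nrow(o1), -1], seq(0, 600, 2),
                         function(t, y, q) fn(t, y, 0), NULL,
                         rtol = .RTOL, atol = .ATOL)
    max(o2[, 2]) > 0
  }
  lo <- 0.5
  hi <- 120
  if (!elicits(hi)) stop("no threshold below 120 A/F", call. = FALSE)
  for (i in 1:13) {
    mid <- (lo + hi) / 2
    if (elicits(mid)) hi <- mid else lo <- mid
  }
  .torsim_cache[[key]] <- hi
  hi
}

.resolve_amplitude <- function(model, protocol) {
  if (!is.null(protocol$stimulus_amplitude)) return(protocol$stimulus_amplitude)
  1.5 * find_diastolic_threshold(model, protocol$stimulus_duration_ms)
}

## integrate `n_beats` paced beats from state y0; record the last
## `record_beats` densely. spm_switch: optional list(beat, spm) applied from
## that beat on (parameters rebuilt). Returns trace + final state.
.integrate_beats <- function(model, params, protocol, y0, n_beats,
                             record_beats, dt_out = 0.5, t0 = 0,
                             keep_states = FALSE, rtol = .RTOL,
                             atol = .ATOL) {
  amp <- .resolve_amplitude(model, protocol)
  period <- 1000 / protocol$frequency_hz
  dur <- protocol$stimulus_duration_ms
  fn <- .make_ode_fn(model$kind, params)
  f_stim <- function(t, y, q) fn(t, y, -amp)
  f_free <- function(t, y, q) fn(t, y, 0)
  y <- y0
  out_t <- list()
  out_y <- list()
  stim_times <- numeric(0)
  for (b in seq_len(n_beats)) {
    rec <- b > n_beats - record_beats
    tb <- t0 + (b - 1) * period
    ts1 <- if (rec) seq(0, dur, by = min(0.1, dur / 4)) else c(0, dur)
    o1 <- deSolve::lsoda(y, ts1, f_stim, NULL, rtol = rtol, atol = atol,
                         maxsteps = 50000)
    o1[, -1] <- .clamp_gates(model$kind, o1[, -1, drop = FALSE])
    y <- o1[nrow(o1), -1]
    ts2 <- if (rec) seq(dur, period, by = dt_out) else c(dur, period)
    o2 <- deSolve::lsoda(y, ts2, f_free, NULL, rtol = rtol, atol = atol,
                         maxsteps = 50000)
    o2[, -1] <- .clamp_gates(model$kind, o2[, -1, drop = FALSE])
    y <- o2[nrow(o2), -1]
    if (!all(is.finite(y))) {
      stop(sprintf("solver failure (non-finite state) at t = %.1f ms",
                   tb + period), call. = FALSE)
    }
    if (rec) {
      seg <- rbind(o1[-nrow(o1), , drop = FALSE], o2)
      out_t[[length(out_t) + 1]] <- seg[, 1] + tb
      out_y[[length(out_y) + 1]] <- seg[, -1, drop = FALSE]
      stim_times <- c(stim_times, tb)
    }
  }
  tt <- unlist(out_t)
  ym <- do.call(rbind, out_y)
  keep <- !duplicated(tt) # beat joins share their boundary sample
  tt <- tt[keep]
  ym <- ym[keep, , drop = FALSE]
  structure(
    list(time_ms = tt, V_mV = ym[, 1],
         states = if (keep_states) ym else NULL,
         stimulus_times = stim_times, stim_duration_ms = dur,
         stimulus_amplitude = amp, frequency_hz = protocol$frequency_hz,
         model_kind = model$kind, final_state = y),
    class = "torsim_trace"
  )
}

#' @export
print.torsim_trace <- function(x, ...) {
  cat(sprintf("<torsim_trace: %s, %.3g-%.3g ms, %d stimuli at %g Hz>\n",
              x$model_kind, min(x$time_ms), max(x$time_ms),
              length(x$stimulus_times), x$frequency_hz))
  invisible(x)
}

#' Integrate a model under a pacing protocol
#'
#' Deterministic stiff integration (lsoda, rtol 1e-6 / atol 1e-8) with the
#' stimulus applied as a square current pulse at each pacing time. All
#' `pre_pacing_beats + record_beats` beats are integrated; the recorded
#' beats are returned on a dense output grid.
#'
#' @param model a [make_model()] object.
#' @param params parameters from [model_params()] (default: nominal).
#' @param protocol a [pacing_protocol()] (default: [default_protocol()]).
#' @param init_state starting state (default: the model's diastolic
#'   equilibrium).
#' @param dt_out output grid step for recorded beats (ms).
#' @param keep_states keep the full state matrix (for gate inspection).
#' @param rtol,atol solver relative/absolute tolerance (defaults 1e-6,
#'   1e-8).
#' @return A `torsim_trace`: `time_ms`, `V_mV`, `stimulus_times`,
#'   `final_state`, and optionally `states`.
#' @export
integrate_model <- function(model, params = NULL, protocol = NULL,
                            init_state = NULL, dt_out = 0.5,
                            keep_states = FALSE, rtol = .RTOL,
                            atol = .ATOL) {
  stopifnot(inherits(model, "torsim_model"))
  if (is.null(params)) params <- model$nominal_params
  .validate_params(params)
  if (is.null(protocol)) protocol <- default_protocol(model)
  if (is.null(init_state)) init_state <- model$initial_state
  n <- protocol$pre_pacing_beats + protocol$record_beats
  .integrate_beats(model, params, protocol, init_state, n,
                   protocol$record_beats, dt_out = dt_out,
                   keep_states = keep_states, rtol = rtol, atol = atol)
}

#' Pace to steady state and return the final beats
#'
#' Applies the drug (conductance-block factors) once, paces through the
#' pre-pacing budget and returns the dense trace of the final
#' `record_beats` beats with stimulus bookkeeping.
#'
#' @inheritParams integrate_model
#' @param drug a [drug_profile()], [directive_block()], or `NULL`.
#' @return A `torsim_trace`.
#' @export
run_paced_to_steady <- function(model, params = NULL, drug = NULL,
                                protocol = NULL, keep_states = FALSE) {
  stopifnot(inherits(model, "torsim_model"))
  if (is.null(params)) params <- model$nominal_params
  if (is.null(protocol)) protocol <- default_protocol(model)
  if (protocol$pre_pacing_beats + protocol$record_beats < 1) {
    stop("need at least one beat", call. = FALSE)
  }
  integrate_model(model, apply_drug(params, drug), protocol,
                  keep_states = keep_states)
}

#' Spermine step schedule
#'
#' @param spm_pre,spm_post intracellular spermine (uM) before / after the
#'   switch; defaults 3 (population mean) and 5 (the less-than-two-fold
#'   metabolic rise).
#' @param switch_time_s,total_time_s switch time and total duration (s);
#'   defaults 180 and 360 (3 min at each level).
#' @export
spm_step_schedule <- function(spm_pre = 3, spm_post = 5,
                              switch_time_s = 180, total_time_s = 360) {
  if (spm_pre < 0 || spm_post < 0) stop("spm must be >= 0", call. = FALSE)
  if (switch_time_s < 0 || switch_time_s > total_time_s) {
    stop("need 0 <= switch_time_s <= total_time_s", call. = FALSE)
  }
  structure(list(spm_pre = spm_pre, spm_post = spm_post,
                 switch_time_s = switch_time_s, total_time_s = total_time_s),
            class = "torsim_spm_schedule")
}

#' Spermine-step protocol
#'
#' Paces continuously (0.5 Hz default) while intracellular spermine is
#' switched from `spm_pre` to `spm_post` at the scheduled time, under an
#' optional drug. Arrhythmia means any spontaneous (non-stimulus-aligned)
#' depolarization: an EAD in any beat or a spontaneous upstroke. The
#' latency is signed time from the switch to the first event.
#'
#' @inheritParams run_paced_to_steady
#' @param schedule a [spm_step_schedule()].
#' @param dt_out recorded output step (ms).
#' @return List of class `torsim_spm_step`: `trace`, `arrhythmia`,
#'   `latency_s` (NA when no event), `event_times_ms`, `switch_time_ms`.
#' @export
run_spm_step <- function(model, params = NULL, drug = NULL,
                         schedule = spm_step_schedule(), protocol = NULL,
                         dt_out = 1) {
  stopifnot(inherits(model, "torsim_model"),
            inherits(schedule, "torsim_spm_schedule"))
  if (is.null(params)) params <- model$nominal_params
  if (is.null(protocol)) {
    protocol <- default_protocol(model, pre_pacing_beats = 0)
  }
  params <- apply_drug(params, drug)
  period <- 1000 / protocol$frequency_hz
  n_pre <- round(schedule$switch_time_s * 1000 / period)
  n_post <- round((schedule$total_time_s - schedule$switch_time_s) *
                    1000 / period)
  p_pre <- params
  p_pre$spm <- schedule$spm_pre
  p_post <- params
  p_post$spm <- schedule$spm_post
  tr1 <- .integrate_beats(model, p_pre, protocol, model$initial_state,
                          n_pre, record_beats = n_pre, dt_out = dt_out)
  switch_ms <- n_pre * period
  tr2 <- .integrate_beats(model, p_post, protocol, tr1$final_state,
                          n_post, record_beats = n_post, dt_out = dt_out,
                          t0 = switch_ms)
  trace <- structure(
    list(time_ms = c(tr1$time_ms, tr2$time_ms),
         V_mV = c(tr1$V_mV, tr2$V_mV), states = NULL,
         stimulus_times = c(tr1$stimulus_times, tr2$stimulus_times),
         stim_duration_ms = protocol$stimulus_duration_ms,
         stimulus_amplitude = tr1$stimulus_amplitude,
         frequency_hz = protocol$frequency_hz, model_kind = model$kind,
         final_state = tr2$final_state),
    class = "torsim_trace"
  )
  seg <- segment_beats(trace)
  ead_times <- unlist(lapply(seg$windows, function(w) detect_ead(w)$times))
  events <- sort(c(ead_times, seg$spontaneous_times))
  structure(
    list(trace = trace, arrhythmia = length(events) > 0,
         latency_s = if (length(events)) (events[1] - switch_ms) / 1000
                     else NA_real_,
         event_times_ms = events, switch_time_ms = switch_ms),
    class = "torsim_spm_step"
  )
}

#' Spermine x L-type-conductance variability grid
#'
#' One steady-pacing run per (spm, g_CaL) combination under the given drug
#' or directive block (or none), with the per-cell EAD flag taken over the
#' recorded beats. Defaults reproduce the 16-cell study grid: spermine
#' {1, 2, 3, 5} uM (the five-fold dietary spread around the 3 uM mean) by
#' g_CaL {1.5, 2, 2.5, 3} pS/pF (the two-fold polymorphism range).
#'
#' @inheritParams run_paced_to_steady
#' @param spm_values,gcal_values grid axes (uM; pS/pF).
#' @return Object of class `torsim_grid`: data frame `cells` (one row per
#'   combination: `spm`, `g_CaL`, `apd90_ms`, `triangulation_ms`, `ead`,
#'   `incomplete`, `n_spontaneous`, `failed`), plus `ead_count`.
#' @export
run_variability_grid <- function(model, drug = NULL,
                                 spm_values = c(1, 2, 3, 5),
                                 gcal_values = c(1.5, 2.0, 2.5, 3.0),
                                 params = NULL, protocol = NULL) {
  stopifnot(inherits(model, "torsim_model"))
  if (!length(spm_values) || !length(gcal_values)) {
    stop("grid axes must be non-empty", call. = FALSE)
  }
  if (is.null(params)) params <- model$nominal_params
  if (is.null(protocol)) protocol <- default_protocol(model)
  cells <- expand.grid(spm = spm_values, g_CaL = gcal_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- params
    p$spm <- cells$spm[i]
    p$g_CaL <- cells$g_CaL[i]
    res <- tryCatch({
      tr <- run_paced_to_steady(model, p, drug, protocol)
      seg <- segment_beats(tr)
      ms <- lapply(seg$windows, ap_metrics)
      last <- ms[[length(ms)]]
      data.frame(
        spm = cells$spm[i], g_CaL = cells$g_CaL[i],
        apd90_ms = last$apd90, triangulation_ms = last$triangulation,
        ead = any(vapply(ms, function(m) m$ead, TRUE)),
        incomplete = any(vapply(ms, function(m) m$incomplete, TRUE)),
        n_spontaneous = length(seg$spontaneous_times), failed = FALSE
      )
    }, error = function(e) {
      data.frame(spm = cells$spm[i], g_CaL = cells$g_CaL[i],
                 apd90_ms = NA_real_, triangulation_ms = NA_real_,
                 ead = NA, incomplete = NA, n_spontaneous = NA_integer_,
                 failed = TRUE)
    })
    res
  })
  cells_df <- do.call(rbind, rows)
  structure(
    list(cells = cells_df,
         ead_count = sum(cells_df$ead %in% TRUE),
         spm_values = spm_values, gcal_values = gcal_values),
    class = "torsim_grid"
  )
}

#' @export
print.torsim_grid <- function(x, ...) {
  cat(sprintf("<torsim_grid: %d x %d cells, %d with EADs>\n",
              length(x$spm_values), length(x$gcal_values), x$ead_count))
  invisible(x)
}

#' Extreme-value population risk scan
#'
#' Evaluates all `3^n` combinations of `{mean - 3sd, mean, mean + 3sd}`
#' over `n` model parameters (each extreme level represents the 0.2% tail
#' of the population distribution, above or under mean +/- 3 SD). If any
#' combination is arrhythmic, the population risk is `0.002^n'` where `n'`
#' is the number of parameters at an extreme level in the minimal
#' arrhythmic combination; otherwise 0.
#'
#' @inheritParams run_paced_to_steady
#' @param parameter_specs a list of [population_spec()] objects (or a data
#'   frame with columns `name`, `mean`, `sd`, `floor`); names must be model
#'   parameters (e.g. `"spm"`, `"g_CaL"`).
#' @param outcome_fn optional predicate `function(params) -> logical`
#'   deciding arrhythmia for one parameter combination; defaults to a
#'   steady-pacing simulation flagged by EAD / spontaneous-event detection.
#' @return Object of class `torsim_popscan`: `combinations` (one row per
#'   combination: parameter values, `n_extreme`, `arrhythmia`), `n_prime`,
#'   `risk`, `clipped` (parameter floors applied).
#' @export
run_population_scan <- function(model, drug = NULL, parameter_specs,
                                params = NULL, protocol = NULL,
                                outcome_fn = NULL) {
  stopifnot(inherits(model, "torsim_model"))
  specs <- .as_spec_list(parameter_specs)
  if (!length(specs)) stop("need >= 1 parameter spec", call. = FALSE)
  if (is.null(params)) params <- model$nominal_params
  if (is.null(protocol)) protocol <- default_protocol(model)
  if (is.null(outcome_fn)) {
    outcome_fn <- function(p) {
      tr <- run_paced_to_steady(model, p, drug, protocol)
      seg <- segment_beats(tr)
      any(vapply(seg$windows, function(w) detect_ead(w)$ead, TRUE)) ||
        length(seg$spontaneous_times) > 0
    }
  }
  lv <- lapply(specs, extreme_levels)
  clipped <- any(vapply(lv, function(x) isTRUE(attr(x, "clipped")), TRUE))
  level_idx <- expand.grid(rep(list(c(-1L, 0L, 1L)), length(specs)),
                           KEEP.OUT.ATTRS = FALSE)
  names(level_idx) <- vapply(specs, function(s) s$name, "")
  combos <- level_idx
  for (j in seq_along(specs)) {
    combos[[j]] <- vapply(level_idx[[j]] + 2L, function(k) lv[[j]][[k]], 0)
  }
  n_extreme <- rowSums(level_idx != 0L)
  arrhythmia <- vapply(seq_len(nrow(combos)), function(i) {
    p <- params
    for (j in seq_along(specs)) p[[specs[[j]]$name]] <- combos[i, j]
    isTRUE(outcome_fn(p))
  }, TRUE)
  n_prime <- if (any(arrhythmia)) as.integer(min(n_extreme[arrhythmia])) else NA_integer_
  risk <- if (any(arrhythmia)) 0.002^n_prime else 0
  out <- cbind(combos, n_extreme = n_extreme, arrhythmia = arrhythmia)
  structure(
    list(combinations = out, n_prime = n_prime, risk = risk,
         clipped = clipped,
         parameter_specs = specs),
    class = "torsim_popscan"
  )
}

#' @export
print.torsim_popscan <- function(x, ...) {
  cat(sprintf("<torsim_popscan: %d combinations, n' = %s, risk = %g>\n",
              nrow(x$combinations),
              ifelse(is.na(x$n_prime), "-", x$n_prime), x$risk))
  invisible(x)
}
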