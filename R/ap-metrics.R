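## Per-beat action-potential biomarkers and arrhythmia flags.
##
## A trace is segmented into one window per stimulus; within a window the
## biomarkers are measured from the maximum-upstroke instant, with all level
## crossings linearly interpolated on the solver output grid. Early
## afterdepolarizations (EADs) are secondary depolarizations: a local
## minimum of membrane potential followed by a re-depolarization of at
## least `min_redep` mV sustained for at least `min_dur` ms, occurring
## after 30% and before 100% repolarization. Spontaneous (non-stimulus-
## aligned) upstrokes are detected by a dV/dt threshold outside stimulus
## windows.

.EAD_MIN_REDEP <- 2 # mV
.EAD_MIN_DUR <- 5 # ms
.SPONT_DVDT <- 5 # mV/ms
.STIM_ALIGN_MS <- 10 # window after stimulus onset attributed to pacing

#' Segment a paced trace into per-stimulus AP windows
#'
#' One window per stimulus, from stimulus onset to the next stimulus onset
#' (or end of trace). Spontaneous upstrokes — contiguous runs of
#' dV/dt above 5 mV/ms starting outside any stimulus-aligned window — are
#' reported separately.
#'
#' @param trace a `torsim_trace` from [integrate_model()] or
#'   [run_paced_to_steady()].
#' @return List with `windows` (list of `torsim_window`) and
#'   `spontaneous_times` (ms, onset of each spontaneous upstroke).
#' @export
segment_beats <- function(trace) {
  stopifnot(inherits(trace, "torsim_trace"))
  t <- trace$time_ms
  v <- trace$V_mV
  if (length(t) < 2) stop("empty trace", call. = FALSE)
  st <- trace$stimulus_times
  windows <- list()
  if (length(st)) {
    bounds <- c(st, t[length(t)] + 1e-9)
    for (k in seq_along(st)) {
      sel <- t >= bounds[k] & t < bounds[k + 1]
      if (sum(sel) < 3) next
      windows[[length(windows) + 1]] <- structure(
        list(time_ms = t[sel], V_mV = v[sel], stim_onset = st[k],
             stim_duration = trace$stim_duration_ms),
        class = "torsim_window"
      )
    }
  }
  list(windows = windows, spontaneous_times = .spontaneous_times(t, v, st))
}

.spontaneous_times <- function(t, v, stim_times) {
  if (length(t) < 3) return(numeric(0))
  dvdt <- diff(v) / diff(t)
  tm <- t[-length(t)]
  fast <- dvdt > .SPONT_DVDT
  aligned <- rep(FALSE, length(tm))
  for (s in stim_times) {
    aligned <- aligned | (tm >= s & tm < s + .STIM_ALIGN_MS)
  }
  onset <- which(fast & !aligned & !c(FALSE, fast[-length(fast)]))
  tm[onset]
}

## locate upstroke and repolarization reference levels within a window
.window_anatomy <- function(window) {
  t <- window$time_ms
  v <- window$V_mV
  dvdt <- c(diff(v) / diff(t), 0)
  i_up <- which.max(dvdt)
  rest <- v[1]
  i_peak <- which.max(v)
  amp <- v[i_peak] - rest
  list(t = t, v = v, dvdt = dvdt, i_up = i_up, i_peak = i_peak,
       rest = rest, amp = amp)
}

#' Action-potential duration at a repolarization level
#'
#' Time from the maximum-upstroke instant to the first crossing of
#' `rest + (1 - level/100) * amplitude` during repolarization, with linear
#' interpolation between samples. If repolarization to that level is not
#' reached before the window ends, the window length (from the upstroke) is
#' returned and the result carries attribute `incomplete = TRUE`.
#'
#' @param window a `torsim_window` from [segment_beats()].
#' @param level repolarization percentage in (0, 100), e.g. 90 for APD90.
#' @return Duration in ms (attribute `incomplete` flags failed
#'   repolarization).
#' @export
apd <- function(window, level) {
  stopifnot(inherits(window, "torsim_window"))
  if (!is.numeric(level) || level <= 0 || level >= 100) {
    stop("level must be in (0, 100)", call. = FALSE)
  }
  a <- .window_anatomy(window)
  thr <- a$rest + (1 - level / 100) * a$amp
  t_up <- a$t[a$i_up]
  idx <- seq(a$i_peak, length(a$v))
  below <- idx[a$v[idx] < thr]
  if (!length(below)) {
    return(structure(a$t[length(a$t)] - t_up, incomplete = TRUE))
  }
  j <- below[1]
  if (j == 1) return(structure(0, incomplete = FALSE))
  ## linear interpolation of the crossing between j-1 and j
  t_cross <- a$t[j - 1] + (a$t[j] - a$t[j - 1]) *
    (a$v[j - 1] - thr) / (a$v[j - 1] - a$v[j])
  structure(t_cross - t_up, incomplete = FALSE)
}

#' Detect early afterdepolarizations in an AP window
#'
#' An EAD is a local minimum of membrane potential followed by a
#' re-depolarization of at least `min_redep` mV sustained for at least
#' `min_dur` ms, occurring after 30% and before 100% repolarization
#' (measured from the within-window resting potential and amplitude), and
#' after the stimulus artifact.
#'
#' @param window a `torsim_window`.
#' @param min_redep minimum re-depolarization (mV).
#' @param min_dur minimum duration above the local minimum (ms).
#' @return List `ead` (logical) and `times` (ms, onset of each event).
#' @export
detect_ead <- function(window, min_redep = .EAD_MIN_REDEP,
                       min_dur = .EAD_MIN_DUR) {
  stopifnot(inherits(window, "torsim_window"))
  a <- .window_anatomy(window)
  if (a$amp <= 0) return(list(ead = FALSE, times = numeric(0)))
  hi <- a$rest + 0.7 * a$amp # 30% repolarized
  lo <- a$rest # 100% repolarized
  t <- a$t
  v <- a$v
  n <- length(v)
  after_stim <- t > window$stim_onset + window$stim_duration + .STIM_ALIGN_MS
  times <- numeric(0)
  i <- a$i_peak + 1
  while (i < n - 1) {
    if (after_stim[i] && v[i] < hi && v[i] > lo &&
        v[i] <= v[i - 1] && v[i] < v[i + 1]) {
      ## local minimum in the EAD band: measure the re-depolarization
      j <- i + 1
      vmax <- v[i]
      while (j <= n && v[j] >= v[i]) {
        if (v[j] > vmax) vmax <- v[j]
        j <- j + 1
      }
      dur <- t[min(j, n)] - t[i]
      if (vmax - v[i] >= min_redep && dur >= min_dur) {
        times <- c(times, t[i])
        i <- j
        next
      }
    }
    i <- i + 1
  }
  list(ead = length(times) > 0, times = times)
}

#' Per-beat biomarkers of one AP window
#'
#' @param window a `torsim_window`.
#' @return List of class `torsim_apmetrics`: `apd30`, `apd40`, `apd50`,
#'   `apd90` (ms), `amplitude` (mV), `resting_potential` (mV),
#'   `max_upstroke` (mV/ms), `triangulation` (= APD90 - APD40, ms), `ead`,
#'   `ead_times`, `incomplete` (repolarization failure flag).
#' @export
ap_metrics <- function(window) {
  a <- .window_anatomy(window)
  vals <- lapply(c(30, 40, 50, 90), function(l) apd(window, l))
  names(vals) <- c("apd30", "apd40", "apd50", "apd90")
  e <- detect_ead(window)
  structure(
    list(
      apd30 = as.numeric(vals$apd30), apd40 = as.numeric(vals$apd40),
      apd50 = as.numeric(vals$apd50), apd90 = as.numeric(vals$apd90),
      amplitude = a$amp, resting_potential = a$rest,
      max_upstroke = max(a$dvdt),
      triangulation = as.numeric(vals$apd90) - as.numeric(vals$apd40),
      ead = e$ead, ead_times = e$times,
      incomplete = isTRUE(attr(vals$apd90, "incomplete"))
    ),
    class = "torsim_apmetrics"
  )
}

#' Beat-by-beat metrics table for a trace
#'
#' @param trace a `torsim_trace`.
#' @return Tidy data frame, one row per paced beat: beat index, the
#'   [ap_metrics()] fields (`ead_times` collapsed to a `;`-separated
#'   string), and `n_spontaneous` events over the whole trace on row 1.
#' @export
beat_metrics <- function(trace) {
  seg <- segment_beats(trace)
  rows <- lapply(seq_along(seg$windows), function(i) {
    m <- ap_metrics(seg$windows[[i]])
    data.frame(
      beat = i, apd30_ms = m$apd30, apd40_ms = m$apd40, apd50_ms = m$apd50,
      apd90_ms = m$apd90, amplitude_mV = m$amplitude,
      resting_potential_mV = m$resting_potential,
      max_upstroke_mV_ms = m$max_upstroke, triangulation_ms = m$triangulation,
      ead = m$ead, ead_times_ms = paste(round(m$ead_times, 3), collapse = ";"),
      incomplete = m$incomplete
    )
  })
  out <- do.call(rbind, rows)
  out$n_spontaneous <- NA_integer_
  if (nrow(out)) out$n_spontaneous[1] <- length(seg$spontaneous_times)
  out
}

#' Paired drug-vs-control effect on one protocol
#'
#' @param control,drug [ap_metrics()] of the same protocol without / with
#'   the drug.
#' @param triang_threshold fractional increase of triangulation
#'   (APD90 - APD40) over control that counts as "triangulation present"
#'   (default 0.2, i.e. +20%).
#' @return List of class `torsim_effect`: `delta_apd90_pct`,
#'   `delta_triangulation_ms`, `triangulation_present`, `ead_emerged`.
#' @export
compare_effects <- function(control, drug, triang_threshold = 0.2) {
  stopifnot(inherits(control, "torsim_apmetrics"),
            inherits(drug, "torsim_apmetrics"))
  if (!is.finite(control$apd90) || control$apd90 == 0) {
    stop("control APD90 must be nonzero", call. = FALSE)
  }
  structure(
    list(
      delta_apd90_pct = 100 * (drug$apd90 - control$apd90) / control$apd90,
      delta_triangulation_ms = drug$triangulation - control$triangulation,
      triangulation_present =
        (drug$triangulation - control$triangulation) >
          triang_threshold * control$triangulation,
      ead_emerged = isTRUE(drug$ead) && !isTRUE(control$ead)
    ),
    class = "torsim_effect"
  )
}
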