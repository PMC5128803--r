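## Reduced single-cell human cardiac electrophysiology models.
##
## Two Hodgkin-Huxley-type membrane models are provided: an endocardial
## ventricular cell and a Purkinje cell. Both carry the five currents whose
## pharmacology drives torsadogenic risk assessment (I_Na, I_CaL, I_Kr, I_Ks
## and a spermine-rectified I_K1) plus a background Na+ leak; the Purkinje
## variant adds a hyperpolarization-activated funny current I_f and a weaker
## I_K1, giving it slow sub-threshold diastolic depolarization. Conventions:
## membrane potential in mV (intracellular minus extracellular), currents in
## A/F with outward positive, time in ms.

# Faraday / gas constants (SI)
.FARADAY <- 96485.33212
.GAS_R <- 8.314462618

# scale from the pharmacological g_CaL axis (pS/pF) to current density:
# I_CaL = g_CaL * .CAL_SCALE * d * f * (V - E_CaL)  [A/F]
.CAL_SCALE <- 0.038

# spermine block of I_K1: unblocked fraction u = 1/(1 + spm/Kd(V)),
# Kd(V) = K_ref * exp(-(V - E_K)/k_v). Calibrated so spm = 3 uM gives the
# model's nominal inward-rectifier profile (steep decay of outward I_K1
# with depolarization, peak near -60 mV).
.SPM_K_REF <- 24 # uM
.SPM_K_V <- 13 # mV

.MODEL_KINDS <- c("endocardial", "purkinje")

# diastolic equilibria of the two models (stimulus-free steady states,
# relaxed to |d/dt| < 1e-15 A/F resp. 1/ms)
.INIT_ENDO <- c(
  V = -8.2968468939e+01, m = 1.6194191829e-03, h = 9.4417438984e-01,
  d = 1.4211974105e-05, f = 9.9999077601e-01, xr = 1.2395158379e-04,
  xs = 2.3077396054e-03, Ca_i = 5.0018530430e-05
)
.INIT_PURK <- c(
  V = -7.6226284084e+01, m = 4.2317550752e-03, h = 8.4610601135e-01,
  d = 4.3717689984e-05, f = 9.9996447566e-01, xr = 3.2468631162e-04,
  xs = 3.7300681954e-03, Ca_i = 5.0054312216e-05, y = 5.5091804999e-01
)

.PARAMS_ENDO <- list(
  g_Na = 12, # nS/pF
  g_CaL = 2.0, # pS/pF (paper's variability axis, 1.5-3)
  g_Kr = 0.12, # nS/pF
  g_Ks = 0.006, # nS/pF
  g_K1 = 0.09, # nS/pF
  g_bNa = 0.002, # nS/pF
  g_f = 0, # nS/pF (Purkinje only)
  E_f = -20, # mV, mixed-ion funny-current reversal
  spm = 3, # uM intracellular spermine
  K_o = 5.4, K_i = 140, Na_o = 140, Na_i = 10, Ca_o = 1.8, # mM
  temperature = 310, # K
  E_CaL = 60, # mV effective L-type reversal
  Ca_rest = 5e-5, # mM diastolic Ca_i
  k_Ca = 2e-6, # mM per (A/F ms), influx coupling
  tau_Ca = 60 # ms, Ca_i relaxation
)

.PARAMS_PURK <- utils::modifyList(.PARAMS_ENDO, list(g_K1 = 0.05, g_f = 0.004))

#' Construct a single-cell cardiac model
#'
#' Builds one of the two reduced human cardiac action-potential models:
#' `"endocardial"` (ventricular endocardium, paced at 0.5 Hz in the standard
#' protocols) or `"purkinje"` (Purkinje fiber cell with funny current and
#' weak inward rectifier, paced at 0.3 Hz). Nominal intracellular spermine is
#' 3 uM, the population mean; nominal L-type conductance is 2.0 pS/pF.
#'
#' @param kind `"endocardial"` or `"purkinje"`.
#' @return An object of class `torsim_model`: a list with `kind`,
#'   `state_names`, `initial_state` (named numeric, the stimulus-free
#'   diastolic equilibrium; membrane potential is state 1) and
#'   `nominal_params` (see [model_params()] for the fields).
#' @examples
#' m <- make_model("endocardial")
#' m$nominal_params$spm
#' @export
make_model <- function(kind = c("endocardial", "purkinje")) {
  if (!is.character(kind) || length(kind) != 1 || !kind %in% .MODEL_KINDS) {
    stop("unknown model kind: must be one of ",
         paste(dQuote(.MODEL_KINDS), collapse = ", "), call. = FALSE)
  }
  init <- if (kind == "endocardial") .INIT_ENDO else .INIT_PURK
  params <- if (kind == "endocardial") .PARAMS_ENDO else .PARAMS_PURK
  structure(
    list(kind = kind, state_names = names(init), initial_state = init,
         nominal_params = params),
    class = "torsim_model"
  )
}

#' @export
print.torsim_model <- function(x, ...) {
  cat(sprintf("<torsim_model: %s, %d states, spm = %g uM, g_CaL = %g pS/pF>\n",
              x$kind, length(x$state_names),
              x$nominal_params$spm, x$nominal_params$g_CaL))
  invisible(x)
}

#' Model parameter set
#'
#' Returns the model's nominal parameters, optionally modified. Overrides are
#' validated against the parameter invariants (conductances and spermine
#' non-negative, ion concentrations positive, temperature positive).
#'
#' @param model a [make_model()] object.
#' @param ... named overrides, e.g. `spm = 5`, `g_CaL = 3`, or a single
#'   named list.
#' @return A named list of parameters.
#' @export
model_params <- function(model, ...) {
  stopifnot(inherits(model, "torsim_model"))
  ov <- list(...)
  if (length(ov) == 1 && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  p <- model$nominal_params
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(ov)] <- ov
  .validate_params(p)
  p
}

.validate_params <- function(p) {
  for (g in c("g_Na", "g_CaL", "g_Kr", "g_Ks", "g_K1", "g_bNa", "g_f")) {
    if (!is.finite(p[[g]]) || p[[g]] < 0) {
      stop(g, " must be finite and >= 0", call. = FALSE)
    }
  }
  if (!is.finite(p$spm) || p$spm < 0) stop("spm must be >= 0", call. = FALSE)
  if (!is.finite(p$temperature) || p$temperature <= 0) {
    stop("temperature must be > 0", call. = FALSE)
  }
  for (cc in c("K_o", "K_i", "Na_o", "Na_i", "Ca_o")) {
    if (!is.finite(p[[cc]]) || p[[cc]] <= 0) {
      stop(cc, " must be > 0", call. = FALSE)
    }
  }
  invisible(p)
}

#' Nernst equilibrium potential
#'
#' @param valence ionic valence z (e.g. 1 for K+, 2 for Ca2+).
#' @param conc_out,conc_in extracellular / intracellular concentration (mM),
#'   both > 0.
#' @param temperature absolute temperature (K).
#' @return Potential in mV: \eqn{(RT/zF)\,\ln([X]_o/[X]_i)}.
#' @examples
#' nernst_potential(1, 5.4, 140, 310) # E_K, about -87 mV
#' @export
nernst_potential <- function(valence, conc_out, conc_in, temperature = 310) {
  if (any(conc_out <= 0) || any(conc_in <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  1000 * .GAS_R * temperature / (valence * .FARADAY) * log(conc_out / conc_in)
}

#' Spermine-rectified inward-rectifier current I_K1
#'
#' The inward rectification of I_K1 is produced by voltage-dependent block by
#' intracellular spermine: the unblocked fraction is
#' \eqn{u = 1/(1 + [\mathrm{SPM}]/K_d(V))} with
#' \eqn{K_d(V) = K_{ref}\, e^{-(V - E_K)/k_v}}, so block strengthens with
#' depolarization and with spermine. At `spm = 0` the current is ohmic.
#'
#' @param V membrane potential (mV).
#' @param E_K potassium reversal potential (mV).
#' @param g_K1 maximal conductance (nS/pF), >= 0.
#' @param spm intracellular spermine concentration (uM), >= 0.
#' @param K_o extracellular potassium (mM); conductance scales with
#'   `sqrt(K_o/5.4)`.
#' @param K_ref,k_v spermine affinity at `V = E_K` (uM) and the e-fold
#'   voltage of the affinity decay (mV).
#' @return Current density (A/F, outward positive). Zero at `V = E_K`.
#' @export
ik1_spermine <- function(V, E_K, g_K1, spm, K_o = 5.4,
                         K_ref = .SPM_K_REF, k_v = .SPM_K_V) {
  if (any(spm < 0)) stop("spm must be >= 0", call. = FALSE)
  if (any(g_K1 < 0)) stop("g_K1 must be >= 0", call. = FALSE)
  kd <- K_ref * exp(-(V - E_K) / k_v)
  u <- 1 / (1 + spm / kd)
  g_K1 * sqrt(K_o / 5.4) * u * (V - E_K)
}

## Hodgkin-Huxley gate kinetics: steady state and time constant per gate.
## Returns list(inf = named numeric, tau = named numeric [ms]).
.gate_kinetics <- function(V, purkinje = FALSE) {
  inf <- c(
    m = 1 / (1 + exp(-(V + 38) / 7)),
    h = 1 / (1 + exp((V + 66) / 6)),
    d = 1 / (1 + exp(-(V + 16) / 6)),
    f = 1 / (1 + exp((V + 25) / 5)),
    xr = 1 / (1 + exp(-(V + 20) / 7)),
    xs = 1 / (1 + exp(-(V - 2) / 14))
  )
  tau <- c(
    m = 0.15,
    h = 1 + 10 / (1 + exp((V + 60) / 5)),
    d = 1.5 + 2.5 * exp(-((V + 25) / 20)^2),
    f = 20 + 180 * exp(-((V + 10) / 45)^2),
    xr = 80 + 400 * exp(-((V + 30) / 30)^2),
    xs = 600 + 700 * exp(-((V - 10) / 40)^2)
  )
  if (purkinje) {
    inf <- c(inf, y = 1 / (1 + exp((V + 75) / 6)))
    tau <- c(tau, y = 800)
  }
  list(inf = inf, tau = tau)
}

## core current computation on plain numerics; st is the full state vector
## in model order. Returns named numeric of current densities (A/F).
.currents_core <- function(kind, st, p) {
  V <- st[[1]]
  E_K <- nernst_potential(1, p$K_o, p$K_i, p$temperature)
  E_Na <- nernst_potential(1, p$Na_o, p$Na_i, p$temperature)
  r_inf <- 1 / (1 + exp((V + 36) / 14)) # instantaneous hERG rectification
  out <- c(
    I_Na = p$g_Na * st[["m"]]^3 * st[["h"]]^2 * (V - E_Na),
    I_CaL = p$g_CaL * .CAL_SCALE * st[["d"]] * st[["f"]] * (V - p$E_CaL),
    I_Kr = p$g_Kr * st[["xr"]] * r_inf * (V - E_K),
    I_Ks = p$g_Ks * st[["xs"]]^2 * (V - E_K),
    I_K1 = ik1_spermine(V, E_K, p$g_K1, p$spm, p$K_o),
    I_b = p$g_bNa * (V - E_Na)
  )
  if (kind == "purkinje") {
    out <- c(out, I_f = p$g_f * st[["y"]] * (V - p$E_f))
  }
  out
}

## full right-hand side on plain numerics; stim in A/F (outward positive,
## i.e. a depolarizing stimulus is negative). No validation: hot path.
.rhs_core <- function(kind, st, p, stim = 0) {
  V <- st[[1]]
  cur <- .currents_core(kind, st, p)
  gk <- .gate_kinetics(V, purkinje = kind == "purkinje")
  gates <- names(gk$inf)
  dst <- numeric(length(st))
  names(dst) <- names(st)
  dst[[1]] <- -(sum(cur) + stim)
  dst[gates] <- (gk$inf - unlist(st[gates])) / gk$tau
  dst[["Ca_i"]] <- -p$k_Ca * cur[["I_CaL"]] -
    (st[["Ca_i"]] - p$Ca_rest) / p$tau_Ca
  dst
}

#' Membrane currents at a given state
#'
#' Pure function of state and parameters; the same current values enter the
#' voltage equation of [model_rhs()].
#'
#' @param model a [make_model()] object.
#' @param state named numeric state vector (see `model$state_names`).
#' @param params parameter list from [model_params()]; defaults to nominal.
#' @param stim stimulus current (A/F, outward positive) to report as
#'   `I_stim`.
#' @return Named numeric vector of current densities (A/F, outward
#'   positive): `I_Na`, `I_CaL`, `I_Kr`, `I_Ks`, `I_K1`, `I_b`, `I_f`
#'   (Purkinje), `I_stim`.
#' @export
compute_currents <- function(model, state, params = NULL, stim = 0) {
  stopifnot(inherits(model, "torsim_model"))
  if (is.null(params)) params <- model$nominal_params
  state <- .check_state(model, state)
  c(.currents_core(model$kind, as.list(state), params), I_stim = stim)
}

#' Model right-hand side
#'
#' Time derivative of the full state under a given stimulus. Deterministic
#' and free of hidden state; gating variables follow
#' \eqn{dx/dt = (x_\infty(V) - x)/\tau_x(V)} and the voltage equation is
#' \eqn{dV/dt = -(\sum I_{ion} + I_{stim})}.
#'
#' @inheritParams compute_currents
#' @param stim stimulus current in A/F (outward positive; pacing pulses are
#'   negative).
#' @return Named numeric vector `d(state)/dt` (mV/ms, 1/ms, mM/ms).
#' @export
model_rhs <- function(model, state, params = NULL, stim = 0) {
  stopifnot(inherits(model, "torsim_model"))
  if (is.null(params)) params <- model$nominal_params
  state <- .check_state(model, state)
  if (!is.finite(stim)) stop("stim must be finite", call. = FALSE)
  .rhs_core(model$kind, as.list(state), params, stim)
}

.check_state <- function(model, state) {
  if (length(state) != length(model$state_names)) {
    stop("state must have ", length(model$state_names), " elements",
         call. = FALSE)
  }
  if (!all(is.finite(state))) stop("non-finite state", call. = FALSE)
  names(state) <- model$state_names
  state
}
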