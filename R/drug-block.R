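## Conductance-block pharmacology.
##
## A drug is represented by its per-channel IC50s (molar), a fractional
## I_K1 block (%), and a test concentration (molar). Channel block enters
## the models purely as conductance scaling by the Hill-type
## conductance-block factor 1/(1 + ([drug]/IC50)^n) with n = 1 by default;
## I_K1 block is a concentration-independent fractional scale.

.BLOCK_CHANNELS <- c(na = "g_Na", cal = "g_CaL", kr = "g_Kr", ks = "g_Ks",
                     k1 = "g_K1")

#' Drug potency/concentration profile
#'
#' @param name drug name.
#' @param ic50_na,ic50_cal,ic50_kr,ic50_ks half-maximal inhibitory
#'   concentration (molar) for I_Na, I_CaL, I_Kr, I_Ks; `NA` means the drug
#'   does not block that current at tested concentrations.
#' @param ik1_block_pct fractional I_K1 inhibition in percent, in `[0, 100]`.
#' @param concentration test concentration (molar), >= 0.
#' @param known_group optional clinical torsadogenic-risk group label
#'   (`"A1"`, `"A2"`, `"B"`, `"C"`).
#' @param hill Hill coefficient for the conductance-block factor (default 1).
#' @return Object of class `torsim_drug`.
#' @export
drug_profile <- function(name, ic50_na = NA, ic50_cal = NA, ic50_kr = NA,
                         ic50_ks = NA, ik1_block_pct = 0, concentration = 0,
                         known_group = NA_character_, hill = 1) {
  ic50 <- c(na = ic50_na, cal = ic50_cal, kr = ic50_kr, ks = ic50_ks)
  for (ch in names(ic50)) {
    v <- ic50[[ch]]
    if (!is.na(v) && (!is.numeric(v) || v <= 0)) {
      stop("ic50_", ch, " must be > 0 or NA (no block)", call. = FALSE)
    }
  }
  if (!is.numeric(ik1_block_pct) || is.na(ik1_block_pct) ||
      ik1_block_pct < 0 || ik1_block_pct > 100) {
    stop("ik1_block_pct must be in [0, 100]", call. = FALSE)
  }
  if (!is.numeric(concentration) || is.na(concentration) ||
      concentration < 0) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  if (!is.na(known_group) && !known_group %in% c("A1", "A2", "B", "C")) {
    stop("known_group must be A1, A2, B, C or NA", call. = FALSE)
  }
  structure(
    list(name = as.character(name), ic50 = ic50,
         ik1_block_pct = ik1_block_pct, concentration = concentration,
         known_group = known_group, hill = hill),
    class = "torsim_drug"
  )
}

#' @export
print.torsim_drug <- function(x, ...) {
  pd <- vapply(x$ic50, function(v) if (is.na(v)) NA_real_ else pd2(v), 0)
  cat(sprintf("<torsim_drug %s @ %.3g M | pD2 Na %.3g CaL %.3g Kr %.3g Ks %.3g | IK1 %g%% | group %s>\n",
              x$name, x$concentration, pd[["na"]], pd[["cal"]], pd[["kr"]],
              pd[["ks"]], x$ik1_block_pct, x$known_group))
  invisible(x)
}

#' Conductance under Hill-type channel block
#'
#' The conductance-block formula: in the presence of drug at concentration
#' `conc`, a channel with drug-free maximal conductance `g_max` conducts
#' \deqn{g = g_{max} / (1 + ([D]/IC_{50})^{n}).}
#'
#' @param g_max drug-free maximal conductance.
#' @param ic50 half-maximal inhibitory concentration (molar), > 0.
#' @param conc drug concentration (molar), >= 0.
#' @param hill Hill coefficient n (default 1).
#' @return Scaled conductance; equals `g_max` at `conc = 0` and
#'   `g_max/2` at `conc = ic50`.
#' @examples
#' blocked_conductance(1, 1e-6, 1e-6) # 0.5
#' blocked_conductance(1, 1e-6, 9e-6) # 0.1
#' @export
blocked_conductance <- function(g_max, ic50, conc, hill = 1) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("conc must be finite and >= 0", call. = FALSE)
  }
  g_max / (1 + (conc / ic50)^hill)
}

#' pD2 potency
#'
#' @param ic50 half-maximal inhibitory concentration in molar, > 0.
#' @return `-log10(ic50)`; pD2 = 6 corresponds to IC50 = 1 uM.
#' @export
pd2 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("ic50 must be finite and > 0", call. = FALSE)
  }
  -log10(ic50)
}

#' Directive fractional block
#'
#' An IC50-free block directive, used for protocol-level experiments such as
#' "90% block of g_Kr": scales one named conductance by `1 - pct/100`.
#'
#' @param channel one of `"g_Na"`, `"g_CaL"`, `"g_Kr"`, `"g_Ks"`, `"g_K1"`.
#' @param pct percent block in `[0, 100]`.
#' @return Object of class `torsim_block`.
#' @examples
#' directive_block("g_Kr", 90)
#' @export
directive_block <- function(channel, pct) {
  if (!channel %in% .BLOCK_CHANNELS) {
    stop("channel must be one of ", paste(.BLOCK_CHANNELS, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(pct) || is.na(pct) || pct < 0 || pct > 100) {
    stop("pct must be in [0, 100]", call. = FALSE)
  }
  structure(list(channel = channel, pct = pct), class = "torsim_block")
}

#' Per-channel block factors of a drug at its test concentration
#'
#' @param drug a [drug_profile()] or [directive_block()].
#' @return Named numeric vector of multiplicative factors in `[0, 1]` for
#'   `g_Na`, `g_CaL`, `g_Kr`, `g_Ks`, `g_K1`; 1 where no block is defined.
#' @export
block_factors <- function(drug) {
  f <- c(g_Na = 1, g_CaL = 1, g_Kr = 1, g_Ks = 1, g_K1 = 1)
  if (inherits(drug, "torsim_block")) {
    f[drug$channel] <- 1 - drug$pct / 100
    return(f)
  }
  stopifnot(inherits(drug, "torsim_drug"))
  for (ch in c("na", "cal", "kr", "ks")) {
    ic50 <- drug$ic50[[ch]]
    if (!is.na(ic50)) {
      f[.BLOCK_CHANNELS[[ch]]] <-
        blocked_conductance(1, ic50, drug$concentration, drug$hill)
    }
  }
  f[["g_K1"]] <- 1 - drug$ik1_block_pct / 100
  f
}

#' Apply a drug (or directive block) to a parameter set
#'
#' Returns a new parameter set with the channel conductances scaled by the
#' conductance-block factors at the drug's test concentration (I_K1 by its
#' fractional block). The input is untouched; apply once per simulation —
#' repeated application compounds the block.
#'
#' @param params parameter list from [model_params()].
#' @param drug a [drug_profile()], a [directive_block()], or `NULL`
#'   (no drug).
#' @return A parameter list with scaled conductances.
#' @export
apply_drug <- function(params, drug) {
  if (is.null(drug)) return(params)
  f <- block_factors(drug)
  for (g in names(f)) params[[g]] <- params[[g]] * f[[g]]
  params
}
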