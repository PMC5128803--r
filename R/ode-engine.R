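## Fast right-hand-side closures for the ODE solver.
##
## The exported model_rhs() favors validation and named access; the solver
## hot path uses the hand-inlined closures below with reversal potentials
## precomputed. A property test asserts the two paths agree to machine
## precision on random states.

.make_ode_fn <- function(kind, p) {
  E_K <- nernst_potential(1, p$K_o, p$K_i, p$temperature)
  E_Na <- nernst_potential(1, p$Na_o, p$Na_i, p$temperature)
  g_na <- p$g_Na
  g_cal <- p$g_CaL * .CAL_SCALE
  g_kr <- p$g_Kr
  g_ks <- p$g_Ks
  gk1 <- p$g_K1 * sqrt(p$K_o / 5.4)
  g_b <- p$g_bNa
  spm <- p$spm
  k_ref <- .SPM_K_REF
  k_v <- .SPM_K_V
  e_cal <- p$E_CaL
  k_ca <- p$k_Ca
  ca_rest <- p$Ca_rest
  tau_ca <- p$tau_Ca
  purk <- kind == "purkinje"
  g_f <- p$g_f
  e_f <- p$E_f

  function(t, y, stim) {
    V <- y[1]
    i_na <- g_na * y[2]^3 * y[3]^2 * (V - E_Na)
    i_cal <- g_cal * y[4] * y[5] * (V - e_cal)
    i_kr <- g_kr * y[6] * (V - E_K) / (1 + exp((V + 36) / 14))
    i_ks <- g_ks * y[7]^2 * (V - E_K)
    i_k1 <- gk1 * (V - E_K) / (1 + spm / (k_ref * exp(-(V - E_K) / k_v)))
    i_b <- g_b * (V - E_Na)
    i_tot <- i_na + i_cal + i_kr + i_ks + i_k1 + i_b
    if (purk) i_tot <- i_tot + g_f * y[9] * (V - e_f)
    dy <- c(
      -(i_tot + stim),
      (1 / (1 + exp(-(V + 38) / 7)) - y[2]) / 0.15,
      (1 / (1 + exp((V + 66) / 6)) - y[3]) /
        (1 + 10 / (1 + exp((V + 60) / 5))),
      (1 / (1 + exp(-(V + 16) / 6)) - y[4]) /
        (1.5 + 2.5 * exp(-((V + 25) / 20)^2)),
      (1 / (1 + exp((V + 25) / 5)) - y[5]) /
        (20 + 180 * exp(-((V + 10) / 45)^2)),
      (1 / (1 + exp(-(V + 20) / 7)) - y[6]) /
        (80 + 400 * exp(-((V + 30) / 30)^2)),
      (1 / (1 + exp(-(V - 2) / 14)) - y[7]) /
        (600 + 700 * exp(-((V - 10) / 40)^2)),
      -k_ca * i_cal - (y[8] - ca_rest) / tau_ca
    )
    if (purk) dy <- c(dy, (1 / (1 + exp((V + 75) / 6)) - y[9]) / 800)
    list(dy)
  }
}
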