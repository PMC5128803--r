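test_that("make_model builds valid models and rejects unknown kinds", {
  expect_error(make_model("epicardial"), "unknown model kind")
  for (kind in c("endocardial", "purkinje")) {
    m <- make_model(kind)
    expect_s3_class(m, "torsim_model")
    expect_identical(m$state_names[1], "V")
    expect_identical(m$nominal_params$spm, 3)
    expect_false(anyDuplicated(m$state_names) > 0)
    expect_length(m$initial_state, length(m$state_names))
    gates <- setdiff(m$state_names, c("V", "Ca_i"))
    expect_true(all(m$initial_state[gates] >= 0 &
                      m$initial_state[gates] <= 1))
    expect_gt(m$initial_state[["Ca_i"]], 0)
    expect_true(all(is.finite(m$initial_state)))
  }
})

test_that("nernst potential matches the closed form", {
  expect_equal(nernst_potential(1, 10, 10, 310), 0)
  # RT/F ~ 26.7 mV at 310 K: physiological E_K
  expect_equal(nernst_potential(1, 5.4, 140, 310), -87.0, tolerance = 0.002)
  # divalent ion halves the magnitude at the same ratio
  expect_equal(nernst_potential(2, 5.4, 140, 310),
               nernst_potential(1, 5.4, 140, 310) / 2)
  expect_error(nernst_potential(1, 0, 140), "concentrations")
  expect_error(nernst_potential(1, 5.4, -1), "concentrations")
})

test_that("spermine-rectified I_K1 behaves as a voltage-dependent block", {
  e_k <- nernst_potential(1, 5.4, 140, 310)
  # zero driving force
  expect_equal(ik1_spermine(e_k, e_k, 0.09, 3), 0)
  # no blocker: plain ohmic conductance
  v <- seq(-60, 40, by = 5)
  expect_equal(ik1_spermine(v, e_k, 0.09, 0), 0.09 * (v - e_k))
  # monotone non-increasing in spm at every depolarized potential
  for (vv in v) {
    i <- vapply(c(0, 1, 2, 3, 5, 8), function(s)
      ik1_spermine(vv, e_k, 0.09, s), 0)
    expect_true(all(diff(i) < 0), info = paste("V =", vv))
  }
  # raising spm 3 -> 5 uM strictly decreases outward current at -30 mV
  expect_lt(ik1_spermine(-30, e_k, 0.09, 5), ik1_spermine(-30, e_k, 0.09, 3))
  expect_gt(ik1_spermine(-30, e_k, 0.09, 3), 0)
  expect_error(ik1_spermine(-30, e_k, 0.09, -1), "spm")
})

test_that("currents scale linearly in their conductances", {
  m <- make_model("endocardial")
  st <- m$initial_state
  st[["V"]] <- -20 # depolarized state with nonzero driving forces
  st[["xr"]] <- 0.5
  st[["d"]] <- 0.2
  st[["f"]] <- 0.4
  c1 <- compute_currents(m, st)
  c2 <- compute_currents(m, st, model_params(m, g_Kr = 2 * 0.12))
  expect_equal(c2[["I_Kr"]], 2 * c1[["I_Kr"]])
  c0 <- compute_currents(m, st, model_params(m, g_CaL = 0))
  expect_identical(c0[["I_CaL"]], 0)
  # I_K1 vanishes at the K+ reversal potential
  stk <- st
  stk[["V"]] <- nernst_potential(1, 5.4, 140, 310)
  expect_equal(compute_currents(m, stk)[["I_K1"]], 0)
})

test_that("gate derivatives vanish at the steady-state curve", {
  m <- make_model("purkinje")
  v <- -35
  gk <- torsim:::.gate_kinetics(v, purkinje = TRUE)
  st <- m$initial_state
  st[["V"]] <- v
  for (g in names(gk$inf)) st[[g]] <- gk$inf[[g]]
  d <- model_rhs(m, st)
  for (g in names(gk$inf)) {
    expect_equal(d[[g]], 0, tolerance = 1e-12, info = g)
  }
})

test_that("a root-solved stimulus-free equilibrium annihilates the rhs", {
  skip_if_not_installed("pracma")
  m <- make_model("endocardial")
  f <- function(y) unname(model_rhs(m, y))
  # start near (but not at) the stored diastolic state
  y0 <- m$initial_state * (1 + 1e-3)
  sol <- pracma::broyden(f, unname(y0), maxiter = 200)
  expect_lt(max(abs(f(sol$zero))), 1e-6)
  # the root is the model's stored diastolic equilibrium
  expect_equal(sol$zero[1], m$initial_state[["V"]], tolerance = 1e-3)
  expect_lt(max(abs(unlist(model_rhs(m, m$initial_state)))), 1e-8)
})

test_that("rhs, compute_currents and the solver fast path agree", {
  set.seed(42)
  for (kind in c("endocardial", "purkinje")) {
    m <- make_model(kind)
    fast <- torsim:::.make_ode_fn(kind, m$nominal_params)
    for (i in 1:50) {
      st <- m$initial_state
      st[["V"]] <- runif(1, -90, 40)
      gates <- setdiff(m$state_names, c("V", "Ca_i"))
      st[gates] <- runif(length(gates))
      st[["Ca_i"]] <- runif(1, 1e-5, 1e-3)
      stim <- runif(1, -60, 5)
      d <- model_rhs(m, st, stim = stim)
      cur <- compute_currents(m, st, stim = stim)
      ionic <- sum(cur[setdiff(names(cur), "I_stim")])
      expect_equal(d[["V"]], -(ionic + stim), tolerance = 1e-12)
      expect_equal(unname(fast(0, unname(st), stim)[[1]]), unname(d),
                   tolerance = 1e-12)
    }
  }
})

test_that("rhs rejects malformed input", {
  m <- make_model("endocardial")
  expect_error(model_rhs(m, m$initial_state[-1]), "8 elements")
  bad <- m$initial_state
  bad[["V"]] <- NaN
  expect_error(model_rhs(m, bad), "non-finite")
  expect_error(model_rhs(m, m$initial_state, stim = Inf), "finite")
})

test_that("paced Purkinje model is periodic with a polarized resting phase", {
  m <- make_model("purkinje")
  tr <- run_paced_to_steady(m, protocol = quick_protocol(m, pre = 18,
                                                         record = 2))
  seg <- segment_beats(tr)
  expect_length(seg$windows, 2)
  m1 <- ap_metrics(seg$windows[[1]])
  m2 <- ap_metrics(seg$windows[[2]])
  expect_lt(abs(m2$apd90 - m1$apd90) / m1$apd90, 0.01)
  expect_lt(m2$resting_potential, -60)
  expect_false(m2$ead)
})
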