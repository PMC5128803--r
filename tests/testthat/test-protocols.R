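test_that("protocol validation", {
  expect_error(pacing_protocol(frequency_hz = 0), "frequency")
  expect_error(pacing_protocol(0.5, stimulus_duration_ms = 3000),
               "stimulus_duration")
  expect_error(pacing_protocol(0.5, stimulus_amplitude = -3), "amplitude")
  expect_error(spm_step_schedule(switch_time_s = 400, total_time_s = 360),
               "switch_time")
  expect_error(spm_step_schedule(spm_pre = -1), "spm")
})

test_that("integration is deterministic", {
  m <- make_model("endocardial")
  pr <- quick_protocol(m, pre = 2, record = 1)
  tr1 <- integrate_model(m, protocol = pr)
  tr2 <- integrate_model(m, protocol = pr)
  expect_identical(tr1$V_mV, tr2$V_mV)
  expect_identical(tr1$final_state, tr2$final_state)
})

test_that("zero-amplitude stimulus leaves the cell at rest", {
  m <- make_model("endocardial")
  pr <- quick_protocol(m, pre = 0, record = 3, stimulus_amplitude = 0)
  tr <- integrate_model(m, protocol = pr)
  expect_lt(max(abs(tr$V_mV - m$initial_state[["V"]])), 2)
})

test_that("a 1-beat protocol equals the first beat of a longer run", {
  m <- make_model("endocardial")
  tr1 <- integrate_model(m, protocol = quick_protocol(m, pre = 0,
                                                      record = 1))
  tr3 <- integrate_model(m, protocol = quick_protocol(m, pre = 0,
                                                      record = 3))
  n <- length(tr1$V_mV)
  expect_equal(tr1$V_mV, tr3$V_mV[seq_len(n)], tolerance = 1e-8)
})

test_that("gates stay within [0, 1] along a paced trajectory", {
  m <- make_model("endocardial")
  tr <- integrate_model(m, protocol = quick_protocol(m, pre = 3,
                                                     record = 3),
                        keep_states = TRUE)
  gates <- setdiff(m$state_names, c("V", "Ca_i"))
  g <- tr$states[, gates]
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(tr$states[, "Ca_i"] > 0))
})

test_that("halving solver tolerances barely moves APD90", {
  m <- make_model("endocardial")
  pr <- quick_protocol(m, pre = 8, record = 1)
  a1 <- ap_metrics(segment_beats(integrate_model(m, protocol = pr))$windows[[1]])
  a2 <- ap_metrics(segment_beats(
    integrate_model(m, protocol = pr, rtol = 5e-7, atol = 5e-9))$windows[[1]])
  expect_lt(abs(a1$apd90 - a2$apd90), 0.5)
})

test_that("diastolic threshold is cached and brackets excitation", {
  m <- make_model("endocardial")
  thr <- find_diastolic_threshold(m)
  expect_gt(thr, 1)
  expect_lt(thr, 120)
  expect_identical(find_diastolic_threshold(m), thr)
  # 1.5 x threshold (the protocol default) elicits an AP
  pr <- quick_protocol(m, pre = 0, record = 1)
  tr <- integrate_model(m, protocol = pr)
  expect_gt(max(tr$V_mV), 0)
  # 0.5 x threshold does not
  pr_sub <- quick_protocol(m, pre = 0, record = 1,
                           stimulus_amplitude = 0.5 * thr)
  expect_lt(max(integrate_model(m, protocol = pr_sub)$V_mV), 0)
})

test_that("a 1x1 grid equals a direct steady-pacing run", {
  m <- make_model("endocardial")
  pr <- quick_protocol(m, pre = 6, record = 2)
  g <- run_variability_grid(m, directive_block("g_Kr", 50),
                            spm_values = 3, gcal_values = 2,
                            protocol = pr)
  expect_identical(nrow(g$cells), 1L)
  tr <- run_paced_to_steady(m, drug = directive_block("g_Kr", 50),
                            protocol = pr)
  seg <- segment_beats(tr)
  direct <- ap_metrics(seg$windows[[length(seg$windows)]])
  expect_equal(g$cells$apd90_ms, direct$apd90)
  expect_error(run_variability_grid(m, spm_values = numeric(0)),
               "non-empty")
})

test_that("grid results are order-independent under axis permutation", {
  m <- make_model("endocardial")
  pr <- quick_protocol(m, pre = 5, record = 2)
  g1 <- run_variability_grid(m, spm_values = c(3, 5), gcal_values = c(2, 3),
                             protocol = pr)
  g2 <- run_variability_grid(m, spm_values = c(5, 3), gcal_values = c(3, 2),
                             protocol = pr)
  key <- function(g) g$cells[order(g$cells$spm, g$cells$g_CaL), ]
  k1 <- key(g1)
  k2 <- key(g2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
  expect_identical(g1$ead_count, g2$ead_count)
})

test_that("population scan enumerates 3^n combinations with exact risk", {
  m <- make_model("endocardial")
  specs <- list(population_spec("spm", 3, 0.5),
                population_spec("g_CaL", 2, 0.25))
  # stub predicate: arrhythmia iff spermine sits at its high extreme
  ps <- run_population_scan(m, parameter_specs = specs,
                            outcome_fn = function(p) p$spm >= 4.5)
  expect_identical(nrow(ps$combinations), 9L)
  expect_identical(ps$n_prime, 1L)
  expect_equal(ps$risk, 0.002)
  # no combination arrhythmic
  ps0 <- run_population_scan(m, parameter_specs = specs,
                             outcome_fn = function(p) FALSE)
  expect_equal(ps0$risk, 0)
  expect_true(is.na(ps0$n_prime))
  # brute-force oracle for n' on a random predicate over three parameters
  specs3 <- list(population_spec("spm", 3, 0.5),
                 population_spec("g_CaL", 2, 0.25),
                 population_spec("g_Kr", 0.12, 0.01))
  set.seed(3)
  arr_set <- sample(27, 6) # arbitrary arrhythmic combinations
  counter <- new.env()
  counter$i <- 0
  pred <- function(p) {
    counter$i <- counter$i + 1
    counter$i %in% arr_set
  }
  ps3 <- run_population_scan(m, parameter_specs = specs3,
                             outcome_fn = pred)
  expect_identical(nrow(ps3$combinations), 27L)
  # oracle: enumerate levels the same way and count extremes directly
  lv <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  oracle_np <- min(rowSums(abs(lv[arr_set, ])))
  expect_identical(ps3$n_prime, as.integer(oracle_np))
  expect_equal(ps3$risk, 0.002^oracle_np)
})

test_that("parameter floors clip extreme levels and are flagged", {
  m <- make_model("endocardial")
  ps <- run_population_scan(
    m, parameter_specs = list(population_spec("spm", 1, 0.5, floor = 0)),
    outcome_fn = function(p) FALSE)
  expect_true(ps$clipped)
  expect_equal(min(ps$combinations$spm), 0)
})

test_that("spm step protocol switches spermine and reports no events when benign", {
  m <- make_model("endocardial")
  sched <- spm_step_schedule(spm_pre = 3, spm_post = 5,
                             switch_time_s = 20, total_time_s = 40)
  s <- run_spm_step(m, schedule = sched)
  expect_false(s$arrhythmia)
  expect_true(is.na(s$latency_s))
  expect_equal(s$switch_time_ms, 20000)
  expect_length(s$trace$stimulus_times, 20)
})
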