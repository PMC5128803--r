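test_that("segmentation yields one window per stimulus", {
  t <- seq(0, 6000, by = 0.5)
  v <- rep(-80, length(t))
  for (s in c(0, 2000, 4000)) {
    v[t > s & t <= s + 300] <- 20
  }
  tr <- synth_trace(t, v, stimulus_times = c(0, 2000, 4000))
  seg <- segment_beats(tr)
  expect_length(seg$windows, 3)
  expect_length(seg$spontaneous_times, 0)
})

test_that("spontaneous (non-stimulus-aligned) upstrokes are reported", {
  t <- seq(0, 4000, by = 0.5)
  v <- rep(-80, length(t))
  v[t > 0 & t <= 300] <- 20 # paced beat at the stimulus
  v[t > 1500 & t <= 1800] <- 15 # injected ectopic upstroke at 1500 ms
  tr <- synth_trace(t, v, stimulus_times = 0)
  seg <- segment_beats(tr)
  expect_length(seg$spontaneous_times, 1)
  expect_equal(seg$spontaneous_times, 1500, tolerance = 1e-6)
  # quiescent trace: no events
  tr0 <- synth_trace(t, rep(-80, length(t)), stimulus_times = numeric(0))
  expect_length(segment_beats(tr0)$spontaneous_times, 0)
})

test_that("APD of canonical synthetic shapes matches the analytic value", {
  # rectangular 200 ms pulse: every APD level reads 200 ms
  w <- square_ap_window(dur_ms = 200)
  expect_equal(as.numeric(apd(w, 90)), 200, tolerance = 1)
  expect_equal(as.numeric(apd(w, 30)), 200, tolerance = 1)
  # linear repolarization from +20 to -80 over 300 ms: APD90 at 90% of the
  # ramp, APD30 at 30%
  wl <- linear_repol_window(rest = -80, peak = 20, ramp_ms = 300)
  expect_equal(as.numeric(apd(wl, 90)), 270, tolerance = 1)
  expect_equal(as.numeric(apd(wl, 30)), 90, tolerance = 1)
  expect_equal(as.numeric(apd(wl, 50)), 150, tolerance = 1)
  expect_error(apd(wl, 0), "level")
  expect_error(apd(wl, 100), "level")
})

test_that("APD levels are ordered and triangulation is non-negative", {
  set.seed(7)
  for (i in 1:25) {
    w <- monotone_ap_window()
    m <- ap_metrics(w)
    expect_true(m$apd30 <= m$apd40 && m$apd40 <= m$apd50 &&
                  m$apd50 <= m$apd90)
    expect_gte(m$triangulation, 0)
  }
})

test_that("APD is invariant to time shift and voltage offset", {
  wl <- linear_repol_window()
  a0 <- as.numeric(apd(wl, 90))
  shifted <- synth_window(wl$time_ms + 137, wl$V_mV)
  expect_equal(as.numeric(apd(shifted, 90)), a0)
  offset <- synth_window(wl$time_ms, wl$V_mV + 12.5)
  expect_equal(as.numeric(apd(offset, 90)), a0)
})

test_that("triangulation scales with a uniform time rescale", {
  wl <- linear_repol_window()
  m1 <- ap_metrics(wl)
  scaled <- synth_window(wl$time_ms * 1.7, wl$V_mV)
  m2 <- ap_metrics(scaled)
  expect_equal(m2$triangulation, 1.7 * m1$triangulation, tolerance = 0.02)
})

test_that("incomplete repolarization is flagged with the window length", {
  t <- seq(0, 500, by = 0.5)
  v <- ifelse(t > 1, 20 - 30 * (t - 1) / 500, -80) # never reaches -70
  w <- synth_window(t, v)
  a <- apd(w, 90)
  expect_true(attr(a, "incomplete"))
  expect_equal(as.numeric(a), 500 - 1, tolerance = 1)
})

test_that("EAD detector flags plateau humps above threshold only", {
  w10 <- ead_ap_window(hump_mv = 10)
  e <- detect_ead(w10)
  expect_true(e$ead)
  # onset at the pre-bump local minimum (about 200 ms)
  expect_true(all(abs(e$times - 200) < 10))
  expect_false(detect_ead(ead_ap_window(hump_mv = 1))$ead)
  expect_false(detect_ead(linear_repol_window())$ead)
  m <- ap_metrics(w10)
  expect_true(m$ead)
  expect_length(m$ead_times, 1)
})

test_that("EAD detector has no false positives on monotone fixtures", {
  set.seed(11)
  hits <- 0L
  for (i in 1:1000) {
    if (detect_ead(monotone_ap_window())$ead) hits <- hits + 1L
  }
  expect_identical(hits, 0L)
})

test_that("paired drug-vs-control comparison", {
  w300 <- linear_repol_window(ramp_ms = 300 / 0.9) # APD90 = 300
  w450 <- linear_repol_window(ramp_ms = 450 / 0.9)
  w250 <- linear_repol_window(ramp_ms = 250 / 0.9)
  m300 <- ap_metrics(w300)
  m450 <- ap_metrics(w450)
  m250 <- ap_metrics(w250)
  expect_equal(compare_effects(m300, m450)$delta_apd90_pct, 50,
               tolerance = 0.01)
  expect_equal(compare_effects(m300, m250)$delta_apd90_pct, -16.7,
               tolerance = 0.01)
  same <- compare_effects(m300, m300)
  expect_equal(same$delta_apd90_pct, 0)
  expect_equal(same$delta_triangulation_ms, 0)
  expect_false(same$triangulation_present)
  expect_false(same$ead_emerged)
  bad <- m300
  bad$apd90 <- 0
  expect_error(compare_effects(bad, m450), "APD90")
})
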