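# Hysteresis event detector, evoked-sweep QC, and the evoked window.

p <- analysis_params()

test_that("threshold/merge/duration rules match the stated examples", {
  # +8 mV square bout of 200 ms -> one event spanning the pulse
  ev <- detect_spontaneous_events(square_sweep(list(c(1000, 1200))), -65, p,
                                  prefilter = FALSE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_ms, 1000, tolerance = 0.2)
  expect_equal(ev$offset_ms, 1200, tolerance = 0.2)

  # 80 ms pulse: shorter than the 100 ms minimum
  expect_equal(nrow(detect_spontaneous_events(
    square_sweep(list(c(1000, 1080))), -65, p, prefilter = FALSE)), 0)

  # two 60 ms pulses, 20 ms apart: merged into one 140 ms event
  ev2 <- detect_spontaneous_events(
    square_sweep(list(c(1000, 1060), c(1080, 1140))), -65, p,
    prefilter = FALSE)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration_ms, 140, tolerance = 0.2)

  # the same pulses 30 ms apart stay separate and are both too short
  expect_equal(nrow(detect_spontaneous_events(
    square_sweep(list(c(1000, 1060), c(1090, 1150))), -65, p,
    prefilter = FALSE)), 0)

  # an event whose baseline window would precede the sweep start is dropped
  expect_equal(nrow(detect_spontaneous_events(
    square_sweep(list(c(50, 300))), -65, p, prefilter = FALSE)), 0)
})

test_that("detector matches the brute-force run/gap oracle on random sequences", {
  set.seed(101)
  for (i in 1:200) {
    rb <- random_binary_sweep(n = 400, rate = 1000,
                              p_flip = runif(1, 0.01, 0.2))
    got <- detect_spontaneous_events(rb$sweep, -65, p, prefilter = FALSE)
    want <- oracle_detect(rb$above, 1000)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$onset_ms, want$onset, tolerance = 1e-9)
      expect_equal(got$offset_ms, want$offset, tolerance = 1e-9)
    }
  }
})

test_that("detected events are disjoint, sorted, and monotone in the threshold", {
  set.seed(202)
  for (i in 1:30) {
    rb <- random_binary_sweep(n = 600, rate = 1000, p_flip = 0.08)
    ev <- detect_spontaneous_events(rb$sweep, -65, p, prefilter = FALSE)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$onset_ms) > 0))
      expect_true(all(ev$onset_ms[-1] >= ev$offset_ms[-nrow(ev)]))
    }
    # raising the threshold (here: same trace against a higher resting
    # estimate) never yields more events
    ev_hi <- detect_spontaneous_events(rb$sweep, -65 + 2, p,
                                       prefilter = FALSE)
    expect_lte(nrow(ev_hi), nrow(ev))
  }
})

test_that("evoked QC excludes contaminated baselines but tolerates spikes", {
  rate <- 10000
  n <- 2.2 * rate
  flat <- rep(-65, n)
  stim <- 1000
  resp <- flat
  resp[(1.1 * rate):(1.3 * rate)] <- -55
  keep <- voltage_sweep(resp, stim_onset = stim, kind = "evoked_cs")
  expect_true(qc_evoked_sweep(keep, p))

  # a 150 ms spontaneous bout inside the baseline
  bad <- resp
  bad[(0.4 * rate):(0.55 * rate)] <- -57
  expect_false(qc_evoked_sweep(
    voltage_sweep(bad, stim_onset = stim, kind = "evoked_cs"), p))

  # a single 2 ms spike transient is removed by the median filter
  spiky <- resp
  spiky[(0.5 * rate):(0.5 * rate + 19)] <- -10
  expect_true(qc_evoked_sweep(
    voltage_sweep(spiky, stim_onset = stim, kind = "evoked_cs"), p))

  expect_error(qc_evoked_sweep(voltage_sweep(flat), p), "stimulus")
})

test_that("evoked_window cuts, filters and baseline-subtracts the 1 s segment", {
  rate <- 10000
  x <- rep(-64.8, 2.2 * rate)
  sw <- voltage_sweep(x, stim_onset = 1000, kind = "evoked_cs")
  w <- evoked_window(sw, p)
  expect_length(w, 10000)
  expect_equal(as.numeric(w), rep(0, 10000))  # constant baseline -> ~0

  short <- voltage_sweep(rep(-65, 2 * rate), stim_onset = 1000,
                         kind = "evoked_cs")
  expect_error(evoked_window(short, analysis_params(window_ms = 1100)),
               "exceeds")
})
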