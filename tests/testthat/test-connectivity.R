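# AP detection, EPSP amplitudes, connection calls, direction summaries.

p <- analysis_params()

# Probe whose postsynaptic trials carry a noiseless EPSP of `amp` mV and a
# per-trial whole-trace offset with the requested SD (epsp_amplitude is
# offset-invariant within a trial, so the offsets set baseline_sd exactly).
fixed_probe <- function(amp, offsets, rate = 10000) {
  n <- 0.6 * rate
  ap_idx <- 2000
  pre <- rep(-65, n); pre[ap_idx + (-10:10)] <- 10
  trials <- purrr::map(offsets, function(o) {
    post <- rep(-65 + o, n)
    i <- ap_idx + round(4 * rate / 1000) + (-5:5)
    post[i] <- post[i] + amp
    list(pre = pre, post = post)
  })
  connectivity_probe("fx", "a", "b", "chrim_to_none", sample_rate = rate,
                     trials = trials)
}

test_that("presynaptic APs are detected at their peaks", {
  x <- rep(-65, 5000)
  x[1000 + (-10:10)] <- -65 + 75 * (1 - abs(-10:10) / 11)
  x[3000 + (-10:10)] <- -65 + 75 * (1 - abs(-10:10) / 11)
  aps <- detect_ap_times(x, 10000, 0)
  expect_length(aps, 2)
  expect_equal(aps, c(99.9, 299.9), tolerance = 0.2)
  expect_length(detect_ap_times(rep(-65, 100), 10000), 0)
})

test_that("epsp_amplitude is peak minus baseline mean, offset-invariant", {
  rate <- 10000
  flat <- rep(-65, 6000)
  expect_equal(epsp_amplitude(flat, 200, rate, p)$amplitude, 0)

  pr <- fixed_probe(0.8, offsets = 0)
  a <- epsp_amplitude(pr$trials[[1]]$post, 200, rate, p)
  expect_equal(a$amplitude, 0.8)
  # constant offset of the whole trace changes nothing
  a2 <- epsp_amplitude(pr$trials[[1]]$post + 3.3, 200, rate, p)
  expect_equal(a2$amplitude, 0.8)
  # out-of-bounds windows drop the trial
  expect_null(epsp_amplitude(flat, 10, rate, p))
  expect_null(epsp_amplitude(flat, 599, rate, p))

  # averaging oracle: 0.5 mV EPSP with 0.1 mV white noise over 20 trials
  set.seed(55)
  amps <- replicate(20, {
    post <- rep(-65, 6000) + rnorm(6000, sd = 0.1)
    i <- 2000 + 40 + (-5:5)
    post[i] <- post[i] + 0.5
    epsp_amplitude(post, 200, rate, p)$amplitude
  })
  expect_gt(mean(amps), 0.4); expect_lt(mean(amps), 0.7)
})

test_that("connection calls use the inclusive 3x baseline-SD rule", {
  # offsets with SD exactly 0.1 mV
  offs <- c(-0.1, 0, 0.1)   # sample SD exactly 0.1
  expect_equal(sd(offs), 0.1)
  expect_true(call_connection(fixed_probe(0.50, offs), p)$connected)
  expect_true(call_connection(fixed_probe(0.30, offs), p)$connected)  # boundary
  cl <- call_connection(fixed_probe(0.29, offs), p)
  expect_false(cl$connected)
  expect_true(cl$low_confidence)  # 3 trials < conn_min_trials
  expect_equal(cl$mean_epsp_mV, 0.29)
  expect_equal(cl$baseline_sd_mV, 0.1)
})

test_that("direction_summary aggregates strength and probability per direction", {
  calls <- dplyr::bind_rows(
    purrr::map(1:3, ~ call_connection(
      fixed_probe(1.0, c(-0.01, 0, 0.01)), p)),
    purrr::map(1:3, ~ {
      cl <- call_connection(fixed_probe(0.5, c(-0.01, 0, 0.01)), p)
      cl$direction <- "none_to_chrim"
      cl
    }))
  s <- direction_summary(calls)
  expect_equal(s$by_direction$mean_epsp_mV,
               c(1.0, 0.5), tolerance = 1e-9)
  expect_equal(s$by_direction$connection_probability, c(1, 1))

  # probability is a plain count ratio
  calls2 <- calls
  calls2$connected[4:5] <- FALSE
  s2 <- direction_summary(calls2)
  expect_equal(
    s2$by_direction$connection_probability[
      s2$by_direction$direction == "none_to_chrim"], 1 / 3)

  # synthetic world: forward connections measurably stronger than reverse
  cfg <- tiny_cfg(seed = 4, conn_p_forward = 1, conn_p_reverse = 1,
                  n_probe_pairs = 5, spont_duration_s = 0, n_neurons = 1)
  d <- simulate_dataset(cfg)
  s3 <- direction_summary(connectivity_calls(d))
  bd <- s3$by_direction
  expect_gt(bd$mean_epsp_mV[bd$direction == "chrim_to_none"],
            bd$mean_epsp_mV[bd$direction == "none_to_chrim"])
})
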