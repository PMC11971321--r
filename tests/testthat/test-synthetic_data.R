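# Generator: determinism, noiseless construction, and ground-truth plumbing.

test_that("equal seeds give identical datasets, different seeds differ", {
  cfg <- tiny_cfg(seed = 11, spont_duration_s = 20)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(tiny_cfg(seed = 12, spont_duration_s = 20))
  expect_false(identical(d1$neurons[[1]]$sweeps[[1]]$samples,
                         d3$neurons[[1]]$sweeps[[1]]$samples))
  # and generate_neuron alone is reproducible
  expect_identical(generate_neuron(cfg, "late"), generate_neuron(cfg, "late"))
})

test_that("noiseless construction places envelope features exactly", {
  cfg <- tiny_cfg()
  n <- generate_neuron(cfg, "late", noise = FALSE, spikes = FALSE,
                       with_spont = FALSE)
  w <- evoked_window(n$sweeps[[1]], analysis_params())
  # post-stimulus maximum at the late component's peak time (10 ms
  # smoothing can move the argmax by well under a millisecond)
  expect_lt(abs(peak_time(w) - cfg$late_peak_ms), 1)

  ne <- generate_neuron(cfg, "early", noise = FALSE, spikes = FALSE,
                        with_spont = FALSE)
  we <- evoked_window(ne$sweeps[[1]], analysis_params())
  expect_lt(abs(peak_time(we) - cfg$early_peak_ms), 1)

  expect_error(generate_neuron(cfg, "sideways"), "condition")
})

test_that("a zero-amplitude envelope leaves only noise and spikes", {
  cfg <- tiny_cfg(envelope_amp_mV = 0, bump_amp_mV = 0,
                  spont_duration_s = 20)
  n <- generate_neuron(cfg, "late", spikes = FALSE)
  for (s in n$sweeps) {
    expect_lt(max(s$samples), cfg$resting_mV + 5 * cfg$noise_sd_mV)
  }
})

test_that("prediction-error assignment follows the deterministic rounding rule", {
  # 25% of 28 Late opsin-negative neurons -> exactly 7, lowest indices
  cfg <- generator_config(seed = 5, n_neurons = 28, spont_duration_s = 0,
                          n_pairs = 0, n_probe_pairs = 0,
                          n_evoked_sweeps = 1, n_csus_sweeps = 1)
  d <- simulate_dataset(cfg)
  pe <- unlist(d$provenance$pe_neurons)
  expect_length(pe, 7)
  expect_identical(pe, sprintf("late_none_%02d", 1:7))
  nt <- neuron_table(d)
  expect_identical(sort(nt$neuron_id[nt$is_pe %in% TRUE]), sort(pe))
})

test_that("connectivity probes honor the connection probabilities", {
  cfg <- tiny_cfg(conn_p_forward = 1, conn_p_reverse = 0, n_probe_pairs = 4,
                  spont_duration_s = 0, n_neurons = 1)
  d <- simulate_dataset(cfg)
  fwd <- Filter(function(p) p$direction == "chrim_to_none", d$probes)
  rev <- Filter(function(p) p$direction == "none_to_chrim", d$probes)
  expect_true(all(vapply(fwd, function(p) p$truth$connected, logical(1))))
  expect_false(any(vapply(rev, function(p) p$truth$connected, logical(1))))
  # a connected forward probe really contains an EPSP, reverse probes do not
  p_noise <- tiny_cfg(conn_p_forward = 1, conn_p_reverse = 0,
                      n_probe_pairs = 1, spont_duration_s = 0, n_neurons = 1,
                      probe_noise_sd_mV = 0)
  d0 <- simulate_dataset(p_noise)
  fwd0 <- Filter(function(p) p$direction == "chrim_to_none", d0$probes)[[1]]
  rev0 <- Filter(function(p) p$direction == "none_to_chrim", d0$probes)[[1]]
  expect_gt(max(fwd0$trials[[1]]$post), -65 + 0.5)
  expect_equal(max(rev0$trials[[1]]$post), -65)
})

test_that("noiseless pairs reproduce the injected lag structure", {
  cfg <- tiny_cfg(spont_duration_s = 60)
  pr0 <- generate_pair(cfg, "untrained", noise = FALSE, spikes = FALSE)
  sa <- pr0$chrim$sweeps[[1]]$samples
  sb <- pr0$chr2$sweeps[[1]]$samples
  expect_identical(sa, sb)  # zero lag, shared bouts, no noise

  pr <- generate_pair(cfg, "late", noise = FALSE, spikes = FALSE)
  seg <- combined_event_segments(pr$chrim, pr$chr2, analysis_params())
  expect_gt(length(seg$segments), 0)
  xc <- xcorr_lag(seg, analysis_params())
  expect_equal(xc$peak_lag_ms, cfg$pair_lag_ms)
  r2 <- pairwise_r2(seg$segments)
  expect_lt(r2$mean_r2, 1)       # the lag decorrelates zero-lag voltage
  expect_gt(xc$peak_r2, 0.99)    # but alignment at the lag restores it
})
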