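# Evoked alignment, mean activity, and the replay correlation matrices.

p <- analysis_params()

test_that("align_evoked shifts the first 5 mV crossing to t = 0", {
  x <- c(rep(0, 1200), rep(8, 800))
  attr(x, "sample_rate") <- 1000
  al <- align_evoked(x, 5)
  expect_equal(al[1], 8)               # crossing at 120 ms now leads
  expect_length(al, length(x))
  expect_equal(al[1500], 8)            # tail padded with the final value

  already <- c(rep(8, 100), rep(0, 100))
  expect_equal(align_evoked(already, 5), already)
  expect_null(align_evoked(rep(2, 500), 5))  # sub-threshold: flagged
})

test_that("mean_activity averages usable traces pointwise", {
  cfg <- tiny_cfg(spont_duration_s = 0)
  n <- generate_neuron(cfg, "early", noise = FALSE, spikes = FALSE)
  m <- mean_activity(n, "evoked", p)
  # identical noiseless traces: the mean equals any single aligned trace
  one <- align_evoked(evoked_window(n$sweeps[[1]], p), 5)
  f <- p$spont_downsample
  one_ds <- colMeans(matrix(one[seq_len(1000 * f)], nrow = f))
  expect_equal(as.numeric(m), as.numeric(one_ds))

  # generator ground truth: mean of noisy spontaneous windows tracks the
  # envelope at probe times (within 3 SEM of the per-window spread)
  cfg2 <- tiny_cfg(seed = 8, spont_duration_s = 120)
  ns <- generate_neuron(cfg2, "early", spikes = FALSE)
  traces <- neuron_spont_windows(ns, p)
  expect_gt(length(traces), 3)
  m2 <- mean_activity(ns, "spontaneous", p)
  len <- length(m2)
  mat <- vapply(traces, function(x) x[seq_len(len)], numeric(len))
  # windows are locked at the detected onset, i.e. the envelope's 5 mV
  # rise crossing; compare against the envelope shifted accordingly
  env <- condition_envelope(seq(0, 2000), "early", cfg2)
  off <- min(which(env > p$spont_threshold_mV)) - 1
  for (t_ms in seq(100, 900, by = 100)) {
    i <- t_ms  # 1 kHz after down-sampling
    expect_lt(abs(m2[i] - mean(mat[i, ])), 1e-9)
    # and the mean tracks the generator envelope within 3 SEM + jitter
    sem_i <- sd(mat[i, ]) / sqrt(ncol(mat))
    expect_lt(abs(m2[i] - env[i + off]), 3 * sem_i + 1.5)
  }
})

test_that("replay matrix entries equal brute-force Pearson r and intra drops self-pairs", {
  cfg <- tiny_cfg(seed = 21, n_neurons = 3, spont_duration_s = 90,
                  n_pairs = 0, n_probe_pairs = 0)
  d <- simulate_dataset(cfg)
  rp <- replay_matrices(d, c("early", "late"), p)

  # intra matrices: n x n with the diagonal masked
  m_ee <- rp$matrices$early_x_early
  k <- sum(rownames(m_ee) %in% colnames(m_ee))
  expect_equal(sum(!is.na(m_ee)), length(m_ee) - k)

  # oracle: recompute a handful of entries from the mean traces directly
  ids_r <- rownames(m_ee); ids_c <- colnames(m_ee)
  for (i in seq_along(ids_r)) {
    for (j in seq_along(ids_c)) {
      if (identical(ids_r[i], ids_c[j])) next
      ev <- mean_activity(d$neurons[[ids_r[i]]], "evoked", p)
      sp <- mean_activity(d$neurons[[ids_c[j]]], "spontaneous", p)
      len <- min(length(ev), length(sp))
      expect_equal(m_ee[i, j], cor(ev[seq_len(len)], sp[seq_len(len)]))
    }
  }
  expect_true(all(abs(rp$values$r) <= 1))
})

test_that("correlation is invariant to affine rescaling of either trace", {
  set.seed(4)
  x <- moving_average(rnorm(500), 10, 1000)
  y <- moving_average(rnorm(500), 10, 1000)
  expect_equal(cor(x, y), cor(3 * x + 7, y))
  expect_equal(cor(x, y), cor(x, -2 * y + 1) * -1)
})

test_that("identical mean traces give off-diagonal r of 1", {
  # two neurons with the same noiseless envelope
  cfg <- tiny_cfg(spont_duration_s = 60)
  n1 <- replaytrace:::gen_neuron_impl(cfg, "a", "early", "none",
                                      noise = FALSE, spikes = FALSE)
  n2 <- replaytrace:::gen_neuron_impl(cfg, "b", "early", "none",
                                      noise = FALSE, spikes = FALSE)
  ev <- mean_activity(n1, "evoked", p)
  sp <- mean_activity(n2, "spontaneous", p)
  len <- min(length(ev), length(sp))
  expect_gt(cor(ev[seq_len(len)], sp[seq_len(len)]), 0.95)
})
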