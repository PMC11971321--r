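# Combined-event segmentation, pairwise r-squared, cross-correlation lag.

p <- analysis_params()

mk_pair <- function(xa, xb, rate = 10000) {
  list(a = neuron_record("pA_chrim", condition = "late", opsin = "chrim",
                         sweeps = list(voltage_sweep(xa, sample_rate = rate)),
                         pair_id = "p"),
       b = neuron_record("pB_chr2", condition = "late", opsin = "chr2",
                         sweeps = list(voltage_sweep(xb, sample_rate = rate)),
                         pair_id = "p"))
}

test_that("combined event index unions and merges the two neurons' events", {
  rate <- 10000
  flat <- rep(-65, 12 * rate)
  # both neurons see the same 400 ms event at 5000 ms -> one segment
  both <- flat; both[(5 * rate):(5.4 * rate)] <- -57
  pr <- mk_pair(both, both)
  seg <- combined_event_segments(pr$a, pr$b, p)
  expect_length(seg$segments, 1)
  expect_equal(seg$segments[[1]]$onset_ms, 5000, tolerance = 5)
  expect_length(seg$segments[[1]]$x,
                round(p$paired_segment_ms / 1000 * seg$rate))

  # events at 5000 ms (A only) and 9000 ms (B only) -> two segments
  a2 <- flat; a2[(5 * rate):(5.4 * rate)] <- -57
  b2 <- flat; b2[(9 * rate):(9.4 * rate)] <- -57
  pr2 <- mk_pair(a2, b2)
  expect_length(combined_event_segments(pr2$a, pr2$b, p)$segments, 2)

  # overlapping events (A at 5000, B at 5030, both 400 ms) merge,
  # anchored at the earliest onset
  a3 <- flat; a3[(5 * rate):(5.4 * rate)] <- -57
  b3 <- flat; b3[(5.03 * rate):(5.43 * rate)] <- -57
  pr3 <- mk_pair(a3, b3)
  seg3 <- combined_event_segments(pr3$a, pr3$b, p)
  expect_length(seg3$segments, 1)
  expect_equal(seg3$segments[[1]]$onset_ms, 5000, tolerance = 5)
  expect_equal(seg3$segments[[1]]$offset_ms, 5430, tolerance = 10)

  # a segment that would run past the record end is dropped
  tail_ev <- flat; tail_ev[(11.7 * rate):(11.95 * rate)] <- -57
  pr4 <- mk_pair(tail_ev, tail_ev)
  expect_length(combined_event_segments(pr4$a, pr4$b, p)$segments, 0)
})

test_that("pairwise r-squared behaves on identical, lagged and independent traces", {
  rate <- 10000
  flat <- rep(-65, 12 * rate)
  env <- function(at_s, lag_ms = 0) {
    x <- flat
    t <- seq(0, 999.9, by = 0.1)
    bump <- 10 * sin(pi * t / 1000)^2 * (1 + 0.5 * sin(2 * pi * t / 180))
    i <- round((at_s * 1000 + lag_ms) / 0.1) + 1:10000
    x[i] <- x[i] + bump
    x
  }
  pr <- mk_pair(env(5), env(5))
  seg <- combined_event_segments(pr$a, pr$b, p)
  expect_equal(pairwise_r2(seg$segments)$mean_r2, 1, tolerance = 1e-9)

  # independent white noise at the paired rate: near-zero r-squared
  set.seed(12)
  n <- 220
  segs <- purrr::map(1:50, ~ list(x = rnorm(n), y = rnorm(n),
                                  onset_ms = 0, offset_ms = 1000))
  expect_lt(pairwise_r2(segs)$mean_r2, 0.05)

  # a 30 ms lag decorrelates the zero-lag comparison below 1
  pr_lag <- mk_pair(env(5), env(5, 30))
  seg_lag <- combined_event_segments(pr_lag$a, pr_lag$b, p)
  expect_lt(pairwise_r2(seg_lag$segments)$mean_r2, 1 - 1e-4)
  xc <- xcorr_lag(seg_lag, p)
  expect_equal(xc$peak_lag_ms, 30)
  expect_gt(xc$peak_r2, 0.99)

  # identical traces peak at zero lag
  expect_equal(xcorr_lag(seg, p)$peak_lag_ms, 0)
})

test_that("cross-correlation is lag-antisymmetric and bounded by 1", {
  set.seed(33)
  x <- as.numeric(stats::filter(rnorm(300), 0.9, "recursive"))
  y <- as.numeric(stats::filter(rnorm(300), 0.9, "recursive"))
  for (L in c(-40, -7, 0, 7, 40)) {
    ab <- replaytrace:::cor_at_lag(x, y, L)
    ba <- replaytrace:::cor_at_lag(y, x, -L)
    expect_equal(ab, ba)
    expect_lte(abs(ab), 1)
  }
})

test_that("paired_dynamics reports one row per pair with the sign convention", {
  cfg <- tiny_cfg(seed = 14, spont_duration_s = 90, n_pairs = 1,
                  n_probe_pairs = 0, n_neurons = 1)
  d <- simulate_dataset(cfg)
  pd <- paired_dynamics(d)
  expect_setequal(pd$condition, c("late", "untrained"))
  late <- pd[pd$condition == "late", ]
  # positive lag: ChR2-labeled follows Chrim-labeled
  expect_gt(late$peak_lag_ms, 0)
  expect_true(all(abs(pd$xcorr[[1]]$r) <= 1 + 1e-12))
})
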