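# Peak time, slope events, center of gravity, CDFs, and their invariances.

p <- analysis_params()
rate <- 1000
as_trace <- function(x, r = rate) { attr(x, "sample_rate") <- r; x }

test_that("peak_time takes the global maximum with earliest-tie rule", {
  tri <- as_trace(c(seq(0, 1, length.out = 481), seq(1, 0, length.out = 520)))
  expect_equal(peak_time(tri), 480)
  expect_equal(peak_time(as_trace(rep(1, 1000))), 0)
})

test_that("slope_event_times matches a brute-force slope scan", {
  expect_length(slope_event_times(as_trace(rep(0, 1000)), p), 0)

  # one linear ramp in a flat trace -> a single event at the ramp onset
  ramp <- rep(0, 1000)
  ramp[301:400] <- seq(0, 5, length.out = 100)
  ramp[401:1000] <- 5
  tr <- as_trace(ramp)
  ev <- slope_event_times(tr, p)
  expect_length(ev, 1)
  expect_equal(ev, oracle_slope_events(ramp, rate))
  expect_lt(abs(ev[1] - 300), p$slope_window_ms + 1)

  # two well-separated ramps -> two events, equal to the oracle
  two <- rep(0, 1000)
  two[201:260] <- seq(0, 4, length.out = 60)
  two[261:600] <- 4
  two[601:660] <- 4 + seq(0, 4, length.out = 60)
  two[661:1000] <- 8
  ev2 <- slope_event_times(as_trace(two), p)
  expect_length(ev2, 2)
  expect_equal(ev2, oracle_slope_events(two, rate))

  # random smooth traces agree with the oracle
  set.seed(9)
  for (i in 1:50) {
    x <- moving_average(cumsum(rnorm(600)), 10, rate)
    expect_equal(slope_event_times(as_trace(x, rate), p),
                 oracle_slope_events(x, rate))
  }
})

test_that("median_event_time pools events across traces", {
  mk <- function(onsets) {
    x <- rep(0, 1000)
    for (o in onsets) x[o:(o + 30)] <- x[o:(o + 30)] + seq(0, 6, length.out = 31)
    for (o in onsets) x[(o + 30):1000] <- x[o + 30]
    as_trace(x)
  }
  # single trace carrying events near 100/200/300 -> median near 200
  t1 <- mk(c(100, 200, 300))
  expect_equal(median_event_time(list(t1), p),
               median(oracle_slope_events(as.numeric(t1), rate)))
  # even count: mean of the central pair, pooled across two traces
  ev_all <- c(oracle_slope_events(as.numeric(mk(100)), rate),
              oracle_slope_events(as.numeric(mk(300)), rate))
  expect_equal(median_event_time(list(mk(100), mk(300)), p), mean(ev_all))
  expect_true(is.na(median_event_time(list(as_trace(rep(0, 1000))), p)))
})

test_that("center_of_gravity is the half-area time of the rectified trace", {
  # symmetric triangle centered at 500 ms
  tri <- as_trace(c(seq(0, 1, length.out = 500), seq(1, 0, length.out = 500)))
  expect_equal(center_of_gravity(tri), 500, tolerance = 2)
  # constant positive trace on [0, 1000)
  expect_equal(center_of_gravity(as_trace(rep(2, 1000))), 500, tolerance = 1)
  # rectangular bump on [600, 800) over zero
  bump <- rep(0, 1000); bump[601:800] <- 1
  expect_equal(center_of_gravity(as_trace(bump)), 700, tolerance = 1)
  expect_true(is.na(center_of_gravity(as_trace(rep(-1, 1000)))))
  # invariant under positive scaling; shifts with the trace
  set.seed(3)
  x <- pmax(moving_average(rnorm(800), 10, rate), 0)
  x[1:50] <- 0  # room to shift
  tr <- as_trace(x, rate)
  expect_equal(center_of_gravity(as_trace(5.5 * x, rate)),
               center_of_gravity(tr))
  shifted <- as_trace(c(rep(0, 40), x[1:(length(x) - 40)]), rate)
  expect_equal(center_of_gravity(shifted), center_of_gravity(tr) + 40,
               tolerance = 1)
  expect_equal(peak_time(shifted), peak_time(tr) + 40)
})

test_that("peak_time_cdf pools the first five traces per neuron", {
  mk_peak <- function(at) {
    x <- rep(0, 1000); x[at + 1] <- 1
    as_trace(x)
  }
  groups <- list(a = list(list(mk_peak(100), mk_peak(100))),
                 b = list(list(mk_peak(600))))
  out <- peak_time_cdf(groups, p)
  cdf_a <- out$cdf[out$cdf$group == "a", ]
  expect_equal(unique(cdf_a$peak_time_ms), 100)
  expect_equal(max(cdf_a$ecdf), 1)
  # disjoint supports -> KS statistic 1
  expect_equal(out$ks_stat, 1)
  # a neuron with more than five traces contributes exactly five
  many <- list(a = list(purrr::map(1:8, ~ mk_peak(100))),
               b = list(list(mk_peak(600))))
  expect_equal(nrow(peak_time_cdf(many, p)$cdf |>
                      dplyr::filter(group == "a")), 5)
  expect_error(peak_time_cdf(list(a = list()), p), "empty")
})
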