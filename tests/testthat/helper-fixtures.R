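# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored data.

# Small, fast generator world for unit tests (acceptance tests use the
# package defaults).
tiny_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_neurons = 2, spont_duration_s = 40,
         n_pairs = 1, n_probe_pairs = 1),
    list(...))
  do.call(generator_config, args)
}

# A sweep that is `resting` everywhere except for square depolarizations of
# `amp` mV over the half-open ms windows in `pulses` (list of c(start, end)).
square_sweep <- function(pulses, dur_ms = 5000, amp = 8, resting = -65,
                         rate = 10000) {
  n <- round(dur_ms / 1000 * rate)
  x <- rep(resting, n)
  for (p in pulses) {
    i <- seq.int(floor(p[1] / 1000 * rate) + 1, ceiling(p[2] / 1000 * rate))
    x[i] <- resting + amp
  }
  voltage_sweep(x, sample_rate = rate)
}

# Independent brute-force event detector: explicit run/gap scan, iterative
# left-to-right merge to fixpoint, then the duration and baseline rules.
# Works directly on a logical vector; returns onset/offset sample indices
# (1-based, offset exclusive).
oracle_detect <- function(above, rate, max_dip_ms = 25, min_event_ms = 100,
                          baseline_ms = 100) {
  dt <- 1000 / rate
  runs <- list()
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  # merge until fixpoint
  repeat {
    merged <- FALSE
    k <- 1
    while (k < length(runs)) {
      gap <- (runs[[k + 1]][1] - runs[[k]][2] - 1) * dt
      if (gap < max_dip_ms) {
        runs[[k]] <- c(runs[[k]][1], runs[[k + 1]][2])
        runs[[k + 1]] <- NULL
        merged <- TRUE
      } else {
        k <- k + 1
      }
    }
    if (!merged) break
  }
  keep <- Filter(function(r) (r[2] - r[1] + 1) * dt >= min_event_ms, runs)
  out <- list()
  last_off_ms <- -Inf
  for (r in keep) {
    onset_ms <- (r[1] - 1) * dt
    offset_ms <- r[2] * dt
    if (onset_ms - baseline_ms >= 0 &&
        onset_ms - last_off_ms >= baseline_ms) {
      out[[length(out) + 1]] <- c(onset = onset_ms, offset = offset_ms)
      last_off_ms <- offset_ms
    }
  }
  if (length(out) == 0) {
    return(data.frame(onset = numeric(), offset = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}

# Random binary sequence with persistent runs (Markov chain), as a voltage
# sweep 8 mV above rest when "on".
random_binary_sweep <- function(n = 400, rate = 1000, p_flip = 0.05) {
  state <- stats::runif(1) < 0.5
  above <- logical(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < p_flip) state <- !state
    above[i] <- state
  }
  list(sweep = voltage_sweep(-65 + 8 * above, sample_rate = rate),
       above = above)
}

# Independent slope-event oracle: explicit loop over all slopes and runs.
oracle_slope_events <- function(trace, rate, window_ms = 10, mult = 3) {
  w <- round(window_ms * rate / 1000)
  n <- length(trace) - w
  s <- numeric(n)
  for (i in seq_len(n)) s[i] <- (trace[i + w] - trace[i]) / window_ms
  th <- mult * stats::sd(s)
  if (!is.finite(th) || th == 0) return(numeric(0))
  out <- numeric(0)
  in_run <- FALSE
  for (i in seq_len(n)) {
    if (s[i] > th && !in_run) {
      out <- c(out, (i - 1) * 1000 / rate)
      in_run <- TRUE
    } else if (s[i] <= th) {
      in_run <- FALSE
    }
  }
  out
}

# Noiseless neuron whose evoked CS window exceeds the CSUS window by a
# constant `diff_mV`; passes QC trivially. Used by the prediction-error
# arithmetic tests.
flat_diff_neuron <- function(id, diff_mV, n_sweeps = 3, rate = 1000) {
  n <- round(2.2 * rate)
  stim <- 1000
  widx <- seq.int(rate + 1, 2 * rate)
  cs <- rep(-65, n); cs[widx] <- -65 + diff_mV
  mk <- function(x, kind) voltage_sweep(x, sample_rate = rate,
                                        stim_onset = stim, kind = kind)
  sweeps <- c(
    lapply(seq_len(n_sweeps), function(i) mk(cs, "evoked_cs")),
    lapply(seq_len(n_sweeps), function(i) mk(rep(-65, n), "evoked_csus")))
  neuron_record(id, condition = "late", opsin = "none", sweeps = sweeps)
}
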