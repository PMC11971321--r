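# Seeded synthetic whole-cell voltage-trace generator.
#
# The generator emulates the statistical structure the analysis assumes:
# a resting potential carrying exponentially correlated (colored) noise,
# stylized triangular action-potential transients riding on depolarized
# segments, evoked polysynaptic envelopes whose temporal profile depends on
# the training condition, spontaneous Up-state-like bouts replaying the
# condition envelope, simultaneously recorded pairs with a configurable
# inter-ensemble lag, prediction-error neurons whose red+blue response has
# the late envelope component suppressed, and paired connectivity probes
# with EPSP-shaped postsynaptic responses.
#
# Condition envelopes are sums of difference-of-exponential components.
# Early: one component peaking at early_peak_ms. Late: the same component
# shifted to late_peak_ms, preceded by a train of brief low-amplitude
# "polysynaptic bump" components that bridge the interval from bout onset
# to the late rise. The bumps keep the trace crossing the 5 mV detection
# threshold with sub-threshold dips shorter than the 25 ms merge limit, so
# event detection anchors at the bout onset, while their small area leaves
# the center of gravity dominated by the main component (see the methods
# vignette for the sizing argument). Untrained: one component at
# untrained_peak_ms.

#' Synthetic-data generator configuration
#'
#' Defaults state the simulated world: 10 kHz sampling, -65 mV rest with
#' 0.4 mV colored noise (20 ms correlation time), 12 mV network envelopes,
#' Early/Late peaks at 120/480 ms, 5-minute spontaneous records with
#' 0.1 Hz bouts, 30 ms inter-ensemble pair lag, a quarter of Late neurons
#' carrying an 80%-suppressed red+blue late component, and 0.8/0.4 mV
#' forward/reverse probe EPSPs.
#'
#' @param seed Integer seed; equal seeds give byte-identical datasets.
#' @param n_neurons Neurons generated per training condition.
#' @param sample_rate Sampling rate (Hz).
#' @param resting_mV Resting membrane potential (mV).
#' @param noise_sd_mV,noise_tau_ms Colored-noise SD (mV) and correlation
#'   time (ms).
#' @param spike_amp_mV,spike_width_ms Stylized triangular action-potential
#'   amplitude (mV) and width (ms).
#' @param spike_rate_hz Spike rate while the envelope is depolarized above
#'   `spike_gate_mV`; 20 ms refractory period.
#' @param spike_gate_mV Envelope level gating spike emission (mV).
#' @param envelope_amp_mV Main envelope component amplitude (mV).
#' @param early_peak_ms,late_peak_ms,untrained_peak_ms Main-component peak
#'   times for the three conditions (ms after stimulus onset).
#' @param envelope_rise_ms,envelope_decay_ms Main-component time constants
#'   (ms).
#' @param bump_amp_mV,bump_rise_ms,bump_decay_ms,bump_spacing_ms Bridge
#'   bump-train shape for the Late condition.
#' @param spont_rate_hz Spontaneous bout rate (Hz); bouts follow a Poisson
#'   process with a 2 s refractory gap.
#' @param spont_duration_s Spontaneous record length per neuron (s); 0
#'   disables the spontaneous record.
#' @param n_evoked_sweeps,n_csus_sweeps Red-alone (CS) sweeps per neuron and
#'   red+blue (CSUS) sweeps per Late opsin-negative neuron.
#' @param pair_lag_ms Lag of the ChR2-labeled trace behind the
#'   Chrim-labeled trace in Late pairs (ms); Untrained pairs have zero lag.
#' @param n_pairs Simultaneously recorded pairs per paired condition
#'   (late and untrained).
#' @param pe_fraction Fraction of Late opsin-negative neurons that are
#'   prediction-error neurons; the count is `round(pe_fraction * n)`,
#'   assigned deterministically to the lowest neuron indices.
#' @param pe_suppression Fraction of the late envelope component removed
#'   from a prediction-error neuron's CSUS response.
#' @param conn_epsp_mV,conn_epsp_reverse_mV EPSP amplitudes for forward
#'   (chrim to opsin-negative) and reverse probe connections (mV).
#' @param probe_noise_sd_mV Noise SD of the quiescent probe sweeps (mV);
#'   smaller than the spontaneous-record noise because probe baselines are
#'   taken outside network events.
#' @param conn_p_forward,conn_p_reverse Connection probabilities per
#'   direction.
#' @param n_probe_pairs Probed neuron pairs (each probed in both
#'   directions).
#' @param probe_trials Trials per probe direction.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_neurons = 15L,
                             sample_rate = 10000,
                             resting_mV = -65,
                             noise_sd_mV = 0.4,
                             noise_tau_ms = 20,
                             spike_amp_mV = 55,
                             spike_width_ms = 2,
                             spike_rate_hz = 15,
                             spike_gate_mV = 8,
                             envelope_amp_mV = 12,
                             early_peak_ms = 120,
                             late_peak_ms = 480,
                             untrained_peak_ms = 250,
                             envelope_rise_ms = 30,
                             envelope_decay_ms = 150,
                             bump_amp_mV = 7.5,
                             bump_rise_ms = 2,
                             bump_decay_ms = 6,
                             bump_spacing_ms = 25,
                             spont_rate_hz = 0.1,
                             spont_duration_s = 300,
                             n_evoked_sweeps = 10L,
                             n_csus_sweeps = 10L,
                             pair_lag_ms = 30,
                             n_pairs = 4L,
                             pe_fraction = 0.25,
                             pe_suppression = 0.8,
                             conn_epsp_mV = 0.8,
                             conn_epsp_reverse_mV = 0.4,
                             probe_noise_sd_mV = 0.15,
                             conn_p_forward = 0.5,
                             conn_p_reverse = 0.5,
                             n_probe_pairs = 6L,
                             probe_trials = 10L) {
  cfg <- as.list(environment())
  abort_if(!is.numeric(cfg$seed) || length(cfg$seed) != 1,
           "generator_config: seed must be a scalar integer")
  abort_if(cfg$pe_fraction < 0 || cfg$pe_fraction > 1,
           "generator_config: pe_fraction must lie in [0, 1]")
  abort_if(cfg$early_peak_ms >= cfg$late_peak_ms,
           "generator_config: early_peak_ms must be < late_peak_ms")
  abort_if(cfg$n_neurons < 0, "generator_config: n_neurons must be >= 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "generator_config")
}

# --- envelope machinery ----------------------------------------------------

# Difference-of-exponentials component with unit peak amplitude, peaking
# tp = rise*decay/(decay-rise)*log(decay/rise) after its onset.
doe_peak_delay <- function(rise, decay) {
  rise * decay / (decay - rise) * log(decay / rise)
}

# Component evaluated at times t (ms), parameterized by its PEAK time.
doe_component <- function(t, peak_ms, amp, rise, decay) {
  tp <- doe_peak_delay(rise, decay)
  x <- t - (peak_ms - tp)
  y <- numeric(length(t))
  pos <- x > 0
  pf <- exp(-tp / decay) - exp(-tp / rise)
  y[pos] <- amp * (exp(-x[pos] / decay) - exp(-x[pos] / rise)) / pf
  y
}

# Time (ms before the peak) at which a rising component crosses `level`.
doe_rise_crossing <- function(peak_ms, amp, rise, decay, level) {
  tp <- doe_peak_delay(rise, decay)
  f <- function(dt) doe_component(peak_ms - tp + dt, peak_ms, amp, rise, decay) - level
  if (f(tp) <= 0) return(NA_real_)
  peak_ms - tp + stats::uniroot(f, c(1e-6, tp))$root
}

#' Condition-specific network envelope
#'
#' Evaluates the deterministic polysynaptic envelope of a training
#' condition at times `t_ms` relative to the stimulus (or bout) onset.
#' `csus_scale` multiplies the main (late) component only and models
#' prediction-error suppression under red+blue stimulation.
#'
#' @param t_ms Times (ms) relative to stimulus onset.
#' @param condition `"early"`, `"late"` or `"untrained"`.
#' @param cfg A [generator_config()].
#' @param csus_scale Multiplier on the main component (1 = red alone).
#' @return Envelope values (mV above rest).
#' @export
condition_envelope <- function(t_ms, condition, cfg, csus_scale = 1) {
  peak <- switch(condition,
                 early = cfg$early_peak_ms,
                 late = cfg$late_peak_ms,
                 untrained = cfg$untrained_peak_ms,
                 stop("condition_envelope: unknown condition '", condition,
                      "'", call. = FALSE))
  env <- doe_component(t_ms, peak, csus_scale * cfg$envelope_amp_mV,
                       cfg$envelope_rise_ms, cfg$envelope_decay_ms)
  if (condition == "late") {
    env <- env + late_bump_train(t_ms, cfg)
  }
  env
}

# Bridge bumps for the Late condition: from the Early-peak latency up to
# just before the main component's own threshold crossing.
late_bump_train <- function(t_ms, cfg) {
  cross <- doe_rise_crossing(cfg$late_peak_ms, cfg$envelope_amp_mV,
                             cfg$envelope_rise_ms, cfg$envelope_decay_ms,
                             5)
  if (is.na(cross)) cross <- cfg$late_peak_ms
  centers <- seq(cfg$early_peak_ms, cross - 5, by = cfg$bump_spacing_ms)
  out <- numeric(length(t_ms))
  for (ct in centers) {
    out <- out + doe_component(t_ms, ct, cfg$bump_amp_mV,
                               cfg$bump_rise_ms, cfg$bump_decay_ms)
  }
  out
}

# --- stochastic ingredients ------------------------------------------------

# Exponentially correlated (Ornstein-Uhlenbeck-like) noise in mV.
colored_noise <- function(n, cfg) {
  a <- exp(-ms_per_sample(cfg$sample_rate) / cfg$noise_tau_ms)
  innov <- stats::rnorm(n, sd = cfg$noise_sd_mV * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = stats::rnorm(1, sd = cfg$noise_sd_mV)))
}

# Stylized triangular spike transients added where the envelope is
# depolarized beyond the gate. Poisson thinning with 20 ms refractory.
add_spikes <- function(trace, env, cfg) {
  gate <- which(env > cfg$spike_gate_mV)
  if (length(gate) == 0 || cfg$spike_rate_hz <= 0) return(trace)
  dt <- ms_per_sample(cfg$sample_rate)
  p <- cfg$spike_rate_hz * dt / 1000
  hits <- gate[stats::runif(length(gate)) < p]
  if (length(hits) == 0) return(trace)
  refr <- round(20 / dt)
  keep <- hits[c(TRUE, diff(hits) > refr)]
  half <- max(1L, round(cfg$spike_width_ms / 2 / dt))
  shape <- cfg$spike_amp_mV * (1 - abs(seq(-half, half)) / (half + 1))
  n <- length(trace)
  for (k in keep) {
    idx <- (k - half):(k + half)
    ok <- idx >= 1 & idx <= n
    trace[idx[ok]] <- trace[idx[ok]] + shape[ok]
  }
  trace
}

# Spontaneous bout onsets (ms): Poisson process with a 2 s refractory gap;
# bouts must fit 1.5 s of envelope before the record end.
draw_bout_onsets <- function(cfg) {
  dur_ms <- cfg$spont_duration_s * 1000
  onsets <- numeric(0)
  t <- 500  # settle time before the first possible bout
  repeat {
    t <- t + 2000 + stats::rexp(1, cfg$spont_rate_hz) * 1000
    if (t > dur_ms - 1500) break
    onsets <- c(onsets, t)
  }
  onsets
}

# --- sweep builders --------------------------------------------------------

build_evoked_sweep <- function(condition, cfg, kind, csus_scale = 1,
                               noise = TRUE, spikes = TRUE) {
  pre_ms <- 1000
  post_ms <- 1200
  n <- round((pre_ms + post_ms) / 1000 * cfg$sample_rate)
  t <- sample_time(seq_len(n), cfg$sample_rate) - pre_ms
  env <- condition_envelope(t, condition, cfg, csus_scale = csus_scale)
  x <- cfg$resting_mV + env
  if (noise) x <- x + colored_noise(n, cfg)
  if (spikes) x <- add_spikes(x, env, cfg)
  voltage_sweep(x, sample_rate = cfg$sample_rate, t0 = 0,
                stim_onset = pre_ms, kind = kind)
}

build_spont_sweep <- function(condition, cfg, bout_onsets, lag_ms = 0,
                              noise = TRUE, spikes = TRUE) {
  n <- round(cfg$spont_duration_s * cfg$sample_rate)
  t <- sample_time(seq_len(n), cfg$sample_rate)
  env <- numeric(n)
  for (b in bout_onsets) {
    lo <- max(1L, floor((b + lag_ms) / 1000 * cfg$sample_rate))
    hi <- min(n, ceiling((b + lag_ms + 1500) / 1000 * cfg$sample_rate))
    if (hi <= lo) next
    seg <- lo:hi
    env[seg] <- env[seg] + condition_envelope(t[seg] - b - lag_ms,
                                              condition, cfg)
  }
  x <- cfg$resting_mV + env
  if (noise) x <- x + colored_noise(n, cfg)
  if (spikes) x <- add_spikes(x, env, cfg)
  voltage_sweep(x, sample_rate = cfg$sample_rate, t0 = 0,
                kind = "spontaneous")
}

# --- public generator operations ------------------------------------------

# Core neuron builder; consumes the ambient RNG stream.
gen_neuron_impl <- function(cfg, neuron_id, condition, opsin,
                            is_pe = FALSE, with_csus = NULL,
                            with_spont = TRUE, pair_id = NULL,
                            bout_onsets = NULL, lag_ms = 0,
                            noise = TRUE, spikes = TRUE) {
  abort_if(!condition %in% c("early", "late", "untrained"),
           paste0("generate_neuron: invalid condition '", condition, "'"))
  with_csus <- with_csus %||% (condition == "late" && opsin == "none")
  sweeps <- list()
  for (i in seq_len(cfg$n_evoked_sweeps)) {
    sweeps[[length(sweeps) + 1]] <-
      build_evoked_sweep(condition, cfg, "evoked_cs", 1, noise, spikes)
  }
  if (with_csus) {
    scale <- if (is_pe) 1 - cfg$pe_suppression else 1
    for (i in seq_len(cfg$n_csus_sweeps)) {
      sweeps[[length(sweeps) + 1]] <-
        build_evoked_sweep(condition, cfg, "evoked_csus", scale, noise,
                           spikes)
    }
  }
  if (with_spont && cfg$spont_duration_s > 0) {
    if (is.null(bout_onsets)) bout_onsets <- draw_bout_onsets(cfg)
    sweeps[[length(sweeps) + 1]] <-
      build_spont_sweep(condition, cfg, bout_onsets, lag_ms, noise, spikes)
  }
  neuron_record(neuron_id, condition = condition, opsin = opsin,
                sweeps = sweeps, pair_id = pair_id, is_pe = is_pe)
}

#' Generate one synthetic neuron record
#'
#' Evoked sweeps carry a 1 s baseline plus the condition's stimulus-locked
#' envelope; the spontaneous record carries Poisson bouts replaying the same
#' envelope; colored noise and stylized spikes are added throughout. The
#' RNG is seeded from `cfg$seed` on entry, so equal configurations give
#' identical records.
#'
#' @param cfg A [generator_config()].
#' @param condition Training condition.
#' @param opsin Opsin label.
#' @param neuron_id Identifier for the record.
#' @param is_pe Make this a prediction-error neuron (Late red+blue sweeps
#'   have the late component suppressed by `cfg$pe_suppression`).
#' @param with_csus Generate red+blue (CSUS) sweeps; defaults to `TRUE` for
#'   Late opsin-negative neurons.
#' @param with_spont Generate the spontaneous record.
#' @param noise,spikes Disable for noiseless construction checks.
#' @return A [neuron_record()].
#' @export
generate_neuron <- function(cfg, condition, opsin = "none",
                            neuron_id = "n1", is_pe = FALSE,
                            with_csus = NULL, with_spont = TRUE,
                            noise = TRUE, spikes = TRUE) {
  set.seed(cfg$seed)
  gen_neuron_impl(cfg, neuron_id, condition, opsin, is_pe = is_pe,
                  with_csus = with_csus, with_spont = with_spont,
                  noise = noise, spikes = spikes)
}

# Pair builder consuming the ambient RNG stream.
gen_pair_impl <- function(cfg, condition, pair_id, id_prefix,
                          noise = TRUE, spikes = TRUE) {
  bouts <- draw_bout_onsets(cfg)
  lag <- if (condition == "late") cfg$pair_lag_ms else 0
  chrim <- gen_neuron_impl(cfg, paste0(id_prefix, "_chrim"), condition,
                           "chrim", with_csus = FALSE, pair_id = pair_id,
                           bout_onsets = bouts, lag_ms = 0, noise = noise,
                           spikes = spikes)
  chr2 <- gen_neuron_impl(cfg, paste0(id_prefix, "_chr2"), condition,
                          "chr2", with_csus = FALSE, pair_id = pair_id,
                          bout_onsets = bouts, lag_ms = lag, noise = noise,
                          spikes = spikes)
  # pairs are analyzed on their spontaneous records only
  chrim$sweeps <- Filter(function(s) s$kind == "spontaneous", chrim$sweeps)
  chr2$sweeps <- Filter(function(s) s$kind == "spontaneous", chr2$sweeps)
  list(chrim = chrim, chr2 = chr2)
}

#' Generate a simultaneously recorded neuron pair
#'
#' Both records share a bout schedule; in the Late condition the
#' ChR2-labeled trace's bout envelope is delayed by `cfg$pair_lag_ms`
#' relative to the Chrim-labeled trace, with independent noise on each.
#' Untrained pairs have zero lag.
#'
#' @inheritParams generate_neuron
#' @param pair_id Shared pair identifier.
#' @return List of two [neuron_record()]s, `chrim` and `chr2`.
#' @export
generate_pair <- function(cfg, condition = c("late", "untrained"),
                          pair_id = "p1", noise = TRUE, spikes = TRUE) {
  condition <- match.arg(condition)
  set.seed(cfg$seed)
  gen_pair_impl(cfg, condition, pair_id, pair_id, noise = noise,
                spikes = spikes)
}

# EPSP waveform added to the postsynaptic trace at each presynaptic AP.
epsp_shape_at <- function(n, ap_idx, amp, cfg) {
  dt <- ms_per_sample(cfg$sample_rate)
  len <- round(60 / dt)
  t <- (seq_len(len) - 1) * dt
  shape <- doe_component(t, 4, amp, 1.5, 8)  # peak ~4 ms after onset
  out <- numeric(n)
  for (k in ap_idx) {
    onset <- k + round(1.5 / dt)
    idx <- onset:(onset + len - 1)
    ok <- idx >= 1 & idx <= n
    out[idx[ok]] <- out[idx[ok]] + shape[ok]
  }
  out
}

gen_probe_impl <- function(cfg, probe_id, pre_id, post_id, direction,
                           connected, amp, noise = TRUE) {
  dur_ms <- 600
  n <- round(dur_ms / 1000 * cfg$sample_rate)
  dt <- ms_per_sample(cfg$sample_rate)
  ap_times <- 200 + (0:4) * 50             # 5 APs at 20 Hz
  ap_idx <- round(ap_times / dt) + 1L
  half <- max(1L, round(cfg$spike_width_ms / 2 / dt))
  spike <- (cfg$spike_amp_mV + 10) *
    (1 - abs(seq(-half, half)) / (half + 1))  # peaks above 0 mV
  trials <- purrr::map(seq_len(cfg$probe_trials), function(i) {
    pre <- rep(cfg$resting_mV, n)
    for (k in ap_idx) {
      idx <- (k - half):(k + half)
      ok <- idx >= 1 & idx <= n
      pre[idx[ok]] <- pre[idx[ok]] + spike[ok]
    }
    post <- rep(cfg$resting_mV, n)
    if (connected) post <- post + epsp_shape_at(n, ap_idx, amp, cfg)
    if (noise) {
      ncfg <- cfg
      ncfg$noise_sd_mV <- cfg$probe_noise_sd_mV
      pre <- pre + colored_noise(n, ncfg)
      post <- post + colored_noise(n, ncfg)
    }
    list(pre = pre, post = post)
  })
  connectivity_probe(probe_id, pre_id, post_id, direction,
                     sample_rate = cfg$sample_rate, trials = trials,
                     truth = list(connected = connected,
                                  epsp_mV = if (connected) amp else 0))
}

#' Generate a complete synthetic dataset
#'
#' Balanced Early/Late/Untrained groups of `cfg$n_neurons` opsin-negative
#' and ChR2-labeled neurons, `round(pe_fraction * n)` prediction-error
#' neurons assigned to the lowest Late opsin-negative indices, `cfg$n_pairs`
#' simultaneously recorded pairs for the Late and Untrained conditions, and
#' `cfg$n_probe_pairs` connectivity probe pairs probed in both directions.
#'
#' @param cfg A [generator_config()].
#' @return An [ephys_dataset()] whose provenance records the seed, the
#'   configuration, and the ground-truth prediction-error and connectivity
#'   assignments.
#' @export
#' @examples
#' d <- simulate_dataset(generator_config(seed = 7, n_neurons = 2,
#'                                        spont_duration_s = 20,
#'                                        n_pairs = 1, n_probe_pairs = 1))
#' neuron_table(d)
simulate_dataset <- function(cfg = generator_config()) {
  abort_if(cfg$n_neurons == 0, "simulate_dataset: n_neurons must be >= 1")
  set.seed(cfg$seed)
  neurons <- list()
  n_pe <- round(cfg$pe_fraction * cfg$n_neurons)
  pe_ids <- character(0)
  for (cond in c("early", "late", "untrained")) {
    for (i in seq_len(cfg$n_neurons)) {
      id <- sprintf("%s_none_%02d", cond, i)
      is_pe <- cond == "late" && i <= n_pe
      if (is_pe) pe_ids <- c(pe_ids, id)
      neurons[[length(neurons) + 1]] <-
        gen_neuron_impl(cfg, id, cond, "none", is_pe = is_pe)
    }
    if (cond %in% c("early", "late")) {
      for (i in seq_len(cfg$n_neurons)) {
        id <- sprintf("%s_chr2_%02d", cond, i)
        neurons[[length(neurons) + 1]] <-
          gen_neuron_impl(cfg, id, cond, "chr2", with_csus = FALSE)
      }
    }
  }
  for (cond in c("late", "untrained")) {
    for (i in seq_len(cfg$n_pairs)) {
      pid <- sprintf("pair_%s_%02d", cond, i)
      pr <- gen_pair_impl(cfg, cond, pid, pid)
      neurons[[length(neurons) + 1]] <- pr$chrim
      neurons[[length(neurons) + 1]] <- pr$chr2
    }
  }
  probes <- list()
  conn_truth <- list()
  for (i in seq_len(cfg$n_probe_pairs)) {
    fwd <- stats::runif(1) < cfg$conn_p_forward
    rev <- stats::runif(1) < cfg$conn_p_reverse
    a <- sprintf("probe%02d_chrim", i)
    b <- sprintf("probe%02d_none", i)
    probes[[length(probes) + 1]] <-
      gen_probe_impl(cfg, sprintf("probe_%02d_fwd", i), a, b,
                     "chrim_to_none", fwd, cfg$conn_epsp_mV)
    probes[[length(probes) + 1]] <-
      gen_probe_impl(cfg, sprintf("probe_%02d_rev", i), b, a,
                     "none_to_chrim", rev, cfg$conn_epsp_reverse_mV)
    conn_truth[[length(conn_truth) + 1]] <-
      list(pair = i, forward = fwd, reverse = rev)
  }
  ephys_dataset(neurons, probes = probes,
                protocol = stimulus_protocol(),
                params = analysis_params(),
                provenance = list(generator = "replaytrace",
                                  generator_version = "0.1.0",
                                  seed = cfg$seed,
                                  config = unclass(cfg),
                                  pe_neurons = as.list(pe_ids),
                                  connectivity_truth = conn_truth))
}
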