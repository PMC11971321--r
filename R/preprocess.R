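# Spike removal, smoothing, down-sampling and resting-potential estimation.
# These run before every feature-extraction stage. Spikes are noise here:
# the analyses concern the subthreshold network envelope, so a short sliding
# median (evoked path) or block-mean down-sampling (spontaneous and paired
# paths) removes 1-3 ms action-potential transients while preserving the
# 100-ms-scale dynamics.

#' Estimate the resting membrane potential of a sweep
#'
#' Evoked sweeps: median of the 1 s pre-stimulus baseline. Spontaneous
#' sweeps: mode of a 0.5 mV-bin histogram over the full record (robust
#' against depolarized event bouts; ties resolve to the lower bin), reported
#' as the bin center.
#'
#' @param sweep A [voltage_sweep()].
#' @param bin_mV Histogram bin width for spontaneous sweeps (mV).
#' @return Resting potential (mV).
#' @export
estimate_resting <- function(sweep, bin_mV = 0.5) {
  x <- sweep$samples
  if (is_evoked(sweep)) {
    pre_ms <- sweep$stim_onset - sweep$t0
    abort_if(pre_ms < 1000 - 1e-9,
             "estimate_resting: evoked sweep has < 1 s pre-stimulus baseline")
    idx <- window_idx(length(x), sweep$sample_rate,
                      sweep$stim_onset - 1000, sweep$stim_onset, sweep$t0)
    return(stats::median(x[idx]))
  }
  histogram_mode(x, bin_mV)
}

# Mode of a fixed-width histogram; bins anchored at floor(min), tie -> lower
# bin. Returns the winning bin's center.
histogram_mode <- function(x, bin_mV = 0.5) {
  lo <- floor(min(x))
  bin <- floor((x - lo) / bin_mV) + 1L
  counts <- tabulate(bin)
  win <- which.max(counts) - 1L  # first max -> lower bin on ties
  lo + (win + 0.5) * bin_mV
}

#' Remove action-potential transients from a sweep
#'
#' `mode = "median"` applies a sliding median (window `window_ms`,
#' length-preserving); `mode = "downsample"` takes block means over
#' consecutive `factor`-sized sample blocks (anti-aliasing by averaging,
#' not decimation), shortening the sweep to `floor(n / factor)` samples and
#' updating its sample rate.
#'
#' @param sweep A [voltage_sweep()].
#' @param mode `"median"` or `"downsample"`.
#' @param window_ms Median window (ms); odd sample count enforced.
#' @param factor Down-sampling factor.
#' @param median_first For `"downsample"`, apply the sliding median before
#'   block-averaging (used by the paired-recording path).
#' @return A filtered [voltage_sweep()].
#' @export
#' @examples
#' sw <- voltage_sweep(c(rep(-65, 100), -10, rep(-65, 99)))
#' range(spike_filter(sw, "median", window_ms = 0.5)$samples)
spike_filter <- function(sweep, mode = c("median", "downsample"),
                         window_ms = 5, factor = 10, median_first = FALSE) {
  mode <- match.arg(mode)
  x <- sweep$samples
  n <- length(x)
  if (mode == "median") {
    k <- median_k(window_ms, sweep$sample_rate)
    abort_if(k > n, "spike_filter: median window longer than trace")
    sweep$samples <- sliding_median(x, k)
    return(sweep)
  }
  abort_if(factor > n, "spike_filter: down-sampling factor longer than trace")
  if (median_first) {
    x <- sliding_median(x, median_k(window_ms, sweep$sample_rate))
  }
  m <- floor(n / factor)
  y <- colMeans(matrix(x[seq_len(m * factor)], nrow = factor))
  voltage_sweep(y, sample_rate = sweep$sample_rate / factor, t0 = sweep$t0,
                stim_onset = sweep$stim_onset, kind = sweep$kind)
}

median_k <- function(window_ms, sample_rate) {
  k <- round(window_ms * sample_rate / 1000)
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  k
}

sliding_median <- function(x, k) {
  if (k <= 1 || length(x) < 3) return(x)
  k <- min(k, if (length(x) %% 2 == 0) length(x) - 1 else length(x))
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

#' Centered moving-average smoothing
#'
#' Box filter with a centered window (no phase shift in peak-time
#' estimates); at the edges the window shrinks symmetrically. Length is
#' preserved; affine signals pass through unchanged away from the edges.
#'
#' @param x Numeric trace.
#' @param window_ms Window (ms); a 10 ms window at 10 kHz spans 101 samples.
#' @param sample_rate Sampling rate (Hz).
#' @param circular Treat the trace as periodic (wrap the window) instead of
#'   shrinking at the edges; exactly mean-preserving.
#' @return Smoothed numeric trace of the same length.
#' @export
moving_average <- function(x, window_ms = 10, sample_rate = 10000,
                           circular = FALSE) {
  h <- round(window_ms * sample_rate / 1000 / 2)
  n <- length(x)
  if (h < 1 || n < 2) return(x)
  if (circular) {
    h <- min(h, (n - 1) %/% 2)
    xx <- c(x[(n - h + 1):n], x, x[1:h])
    cs <- cumsum(c(0, xx))
    i <- seq_len(n) + h
    return((cs[i + h + 1] - cs[i - h]) / (2 * h + 1))
  }
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  # shrink symmetrically at the edges so the window stays centered
  w <- pmin(pmin(i - 1L, h), pmin(n - i, h))
  lo <- i - w
  hi <- i + w
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
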