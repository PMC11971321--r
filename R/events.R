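# Spontaneous network-event (Up-state-like bout) detection and evoked-sweep
# quality control.
#
# Detection rule: binarize the voltage at resting + threshold; merge
# above-threshold runs separated by sub-threshold dips shorter than
# max_dip_ms; keep merged runs lasting at least min_event_ms (internal dips
# count toward the duration). Onset is the first above-threshold sample of
# the merged run and offset the last plus one (half-open). Events whose
# 100 ms baseline window would precede the sweep start, or whose onset
# falls within baseline_ms of the previous event's offset, are dropped so
# every retained event owns a clean baseline.

#' Detect spontaneous network events in a sweep
#'
#' Hysteresis threshold detector operating on median-filtered voltage (the
#' filter window is `params$median_window_ms`; set `prefilter = FALSE` to
#' detect on the raw trace).
#'
#' @param sweep A spontaneous [voltage_sweep()] (evoked baselines are
#'   screened through [qc_evoked_sweep()]).
#' @param resting Resting potential estimated on the same sweep (mV).
#' @param params An [analysis_params()].
#' @param prefilter Apply the sliding-median spike filter before
#'   thresholding.
#' @return Tibble with one row per event: `onset_ms`, `offset_ms`,
#'   `duration_ms`, `baseline_start_ms`. Empty when nothing is detected.
#' @export
#' @examples
#' x <- rep(-65, 5000); x[2001:4000] <- -57   # 200 ms square bout at 10 kHz
#' sw <- voltage_sweep(x)
#' detect_spontaneous_events(sw, resting = -65, prefilter = FALSE)
detect_spontaneous_events <- function(sweep, resting,
                                      params = analysis_params(),
                                      prefilter = TRUE) {
  x <- sweep$samples
  if (prefilter) {
    x <- sliding_median(x, median_k(params$median_window_ms, sweep$sample_rate))
  }
  above <- x > resting + params$spont_threshold_mV
  runs <- merged_runs(above, sweep$sample_rate,
                      max_dip_ms = params$max_dip_ms,
                      min_event_ms = params$min_event_ms)
  if (nrow(runs) == 0) {
    return(tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                          duration_ms = numeric(),
                          baseline_start_ms = numeric()))
  }
  dt <- ms_per_sample(sweep$sample_rate)
  onset <- sample_time(runs$start, sweep$sample_rate, sweep$t0)
  offset <- sample_time(runs$end, sweep$sample_rate, sweep$t0) + dt
  keep <- logical(nrow(runs))
  last_off <- -Inf
  for (i in seq_along(keep)) {
    ok <- (onset[i] - params$baseline_ms >= sweep$t0 - 1e-9) &&
      (onset[i] - last_off >= params$baseline_ms - 1e-9)
    keep[i] <- ok
    if (ok) last_off <- offset[i]
  }
  tibble::tibble(onset_ms = onset[keep], offset_ms = offset[keep],
                 duration_ms = offset[keep] - onset[keep],
                 baseline_start_ms = onset[keep] - params$baseline_ms)
}

# Merge above-threshold runs separated by short dips, then apply the
# minimum-duration rule. Iterates left-to-right to a fixpoint: a merged run
# absorbs every following run while the intervening dip is < max_dip_ms.
# Returns 1-based start/end sample indices (inclusive).
merged_runs <- function(above, sample_rate, max_dip_ms, min_event_ms) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  dt <- ms_per_sample(sample_rate)
  out_start <- integer()
  out_end <- integer()
  cur_start <- starts[on[1]]
  cur_end <- ends[on[1]]
  if (length(on) > 1) {
    for (j in on[-1]) {
      gap_ms <- (starts[j] - cur_end - 1L) * dt
      if (gap_ms < max_dip_ms) {
        cur_end <- ends[j]
      } else {
        out_start <- c(out_start, cur_start)
        out_end <- c(out_end, cur_end)
        cur_start <- starts[j]
        cur_end <- ends[j]
      }
    }
  }
  out_start <- c(out_start, cur_start)
  out_end <- c(out_end, cur_end)
  dur_ms <- (out_end - out_start + 1L) * dt
  keep <- dur_ms >= min_event_ms - 1e-9
  data.frame(start = out_start[keep], end = out_end[keep])
}

#' Screen an evoked sweep for baseline contamination
#'
#' Sweeps whose 1 s pre-stimulus baseline contains spontaneous network
#' activity are excluded so evoked responses are not contaminated. The
#' resting estimate used for the baseline screen is re-computed on the first
#' 500 ms of the baseline (median) to avoid circularity when the late
#' baseline is itself contaminated.
#'
#' @param sweep An evoked [voltage_sweep()].
#' @param params An [analysis_params()].
#' @return `TRUE` to keep the sweep, `FALSE` to exclude it.
#' @export
qc_evoked_sweep <- function(sweep, params = analysis_params()) {
  abort_if(!is_evoked(sweep) || is.null(sweep$stim_onset),
           "qc_evoked_sweep: sweep has no stimulus onset")
  idx <- window_idx(length(sweep$samples), sweep$sample_rate,
                    sweep$stim_onset - 1000, sweep$stim_onset, sweep$t0)
  base <- sweep$samples[idx]
  half <- base[seq_len(floor(length(base) / 2))]
  resting <- stats::median(half)
  # events at the very start of the baseline also disqualify: no onset guard
  x <- sliding_median(base, median_k(params$median_window_ms, sweep$sample_rate))
  runs <- merged_runs(x > resting + params$spont_threshold_mV,
                      sweep$sample_rate, params$max_dip_ms,
                      params$min_event_ms)
  nrow(runs) == 0
}

#' Extract the preprocessed evoked analysis window
#'
#' Returns the `[stim_onset, stim_onset + window_ms)` segment of an evoked
#' sweep, spike-filtered (sliding median), smoothed (centered moving
#' average) and baseline-subtracted by the median of the 1 s pre-stimulus
#' baseline. Filtering happens on the whole sweep before the window is cut
#' so the segment carries no filter edge artifacts.
#'
#' @param sweep An evoked [voltage_sweep()] that passed QC.
#' @param params An [analysis_params()].
#' @return Numeric trace of the analysis window (mV relative to baseline),
#'   with attributes `sample_rate` and `baseline_mV`.
#' @export
evoked_window <- function(sweep, params = analysis_params()) {
  abort_if(!is_evoked(sweep), "evoked_window: not an evoked sweep")
  end_ms <- sweep$stim_onset + params$window_ms
  abort_if(end_ms - 1e-9 > sweep$t0 + sweep_duration_ms(sweep),
           "evoked_window: analysis window exceeds sweep end")
  x <- sliding_median(sweep$samples,
                      median_k(params$median_window_ms, sweep$sample_rate))
  x <- moving_average(x, params$smooth_ms, sweep$sample_rate)
  bidx <- window_idx(length(x), sweep$sample_rate,
                     sweep$stim_onset - 1000, sweep$stim_onset, sweep$t0)
  baseline <- stats::median(x[bidx])
  widx <- window_idx(length(x), sweep$sample_rate, sweep$stim_onset, end_ms,
                     sweep$t0)
  out <- x[widx] - baseline
  attr(out, "sample_rate") <- sweep$sample_rate
  attr(out, "baseline_mV") <- baseline
  out
}

#' Extract onset-locked spontaneous analysis windows
#'
#' For every detected event, cuts `[onset - baseline_ms, onset + window_ms)`
#' from the raw sweep, block-averages it down by `params$spont_downsample`
#' (spike removal), and subtracts the median of the baseline segment.
#' Windows running past the sweep end are dropped.
#'
#' @param sweep The spontaneous [voltage_sweep()] the events came from.
#' @param events Tibble from [detect_spontaneous_events()].
#' @param params An [analysis_params()].
#' @return List of numeric analysis-window traces (length
#'   `window_ms / spont_downsample * sample_rate / 1000` each), with
#'   attribute `sample_rate` on each.
#' @export
spontaneous_windows <- function(sweep, events, params = analysis_params()) {
  f <- params$spont_downsample
  rate <- sweep$sample_rate / f
  purrr::compact(purrr::map(seq_len(nrow(events)), function(i) {
    on <- events$onset_ms[i]
    if (on + params$window_ms - 1e-9 > sweep$t0 + sweep_duration_ms(sweep)) {
      return(NULL)
    }
    idx <- window_idx(length(sweep$samples), sweep$sample_rate,
                      on - params$baseline_ms, on + params$window_ms,
                      sweep$t0)
    seg <- sweep$samples[idx]
    m <- floor(length(seg) / f)
    seg <- colMeans(matrix(seg[seq_len(m * f)], nrow = f))
    nb <- round(params$baseline_ms / 1000 * rate)
    out <- seg[(nb + 1):length(seg)] - stats::median(seg[seq_len(nb)])
    attr(out, "sample_rate") <- rate
    out
  }))
}
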