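# Monosynaptic connectivity calls from paired current-clamp probe
# recordings: EPSP amplitudes relative to a pre-spike baseline, a
# connection call when the mean amplitude reaches conn_sd_mult times the
# across-trial baseline SD, and per-direction summaries of connected-pair
# strength and connection probability.

#' Detect presynaptic action-potential times in a probe trial
#'
#' Upward crossings of `ap_threshold_mV` (default 0 mV — only spike
#' transients reach it from a subthreshold resting potential).
#'
#' @param pre Presynaptic trace (mV).
#' @param sample_rate Sampling rate (Hz).
#' @param threshold_mV Crossing threshold (mV, absolute).
#' @return AP peak times (ms); one per suprathreshold excursion.
#' @export
detect_ap_times <- function(pre, sample_rate, threshold_mV = 0) {
  above <- pre > threshold_mV
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  peaks <- vapply(on, function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(pre[seg])]
  }, integer(1))
  sample_time(peaks, sample_rate)
}

#' EPSP amplitude following one presynaptic action potential
#'
#' Peak voltage in the post-AP search window minus the mean of the pre-AP
#' baseline window (windows set in [analysis_params()]); invariant to a
#' constant offset of the whole trace.
#'
#' @param post Postsynaptic trace (mV).
#' @param ap_time_ms Presynaptic AP peak time (ms).
#' @param sample_rate Sampling rate (Hz).
#' @param params An [analysis_params()].
#' @return List `amplitude` (mV) and `baseline_mean` (mV); `NULL` when a
#'   window leaves the sweep (the trial is dropped).
#' @export
epsp_amplitude <- function(post, ap_time_ms, sample_rate,
                           params = analysis_params()) {
  n <- length(post)
  bidx <- window_idx(n, sample_rate,
                     ap_time_ms + params$epsp_baseline_from_ms,
                     ap_time_ms + params$epsp_baseline_to_ms)
  sidx <- window_idx(n, sample_rate,
                     ap_time_ms + params$epsp_search_from_ms,
                     ap_time_ms + params$epsp_search_to_ms)
  full_b <- round((params$epsp_baseline_to_ms - params$epsp_baseline_from_ms) *
                    sample_rate / 1000)
  full_s <- round((params$epsp_search_to_ms - params$epsp_search_from_ms) *
                    sample_rate / 1000)
  if (length(bidx) < full_b || length(sidx) < full_s) return(NULL)
  bl <- mean(post[bidx])
  list(amplitude = max(post[sidx]) - bl, baseline_mean = bl)
}

#' Call a monosynaptic connection from a probe
#'
#' Scores the first AP of each trial train ("first EPSP amplitude"),
#' averages amplitudes across trials, and calls a connection when the mean
#' amplitude is at least `conn_sd_mult` times the across-trial SD of the
#' baseline means (inclusive boundary, per "at least"). Calls from fewer
#' than `conn_min_trials` trials are flagged low-confidence but still
#' returned.
#'
#' @param probe A [connectivity_probe()].
#' @param params An [analysis_params()].
#' @return One-row tibble: `probe_id`, `pre_id`, `post_id`, `direction`,
#'   `n_trials`, `mean_epsp_mV`, `baseline_sd_mV`, `connected`,
#'   `low_confidence`.
#' @export
call_connection <- function(probe, params = analysis_params()) {
  trials <- purrr::compact(purrr::map(probe$trials, function(tr) {
    aps <- detect_ap_times(tr$pre, probe$sample_rate,
                           params$ap_threshold_mV)
    if (length(aps) == 0) return(NULL)
    epsp_amplitude(tr$post, aps[1], probe$sample_rate, params)
  }))
  abort_if(length(trials) == 0,
           paste0("call_connection: no scorable trials in ", probe$probe_id))
  amps <- purrr::map_dbl(trials, "amplitude")
  bls <- purrr::map_dbl(trials, "baseline_mean")
  mean_epsp <- mean(amps)
  baseline_sd <- stats::sd(bls)
  # inclusive boundary ("at least"); epsilon keeps exact ties connected
  # under floating point
  thr <- params$conn_sd_mult * baseline_sd
  tibble::tibble(
    probe_id = probe$probe_id, pre_id = probe$pre_id,
    post_id = probe$post_id, direction = probe$direction,
    n_trials = length(trials),
    mean_epsp_mV = mean_epsp, baseline_sd_mV = baseline_sd,
    connected = mean_epsp >= thr - 1e-9 * max(1, abs(thr)),
    low_confidence = length(trials) < params$conn_min_trials)
}

#' Connection calls for every probe in a dataset
#'
#' @param dataset An [ephys_dataset()] with probes.
#' @param params Analysis parameters; defaults to the dataset's own.
#' @return Tibble of [call_connection()] rows, class `connectivity_calls`.
#' @export
connectivity_calls <- function(dataset, params = NULL) {
  params <- params %||% dataset$params
  out <- purrr::map_dfr(dataset$probes, call_connection, params = params)
  class(out) <- c("connectivity_calls", class(out))
  out
}

#' Per-direction connectivity summary
#'
#' Mean and SEM of connected-pair EPSP amplitudes and the connection
#' probability (connected / probed) per direction, with a two-sided
#' unpaired t comparison of amplitudes and a two-proportion comparison of
#' probabilities between the first two directions.
#'
#' @param calls Tibble from [connectivity_calls()] or [call_connection()].
#' @return List with `by_direction` (tibble) and, when two directions are
#'   present, `amplitude_t_p`, `probability_p`.
#' @export
direction_summary <- function(calls) {
  abort_if(nrow(calls) == 0, "direction_summary: no calls")
  by_dir <- calls |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      n_probed = dplyr::n(),
      n_connected = sum(.data$connected),
      connection_probability = mean(.data$connected),
      mean_epsp_mV = mean(.data$mean_epsp_mV[.data$connected]),
      sem_epsp_mV = sem(.data$mean_epsp_mV[.data$connected]),
      .groups = "drop")
  out <- list(by_direction = by_dir)
  dirs <- by_dir$direction
  if (length(dirs) == 2) {
    a <- calls$mean_epsp_mV[calls$connected & calls$direction == dirs[1]]
    b <- calls$mean_epsp_mV[calls$connected & calls$direction == dirs[2]]
    out$amplitude_t_p <- if (length(a) >= 2 && length(b) >= 2) {
      tryCatch(stats::t.test(a, b, var.equal = TRUE)$p.value,
               error = function(e) NA_real_)  # degenerate: zero variance
    } else {
      NA_real_
    }
    cnt <- by_dir$n_connected
    tot <- by_dir$n_probed
    out$probability_p <- tryCatch(
      suppressWarnings(stats::prop.test(cnt, tot)$p.value),
      error = function(e) NA_real_)
  }
  out
}
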