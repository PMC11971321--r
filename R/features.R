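# Temporal features of evoked and spontaneous analysis-window traces:
# peak time, slope-threshold event times, center of gravity, and pooled
# peak-time cumulative distributions. Per-neuron aggregation uses medians
# of per-trace values; group-level summaries use means of per-neuron
# medians.

#' Time of the peak voltage in an analysis window
#'
#' @param trace Filtered, smoothed analysis-window trace (from
#'   [evoked_window()] or [spontaneous_windows()]).
#' @param sample_rate Sampling rate (Hz); defaults to the trace's
#'   `sample_rate` attribute.
#' @return Peak time in ms from window start; ties resolve to the earliest
#'   sample.
#' @export
peak_time <- function(trace, sample_rate = attr(trace, "sample_rate")) {
  abort_if(is.null(sample_rate), "peak_time: sample_rate unknown")
  (which.max(trace) - 1) * ms_per_sample(sample_rate)
}

#' Onset times of suprathreshold voltage slopes
#'
#' The slope at time t is `(V(t + w) - V(t)) / w` with `w =
#' params$slope_window_ms`. The threshold is `slope_sd_mult` times the
#' standard deviation of all slopes of the trace; event times are the
#' onsets of maximal contiguous runs of suprathreshold slope. A
#' zero-variance trace yields no events.
#'
#' @param trace Analysis-window trace.
#' @param params An [analysis_params()].
#' @param sample_rate Sampling rate (Hz).
#' @return Numeric vector of event onset times (ms from window start).
#' @export
slope_event_times <- function(trace, params = analysis_params(),
                              sample_rate = attr(trace, "sample_rate")) {
  abort_if(is.null(sample_rate), "slope_event_times: sample_rate unknown")
  w <- round(params$slope_window_ms * sample_rate / 1000)
  abort_if(length(trace) <= w, "slope_event_times: trace shorter than slope window")
  n <- length(trace) - w
  s <- (trace[(w + 1):(w + n)] - trace[1:n]) / params$slope_window_ms
  sd_s <- stats::sd(s)
  if (!is.finite(sd_s) || sd_s == 0) return(numeric(0))
  above <- s > params$slope_sd_mult * sd_s
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  (starts[r$values] - 1) * ms_per_sample(sample_rate)
}

#' Median time of pooled slope events for one neuron
#'
#' Pools slope-event times across all of a neuron's analysis-window traces
#' and returns the median (mean of the central pair for an even count).
#'
#' @param traces List of analysis-window traces.
#' @param params An [analysis_params()].
#' @return Median event time (ms), or `NA` when no trace has any event.
#' @export
median_event_time <- function(traces, params = analysis_params()) {
  ev <- unlist(purrr::map(traces, slope_event_times, params = params))
  if (length(ev) == 0) return(NA_real_)
  stats::median(ev)
}

#' Center of gravity of an analysis-window trace
#'
#' Midpoint of the integrated trace area: negative values are rectified to
#' zero, the cumulative trapezoidal integral is formed, and the earliest
#' time at which it reaches half its final value is returned. Invariant
#' under positive scaling of the trace.
#'
#' @param trace Baseline-subtracted analysis-window trace.
#' @param sample_rate Sampling rate (Hz).
#' @param rectify Rectify negatives before integrating (the default); set
#'   `FALSE` for the signed-integral variant.
#' @return Center-of-gravity time (ms), or `NA` for an all-zero rectified
#'   trace.
#' @export
center_of_gravity <- function(trace, sample_rate = attr(trace, "sample_rate"),
                              rectify = TRUE) {
  abort_if(is.null(sample_rate), "center_of_gravity: sample_rate unknown")
  y <- as.numeric(trace)
  if (rectify) y <- pmax(y, 0)
  n <- length(y)
  if (n < 2) return(NA_real_)
  inc <- (y[-1] + y[-n]) / 2          # per-step trapezoid areas
  cum <- c(0, cumsum(inc))
  total <- cum[n]
  if (total <= 0) return(NA_real_)
  i <- which(cum >= total / 2)[1]
  (i - 1) * ms_per_sample(sample_rate)
}

#' Per-neuron temporal feature summary
#'
#' Computes per-trace peak times, slope-event times and centers of gravity
#' for one context (evoked or spontaneous) and aggregates them per neuron:
#' the median of per-trace peak times, the median of pooled slope-event
#' times, and the mean of per-trace centers of gravity.
#'
#' @param traces List of analysis-window traces for one neuron.
#' @param params An [analysis_params()].
#' @return One-row tibble: `median_peak_time_ms`, `median_event_time_ms`,
#'   `mean_cog_ms`, `n_traces`, plus a `per_trace` list-column.
#' @export
feature_summary <- function(traces, params = analysis_params()) {
  abort_if(length(traces) == 0, "feature_summary: no traces")
  per <- purrr::map_dfr(seq_along(traces), function(i) {
    tr <- traces[[i]]
    tibble::tibble(
      trace = i,
      peak_time_ms = peak_time(tr),
      cog_ms = center_of_gravity(tr),
      event_times_ms = list(slope_event_times(tr, params)))
  })
  tibble::tibble(
    median_peak_time_ms = stats::median(per$peak_time_ms),
    median_event_time_ms = {
      ev <- unlist(per$event_times_ms)
      if (length(ev)) stats::median(ev) else NA_real_
    },
    mean_cog_ms = mean(per$cog_ms, na.rm = TRUE),
    n_traces = nrow(per),
    per_trace = list(per))
}

#' Pooled peak-time empirical distribution for a group of neurons
#'
#' Each neuron contributes its first `min(cdf_n_sweeps, available)` traces;
#' per-trace peak times are pooled into one empirical CDF per group. When
#' two groups are supplied the two-sample Kolmogorov-Smirnov statistic is
#' attached.
#'
#' @param group_traces Named list: one element per group, each a list of
#'   per-neuron trace lists.
#' @param params An [analysis_params()].
#' @return List with `cdf` (tibble `group`, `peak_time_ms`, `ecdf`) and,
#'   for two groups, `ks_stat` and `ks_p`.
#' @export
peak_time_cdf <- function(group_traces, params = analysis_params()) {
  abort_if(length(group_traces) == 0, "peak_time_cdf: no groups")
  pools <- purrr::map(group_traces, function(neurons) {
    abort_if(length(neurons) == 0, "peak_time_cdf: empty group")
    unlist(purrr::map(neurons, function(traces) {
      take <- utils::head(traces, params$cdf_n_sweeps)
      vapply(take, peak_time, numeric(1))
    }))
  })
  cdf <- purrr::imap_dfr(pools, function(x, g) {
    x <- sort(x)
    tibble::tibble(group = g, peak_time_ms = x,
                   ecdf = seq_along(x) / length(x))
  })
  out <- list(cdf = cdf)
  if (length(pools) == 2) {
    ks <- suppressWarnings(stats::ks.test(pools[[1]], pools[[2]]))
    out$ks_stat <- unname(ks$statistic)
    out$ks_p <- ks$p.value
  }
  out
}
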