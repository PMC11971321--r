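# Pairwise correlation and cross-correlation lag between simultaneously
# recorded neurons during spontaneous network events.
#
# Both traces are median-filtered and block-averaged down by a factor of 50
# (200 Hz at the native 10 kHz). Event indices detected on each neuron are
# unioned; overlapping events merge, keeping the earliest onset and the
# latest offset. Each analysis segment spans paired_segment_ms (1100 ms),
# including baseline_ms (100 ms) before the combined onset. For the
# cross-correlation the segments are trimmed to [onset + 50, offset - 50) ms
# to exclude transitions between active and inactive states.
#
# Sign convention: pairs are ordered (chrim, chr2) when opsin labels exist,
# else by neuron_id; a positive peak lag means the second (ChR2-labeled)
# neuron's activity follows the first (Chrim-labeled) neuron's.

order_pair <- function(a, b) {
  if (a$opsin == "chrim" || b$opsin == "chrim") {
    if (b$opsin == "chrim") list(first = b, second = a) else list(first = a, second = b)
  } else if (identical(sort(c(a$neuron_id, b$neuron_id))[1], a$neuron_id)) {
    list(first = a, second = b)
  } else {
    list(first = b, second = a)
  }
}

first_spont_sweep <- function(neuron) {
  s <- Filter(function(x) x$kind == "spontaneous", neuron$sweeps)
  abort_if(length(s) == 0,
           paste0("paired analysis: neuron ", neuron$neuron_id,
                  " has no spontaneous sweep"))
  s[[1]]
}

#' Combined-event segments for a simultaneously recorded pair
#'
#' Detects spontaneous events on each neuron, unions and merges the event
#' index, and cuts the paired segments from both median-filtered,
#' down-sampled traces.
#'
#' @param a,b The two [neuron_record()]s of a pair (any order; the
#'   chrim/chr2 convention is applied internally).
#' @param params An [analysis_params()].
#' @return List with `segments` (list of `list(x, y, onset_ms, offset_ms)`
#'   where `x` is the Chrim-labeled/first trace segment), `rate` (Hz), and
#'   `pair` (the ordered records). Segments exceeding the record bounds are
#'   dropped.
#' @export
combined_event_segments <- function(a, b, params = analysis_params()) {
  pr <- order_pair(a, b)
  sa <- first_spont_sweep(pr$first)
  sb <- first_spont_sweep(pr$second)
  abort_if(sa$sample_rate != sb$sample_rate,
           "combined_event_segments: pair sample rates differ")

  ev_a <- detect_spontaneous_events(sa, estimate_resting(sa), params)
  ev_b <- detect_spontaneous_events(sb, estimate_resting(sb), params)
  ev <- dplyr::arrange(dplyr::bind_rows(ev_a, ev_b), .data$onset_ms)
  merged <- merge_event_intervals(ev)

  f <- params$paired_downsample
  da <- spike_filter(sa, "downsample", window_ms = params$median_window_ms,
                     factor = f, median_first = TRUE)
  db <- spike_filter(sb, "downsample", window_ms = params$median_window_ms,
                     factor = f, median_first = TRUE)
  rate <- da$sample_rate
  nseg <- round(params$paired_segment_ms / 1000 * rate)
  dur <- sweep_duration_ms(da)

  segments <- purrr::compact(purrr::map(seq_len(nrow(merged)), function(i) {
    start <- merged$onset_ms[i] - params$baseline_ms
    if (start < da$t0 || start + params$paired_segment_ms > da$t0 + dur) {
      return(NULL)
    }
    idx <- window_idx(length(da$samples), rate, start,
                      start + params$paired_segment_ms, da$t0)
    if (length(idx) < nseg) return(NULL)
    idx <- idx[seq_len(nseg)]
    list(x = da$samples[idx], y = db$samples[idx],
         onset_ms = merged$onset_ms[i], offset_ms = merged$offset_ms[i])
  }))
  list(segments = segments, rate = rate, pair = pr)
}

# Union of event intervals: overlapping (or touching) events merge, keeping
# the earliest onset and latest offset.
merge_event_intervals <- function(ev) {
  if (nrow(ev) == 0) {
    return(tibble::tibble(onset_ms = numeric(), offset_ms = numeric()))
  }
  on <- ev$onset_ms
  off <- ev$offset_ms
  o_out <- on[1]; f_out <- off[1]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      k <- length(o_out)
      if (on[i] <= f_out[k]) {
        f_out[k] <- max(f_out[k], off[i])
      } else {
        o_out <- c(o_out, on[i]); f_out <- c(f_out, off[i])
      }
    }
  }
  tibble::tibble(onset_ms = o_out, offset_ms = f_out)
}

#' Mean pairwise r-squared over combined-event segments
#'
#' Pearson correlation between the two traces of each segment, squared, and
#' averaged across segments. Zero-variance segments are dropped.
#'
#' @param segments `segments` element from [combined_event_segments()].
#' @return List `mean_r2`, `per_segment` (numeric vector), `n_segments`.
#' @export
pairwise_r2 <- function(segments) {
  abort_if(length(segments) == 0, "pairwise_r2: no segments")
  r2 <- purrr::map_dbl(segments, function(s) {
    if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0) return(NA_real_)
    stats::cor(s$x, s$y)^2
  })
  r2 <- r2[!is.na(r2)]
  list(mean_r2 = mean(r2), per_segment = r2, n_segments = length(r2))
}

# Pearson correlation of two equal-length traces at an integer lag
# (positive lag: y shifted later); NA when the overlap is degenerate.
cor_at_lag <- function(x, y, lag) {
  n <- length(x)
  if (abs(lag) > n - 3) return(NA_real_)
  if (lag >= 0) {
    xs <- x[seq_len(n - lag)]
    ys <- y[seq_len(n - lag) + lag]
  } else {
    xs <- x[seq_len(n + lag) - lag]
    ys <- y[seq_len(n + lag)]
  }
  if (length(xs) < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(NA_real_)
  }
  stats::cor(xs, ys)
}

#' Cross-correlation function and peak lag for a pair
#'
#' Per-segment normalized cross-correlation of the trimmed event segments
#' over lags within `xcorr_max_lag_ms`, averaged across segments. The peak
#' lag is the lag of the averaged function's maximum (ties resolve to the
#' smallest absolute lag); `peak_r2` is the mean across segments of the
#' squared correlation at that lag.
#'
#' @param seg Result of [combined_event_segments()].
#' @param params An [analysis_params()].
#' @return List with `xcorr` (tibble `lag_ms`, `r`), `peak_lag_ms`,
#'   `peak_r2`, `n_segments`; `NULL` when all segments are too short after
#'   trimming.
#' @export
xcorr_lag <- function(seg, params = analysis_params()) {
  rate <- seg$rate
  dt <- ms_per_sample(rate)
  max_lag <- round(params$xcorr_max_lag_ms / dt)
  trimmed <- purrr::compact(purrr::map(seg$segments, function(s) {
    # segment starts baseline_ms before the onset
    from <- params$baseline_ms + params$xcorr_trim_ms
    to <- params$baseline_ms + (s$offset_ms - s$onset_ms) - params$xcorr_trim_ms
    i0 <- floor(from / dt) + 1
    i1 <- min(ceiling(to / dt), length(s$x))
    if (i1 - i0 + 1 < 3) return(NULL)
    list(x = s$x[i0:i1], y = s$y[i0:i1])
  }))
  if (length(trimmed) == 0) return(NULL)
  lags <- seq.int(-max_lag, max_lag)
  cc <- vapply(trimmed, function(s) {
    vapply(lags, function(L) cor_at_lag(s$x, s$y, L), numeric(1))
  }, numeric(length(lags)))
  cc <- matrix(cc, nrow = length(lags))
  # only search lags every segment covers; short segments would otherwise
  # contribute spuriously high correlations from tiny overlaps
  full <- rowSums(is.na(cc)) == 0
  if (!any(full)) full <- rowMeans(is.na(cc)) <= 0.5
  if (!any(full)) return(NULL)
  cc <- cc[full, , drop = FALSE]
  lags <- lags[full]
  avg <- rowMeans(cc, na.rm = TRUE)
  best <- which(avg >= max(avg, na.rm = TRUE) - 1e-12)
  best <- best[which.min(abs(lags[best]))]       # tie -> smallest |lag|
  peak_r2 <- mean(cc[best, ]^2, na.rm = TRUE)
  list(xcorr = tibble::tibble(lag_ms = lags * dt, r = avg),
       peak_lag_ms = lags[best] * dt, peak_r2 = peak_r2,
       n_segments = length(trimmed))
}

#' Paired spontaneous-activity dynamics for all pairs in a dataset
#'
#' Runs the combined-event segmentation, pairwise r-squared, and
#' cross-correlation lag analysis on every `pair_id` in the dataset.
#'
#' @param dataset An [ephys_dataset()].
#' @param params Analysis parameters; defaults to the dataset's own.
#' @return Object of class `paired_result`: tibble with one row per pair
#'   (`pair_id`, `condition`, `n_segments`, `mean_r2`, `peak_lag_ms`,
#'   `peak_r2`) and an `xcorr` list-column of lag-indexed correlation
#'   functions. Pairs without usable segments are reported with `NA`s.
#' @export
paired_dynamics <- function(dataset, params = NULL) {
  params <- params %||% dataset$params
  nt <- neuron_table(dataset)
  pids <- unique(nt$pair_id[!is.na(nt$pair_id)])
  out <- purrr::map_dfr(pids, function(pid) {
    ids <- nt$neuron_id[!is.na(nt$pair_id) & nt$pair_id == pid]
    if (length(ids) != 2) return(NULL)
    a <- dataset$neurons[[ids[1]]]
    b <- dataset$neurons[[ids[2]]]
    seg <- combined_event_segments(a, b, params)
    if (length(seg$segments) == 0) {
      return(tibble::tibble(pair_id = pid, condition = a$condition,
                            n_segments = 0L, mean_r2 = NA_real_,
                            peak_lag_ms = NA_real_, peak_r2 = NA_real_,
                            xcorr = list(NULL)))
    }
    r2 <- pairwise_r2(seg$segments)
    xc <- xcorr_lag(seg, params)
    tibble::tibble(pair_id = pid, condition = a$condition,
                   n_segments = length(seg$segments),
                   mean_r2 = r2$mean_r2,
                   peak_lag_ms = if (is.null(xc)) NA_real_ else xc$peak_lag_ms,
                   peak_r2 = if (is.null(xc)) NA_real_ else xc$peak_r2,
                   xcorr = list(if (is.null(xc)) NULL else xc$xcorr))
  })
  class(out) <- c("paired_result", class(out))
  out
}
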