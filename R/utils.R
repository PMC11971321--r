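# Shared internal helpers.
#
# Time convention used throughout: milliseconds, half-open windows
# [start, end); sample i (1-based R index) of a sweep sits at
# t0 + (i - 1) * 1000 / sample_rate ms.

ms_per_sample <- function(sample_rate) 1000 / sample_rate

#' @noRd
#' Indices of samples falling in the half-open window [start_ms, end_ms).
window_idx <- function(n, sample_rate, start_ms, end_ms, t0 = 0) {
  dt <- ms_per_sample(sample_rate)
  i0 <- ceiling((start_ms - t0) / dt - 1e-9) + 1L
  i1 <- ceiling((end_ms - t0) / dt - 1e-9)  # last index with t < end
  i0 <- max(1L, as.integer(i0))
  i1 <- min(n, as.integer(i1))
  if (i1 < i0) return(integer(0))
  seq.int(i0, i1)
}

sample_time <- function(i, sample_rate, t0 = 0) t0 + (i - 1) * ms_per_sample(sample_rate)

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' @noRd
#' Trapezoidal integral of y sampled at uniform spacing dt.
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
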