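# Replay quantification: similarity of mean evoked and mean spontaneous
# activity within and across training conditions. Evoked traces are
# onset-aligned at their first 5 mV threshold crossing (the same criterion
# the spontaneous event detector uses), so both contexts are locked to
# comparable phases of the network event; the shift is used for this
# correlation analysis only.

#' Align an evoked trace at its threshold crossing
#'
#' Shifts a baseline-subtracted evoked analysis-window trace so its first
#' crossing of `threshold_mV` sits at t = 0, padding the tail with the final
#' value. Traces that never cross are flagged (`NULL` return) and excluded
#' from replay correlation only.
#'
#' @param trace Evoked analysis-window trace (baseline-subtracted mV).
#' @param threshold_mV Crossing threshold above baseline (mV).
#' @return Aligned trace of equal length, or `NULL` when sub-threshold.
#' @export
align_evoked <- function(trace, threshold_mV = 5) {
  k <- which(trace > threshold_mV)
  if (length(k) == 0) return(NULL)
  k <- k[1]
  n <- length(trace)
  out <- c(trace[k:n], rep(trace[n], k - 1))
  attributes(out) <- attributes(trace)
  out
}

#' Mean activity trace of one neuron
#'
#' Pointwise mean across a neuron's usable traces on the common 1 s window
#' at the spontaneous-analysis rate. Evoked traces are aligned at the 5 mV
#' crossing and block-averaged down by `params$spont_downsample` so both
#' contexts live on the same time base; spontaneous windows enter
#' onset-locked, unaligned beyond onset.
#'
#' @param neuron A [neuron_record()].
#' @param context `"evoked"` or `"spontaneous"`.
#' @param params An [analysis_params()].
#' @return Mean trace (numeric, `sample_rate` attribute), or `NULL` when no
#'   usable trace exists.
#' @export
mean_activity <- function(neuron, context = c("evoked", "spontaneous"),
                          params = analysis_params()) {
  context <- match.arg(context)
  if (context == "evoked") {
    f <- params$spont_downsample
    traces <- neuron_evoked_windows(neuron, params)
    traces <- purrr::compact(purrr::map(traces, align_evoked,
                                        threshold_mV = params$spont_threshold_mV))
    traces <- purrr::map(traces, function(x) {
      m <- floor(length(x) / f)
      out <- colMeans(matrix(x[seq_len(m * f)], nrow = f))
      attr(out, "sample_rate") <- attr(x, "sample_rate") / f
      out
    })
  } else {
    traces <- neuron_spont_windows(neuron, params)
  }
  if (length(traces) == 0) return(NULL)
  len <- min(vapply(traces, length, integer(1)))
  m <- rowMeans(vapply(traces, function(x) x[seq_len(len)],
                       numeric(len)))
  attr(m, "sample_rate") <- attr(traces[[1]], "sample_rate")
  m
}

#' Evoked-by-spontaneous replay correlation matrices
#'
#' Computes the Pearson correlation between every (mean evoked trace of
#' neuron i, mean spontaneous trace of neuron j) combination, within each
#' training condition (intra; self-pairs i = j excluded) and across the two
#' conditions (inter). The summary compares the flattened intra and inter
#' correlation distributions per condition with a two-sided rank-sum test.
#'
#' @param dataset An [ephys_dataset()].
#' @param conditions Two conditions to compare.
#' @param params Analysis parameters; defaults to the dataset's own.
#' @return Object of class `replay_result`: list with `matrices` (named
#'   list of r matrices, rows = evoked neurons, cols = spontaneous
#'   neurons), `values` (tidy tibble of all r values with `comparison` and
#'   `type`), and `summary` (per-condition mean intra r, mean inter r,
#'   rank-sum U and p).
#' @export
replay_matrices <- function(dataset, conditions = c("early", "late"),
                            params = NULL) {
  params <- params %||% dataset$params
  abort_if(length(conditions) != 2, "replay_matrices: need two conditions")
  means <- list()
  for (cond in conditions) {
    recs <- Filter(function(n) n$condition == cond && is.null(n$pair_id),
                   dataset$neurons)
    ev <- purrr::compact(purrr::map(recs, mean_activity, context = "evoked",
                                    params = params))
    sp <- purrr::compact(purrr::map(recs, mean_activity,
                                    context = "spontaneous", params = params))
    abort_if(length(ev) < 2 || length(sp) < 2,
             paste0("replay_matrices: < 2 usable neurons in condition ", cond))
    means[[cond]] <- list(evoked = ev, spontaneous = sp)
  }

  corr_matrix <- function(ev, sp, drop_self = FALSE) {
    m <- matrix(NA_real_, length(ev), length(sp),
                dimnames = list(names(ev), names(sp)))
    for (i in seq_along(ev)) {
      for (j in seq_along(sp)) {
        if (drop_self && identical(names(ev)[i], names(sp)[j])) next
        len <- min(length(ev[[i]]), length(sp[[j]]))
        m[i, j] <- stats::cor(ev[[i]][seq_len(len)], sp[[j]][seq_len(len)])
      }
    }
    m
  }

  c1 <- conditions[1]; c2 <- conditions[2]
  mats <- list()
  mats[[paste0(c1, "_x_", c1)]] <-
    corr_matrix(means[[c1]]$evoked, means[[c1]]$spontaneous, TRUE)
  mats[[paste0(c2, "_x_", c2)]] <-
    corr_matrix(means[[c2]]$evoked, means[[c2]]$spontaneous, TRUE)
  mats[[paste0(c1, "_x_", c2)]] <-
    corr_matrix(means[[c1]]$evoked, means[[c2]]$spontaneous, FALSE)
  mats[[paste0(c2, "_x_", c1)]] <-
    corr_matrix(means[[c2]]$evoked, means[[c1]]$spontaneous, FALSE)

  values <- purrr::imap_dfr(mats, function(m, nm) {
    type <- if (substr(nm, 1, regexpr("_x_", nm) - 1) ==
                substr(nm, regexpr("_x_", nm) + 3, nchar(nm))) {
      "intra"
    } else {
      "inter"
    }
    v <- as.vector(m)
    tibble::tibble(comparison = nm, type = type, r = v[!is.na(v)])
  })

  summary <- purrr::map_dfr(conditions, function(cond) {
    intra <- values$r[values$comparison == paste0(cond, "_x_", cond)]
    other <- setdiff(conditions, cond)
    inter <- values$r[values$comparison == paste0(cond, "_x_", other)]
    gs <- group_stats(intra, inter)
    tibble::tibble(condition = cond, mean_intra_r = mean(intra),
                   mean_inter_r = mean(inter), n_intra = length(intra),
                   n_inter = length(inter), U = gs$U, p_ranksum = gs$p_u)
  })

  structure(list(matrices = mats, values = values, summary = summary,
                 conditions = conditions),
            class = "replay_result")
}

#' @export
print.replay_result <- function(x, ...) {
  cat("<replay_result> evoked x spontaneous Pearson correlations\n")
  print(x$summary)
  invisible(x)
}
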