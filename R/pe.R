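# Timed prediction-error classification: neurons whose response to the
# red-alone conditioned stimulus (CS) exceeds their response to red+blue
# (CSUS) carry an internally generated late response that the delivered
# blue light suppresses. The per-neuron statistic is the area under the
# signed mean CS - mean CSUS difference over the 1 s analysis window; the
# population threshold is mean + pe_sem_mult * SEM of that statistic over
# all classifiable neurons, with a strict inequality at the threshold.

#' Prediction-error statistic for one neuron
#'
#' Mean CS and CSUS analysis-window traces (identically preprocessed and
#' QC-screened) and the trapezoidal integral of their signed difference.
#'
#' @param neuron A [neuron_record()] with both CS and CSUS sweeps.
#' @param params An [analysis_params()].
#' @param min_sweeps Minimum QC-passing sweeps required per condition.
#' @return List `auc` (mV.ms), `mean_cs`, `mean_csus`, `diff_trace`,
#'   `n_cs`, `n_csus`; `NULL` when either condition is missing or
#'   under-replicated (the neuron is excluded from classification).
#' @export
pe_auc <- function(neuron, params = analysis_params(), min_sweeps = 3) {
  cs <- neuron_evoked_windows(neuron, params, kind = "evoked_cs")
  csus <- neuron_evoked_windows(neuron, params, kind = "evoked_csus")
  if (length(cs) < min_sweeps || length(csus) < min_sweeps) return(NULL)
  rate <- attr(cs[[1]], "sample_rate")
  len <- min(vapply(c(cs, csus), length, integer(1)))
  mean_cs <- rowMeans(vapply(cs, function(x) x[seq_len(len)], numeric(len)))
  mean_csus <- rowMeans(vapply(csus, function(x) x[seq_len(len)],
                               numeric(len)))
  d <- mean_cs - mean_csus
  list(auc = trapz(d, ms_per_sample(rate)),
       mean_cs = mean_cs, mean_csus = mean_csus, diff_trace = d,
       n_cs = length(cs), n_csus = length(csus), sample_rate = rate)
}

#' Classify timed prediction-error neurons
#'
#' Computes the CS - CSUS area statistic for every classifiable neuron in
#' the group and flags neurons whose statistic strictly exceeds
#' `mean + pe_sem_mult * SEM` of the group's statistics.
#'
#' @param neurons List of [neuron_record()]s (the analysis group over which
#'   mean and SEM are taken), or an [ephys_dataset()] whose Late
#'   opsin-negative neurons form the group.
#' @param params An [analysis_params()].
#' @param min_sweeps Minimum QC-passing sweeps per condition.
#' @return Object of class `pe_result`: tibble with one row per classified
#'   neuron (`neuron_id`, `auc`, `is_pe`, `n_cs`, `n_csus`) plus
#'   attributes `threshold`, `pe_fraction`, `n_classified` and a `traces`
#'   list-column holding the mean traces.
#' @export
#' @examples
#' cfg <- generator_config(seed = 2, n_neurons = 8, spont_duration_s = 0,
#'                         n_pairs = 0, n_probe_pairs = 0)
#' d <- simulate_dataset(cfg)
#' res <- classify_pe(d)
#' attr(res, "pe_fraction")
classify_pe <- function(neurons, params = NULL, min_sweeps = 3) {
  if (inherits(neurons, "ephys_dataset")) {
    params <- params %||% neurons$params
    neurons <- Filter(function(n) n$condition == "late" && n$opsin == "none",
                      neurons$neurons)
  }
  params <- params %||% analysis_params()
  stats_list <- purrr::compact(purrr::map(neurons, function(n) {
    a <- pe_auc(n, params, min_sweeps)
    if (is.null(a)) return(NULL)
    c(list(neuron_id = n$neuron_id), a)
  }))
  abort_if(length(stats_list) < 3,
           "classify_pe: need at least 3 classifiable neurons")
  aucs <- purrr::map_dbl(stats_list, "auc")
  threshold <- mean(aucs) + params$pe_sem_mult * sem(aucs)
  # strict inequality ("exceeded"); the epsilon keeps exact boundary ties,
  # which the rule does not flag, deterministic under floating point
  eps <- 1e-9 * max(1, abs(threshold))
  out <- tibble::tibble(
    neuron_id = purrr::map_chr(stats_list, "neuron_id"),
    auc = aucs,
    is_pe = aucs > threshold + eps,
    n_cs = purrr::map_int(stats_list, ~ as.integer(.x$n_cs)),
    n_csus = purrr::map_int(stats_list, ~ as.integer(.x$n_csus)),
    traces = purrr::map(stats_list,
                        ~ .x[c("mean_cs", "mean_csus", "diff_trace",
                               "sample_rate")]))
  attr(out, "threshold") <- threshold
  attr(out, "pe_fraction") <- mean(out$is_pe)
  attr(out, "n_classified") <- nrow(out)
  class(out) <- c("pe_result", class(out))
  out
}
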