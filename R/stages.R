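# Per-neuron glue between the low-level operations and the dataset-level
# stages: QC-screened evoked analysis windows and onset-locked spontaneous
# windows.

#' Preprocessed evoked analysis windows for one neuron
#'
#' Applies baseline QC ([qc_evoked_sweep()]) to every evoked sweep of the
#' requested kind and returns the surviving [evoked_window()] traces.
#'
#' @param neuron A [neuron_record()].
#' @param params An [analysis_params()].
#' @param kind `"evoked_cs"` or `"evoked_csus"`.
#' @return List of analysis-window traces (possibly empty).
#' @export
neuron_evoked_windows <- function(neuron, params = analysis_params(),
                                  kind = "evoked_cs") {
  sweeps <- Filter(function(s) s$kind == kind, neuron$sweeps)
  kept <- Filter(function(s) qc_evoked_sweep(s, params), sweeps)
  purrr::map(kept, evoked_window, params = params)
}

#' Onset-locked spontaneous analysis windows for one neuron
#'
#' Estimates the resting potential of each spontaneous sweep, detects
#' network events, and returns the down-sampled, baseline-subtracted
#' analysis windows in onset order.
#'
#' @inheritParams neuron_evoked_windows
#' @return List of analysis-window traces (possibly empty).
#' @export
neuron_spont_windows <- function(neuron, params = analysis_params()) {
  sweeps <- Filter(function(s) s$kind == "spontaneous", neuron$sweeps)
  purrr::flatten(purrr::map(sweeps, function(s) {
    resting <- estimate_resting(s)
    ev <- detect_spontaneous_events(s, resting, params)
    if (nrow(ev) == 0) return(list())
    spontaneous_windows(s, ev, params)
  }))
}

#' Detect spontaneous events across a whole dataset
#'
#' Runs resting-potential estimation and event detection on every
#' spontaneous sweep of every neuron.
#'
#' @param dataset An [ephys_dataset()].
#' @param params Analysis parameters; defaults to the dataset's own.
#' @return Tibble: `neuron_id`, `sweep`, `onset_ms`, `offset_ms`,
#'   `duration_ms` (exportable as the event CSV).
#' @export
detect_events <- function(dataset, params = NULL) {
  params <- params %||% dataset$params
  purrr::map_dfr(dataset$neurons, function(n) {
    purrr::imap_dfr(n$sweeps, function(s, i) {
      if (s$kind != "spontaneous") return(NULL)
      ev <- detect_spontaneous_events(s, estimate_resting(s), params)
      if (nrow(ev) == 0) return(NULL)
      tibble::tibble(neuron_id = n$neuron_id, sweep = i,
                     onset_ms = ev$onset_ms, offset_ms = ev$offset_ms,
                     duration_ms = ev$duration_ms)
    })
  })
}

#' Temporal features for every neuron in a dataset
#'
#' Per-neuron feature summaries ([feature_summary()]) for the evoked and/or
#' spontaneous context, as one tidy tibble.
#'
#' @param dataset An [ephys_dataset()].
#' @param context Character vector from `c("evoked", "spontaneous")`.
#' @param params Analysis parameters; defaults to the dataset's own.
#' @return Tibble with `neuron_id`, `condition`, `opsin`, `context`,
#'   the three feature columns, `n_traces`, and a `per_trace` list-column.
#'   Neurons with no usable traces in a context are omitted.
#' @export
temporal_features <- function(dataset,
                              context = c("evoked", "spontaneous"),
                              params = NULL) {
  params <- params %||% dataset$params
  context <- match.arg(context, several.ok = TRUE)
  purrr::map_dfr(dataset$neurons, function(n) {
    purrr::map_dfr(context, function(ctx) {
      traces <- if (ctx == "evoked") {
        neuron_evoked_windows(n, params)
      } else {
        neuron_spont_windows(n, params)
      }
      if (length(traces) == 0) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(neuron_id = n$neuron_id, condition = n$condition,
                       opsin = n$opsin, context = ctx),
        feature_summary(traces, params))
    })
  })
}
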