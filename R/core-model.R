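#' A single membrane-potential sweep
#'
#' One fixed-rate current-clamp voltage trace with stimulus annotations.
#' Evoked sweeps (`evoked_cs`, red alone; `evoked_csus`, red + blue) carry a
#' stimulus onset time and must contain at least 1 s of pre-stimulus baseline
#' and 1 s of post-stimulus data; spontaneous sweeps carry no stimulus onset.
#'
#' @param samples Numeric vector of membrane potential (mV).
#' @param sample_rate Sampling rate in Hz (recordings are sampled at 10 kHz).
#' @param t0 Time of the first sample on the sweep clock (ms).
#' @param stim_onset Time of the first red pulse (ms), or `NULL` for
#'   spontaneous sweeps.
#' @param kind One of `"evoked_cs"`, `"evoked_csus"`, `"spontaneous"`.
#'
#' @return An object of class `voltage_sweep`.
#' @export
#' @examples
#' sw <- voltage_sweep(rep(-65, 25000), stim_onset = 1000, kind = "evoked_cs")
#' sweep_duration_ms(sw)
voltage_sweep <- function(samples, sample_rate = 10000, t0 = 0,
                          stim_onset = NULL, kind = c("spontaneous",
                                                      "evoked_cs",
                                                      "evoked_csus")) {
  kind <- match.arg(kind)
  abort_if(!is.numeric(samples) || length(samples) == 0,
           "voltage_sweep: samples must be a non-empty numeric vector")
  abort_if(any(!is.finite(samples)), "voltage_sweep: samples must be finite")
  abort_if(!is.numeric(sample_rate) || sample_rate <= 0,
           "voltage_sweep: sample_rate must be positive")
  evoked <- kind != "spontaneous"
  abort_if(evoked && is.null(stim_onset),
           "voltage_sweep: evoked sweeps require stim_onset")
  abort_if(!evoked && !is.null(stim_onset),
           "voltage_sweep: spontaneous sweeps must not carry stim_onset")
  sw <- structure(list(samples = as.numeric(samples),
                       sample_rate = sample_rate,
                       t0 = t0,
                       stim_onset = if (evoked) as.numeric(stim_onset) else NULL,
                       kind = kind),
                  class = "voltage_sweep")
  if (evoked) {
    dur <- sweep_duration_ms(sw)
    pre <- stim_onset - t0
    post <- dur - pre
    abort_if(pre < 1000 - 1e-9,
             "voltage_sweep: evoked sweeps need >= 1000 ms pre-stimulus data")
    abort_if(post < 1000 - 1e-9,
             "voltage_sweep: evoked sweeps need >= 1000 ms post-stimulus data")
  }
  sw
}

#' @rdname voltage_sweep
#' @param sweep A `voltage_sweep`.
#' @export
sweep_duration_ms <- function(sweep) {
  length(sweep$samples) * ms_per_sample(sweep$sample_rate)
}

is_evoked <- function(sweep) sweep$kind != "spontaneous"

#' All sweeps and metadata for one recorded neuron
#'
#' @param neuron_id Unique identifier string.
#' @param condition Training condition: `"early"`, `"late"` or `"untrained"`.
#' @param opsin Opsin label: `"chr2"`, `"chrim"` or `"none"`.
#' @param sweeps List of [voltage_sweep()] objects sharing one sample rate.
#' @param pair_id Identifier linking simultaneously recorded neurons, or
#'   `NULL`. At most two neurons may share a `pair_id`.
#' @param is_pe Ground-truth prediction-error flag used by the synthetic
#'   generator (`NA` for recorded data).
#'
#' @return An object of class `neuron_record`.
#' @export
neuron_record <- function(neuron_id, condition = c("early", "late", "untrained"),
                          opsin = c("none", "chr2", "chrim"),
                          sweeps = list(), pair_id = NULL, is_pe = NA) {
  condition <- match.arg(condition)
  opsin <- match.arg(opsin)
  abort_if(!is.character(neuron_id) || length(neuron_id) != 1 ||
             !nzchar(neuron_id), "neuron_record: neuron_id must be a string")
  abort_if(!all(vapply(sweeps, inherits, logical(1), "voltage_sweep")),
           "neuron_record: sweeps must be voltage_sweep objects")
  if (length(sweeps) > 1) {
    rates <- vapply(sweeps, function(s) s$sample_rate, numeric(1))
    abort_if(length(unique(rates)) > 1,
             "neuron_record: all sweeps must share one sample_rate")
  }
  structure(list(neuron_id = neuron_id, condition = condition, opsin = opsin,
                 pair_id = pair_id, is_pe = is_pe, sweeps = sweeps),
            class = "neuron_record")
}

#' In-memory dataset container
#'
#' Holds every neuron record, paired connectivity probes, the stimulus
#' protocol, the analysis parameters, and free-form provenance metadata.
#' All downstream analysis stages consume this container, never raw files.
#'
#' @param neurons List of [neuron_record()] objects with unique ids.
#' @param probes List of connectivity probes (see [connectivity_probe()]).
#' @param protocol A [stimulus_protocol()].
#' @param params An [analysis_params()].
#' @param provenance Named list of free-form metadata (seed, generator
#'   version, source path, ...).
#'
#' @return An object of class `ephys_dataset`.
#' @export
ephys_dataset <- function(neurons, probes = list(),
                          protocol = stimulus_protocol(),
                          params = analysis_params(),
                          provenance = list()) {
  abort_if(!all(vapply(neurons, inherits, logical(1), "neuron_record")),
           "ephys_dataset: neurons must be neuron_record objects")
  ids <- vapply(neurons, function(n) n$neuron_id, character(1))
  abort_if(anyDuplicated(ids) > 0, "ephys_dataset: neuron_ids must be unique")
  names(neurons) <- ids
  structure(list(neurons = neurons, probes = probes, protocol = protocol,
                 params = params, provenance = provenance),
            class = "ephys_dataset")
}

#' @export
print.ephys_dataset <- function(x, ...) {
  nt <- neuron_table(x)
  cat("<ephys_dataset> ", nrow(nt), " neurons, ", length(x$probes),
      " connectivity probes\n", sep = "")
  if (nrow(nt)) print(dplyr::count(nt, .data$condition, .data$opsin))
  invisible(x)
}

#' Tabular views of a dataset
#'
#' `neuron_table()` returns one row per neuron; `sweep_table()` one row per
#' sweep. Both are tibbles suitable for dplyr pipelines.
#'
#' @param dataset An [ephys_dataset()].
#' @return A tibble.
#' @export
neuron_table <- function(dataset) {
  purrr::map_dfr(dataset$neurons, function(n) {
    tibble::tibble(neuron_id = n$neuron_id, condition = n$condition,
                   opsin = n$opsin,
                   pair_id = n$pair_id %||% NA_character_,
                   is_pe = n$is_pe,
                   n_sweeps = length(n$sweeps))
  })
}

#' @rdname neuron_table
#' @export
sweep_table <- function(dataset) {
  purrr::map_dfr(dataset$neurons, function(n) {
    purrr::imap_dfr(n$sweeps, function(s, i) {
      tibble::tibble(neuron_id = n$neuron_id, sweep = i, kind = s$kind,
                     sample_rate = s$sample_rate, t0 = s$t0,
                     stim_onset = s$stim_onset %||% NA_real_,
                     duration_ms = sweep_duration_ms(s))
    })
  })
}

#' Validate a dataset against its structural invariants
#'
#' Pure check: returns a tibble of findings (possibly empty) and never
#' throws. Severity `"error"` findings violate hard invariants; `"warning"`
#' findings flag departures from the study's stated recording practice
#' (short spontaneous records, the printed-vs-nominal red-train mismatch).
#'
#' @param dataset An [ephys_dataset()].
#' @return Tibble with columns `neuron_id`, `rule`, `severity`, `message`.
#' @export
#' @examples
#' d <- simulate_dataset(generator_config(seed = 1, n_neurons = 1,
#'                                        spont_duration_s = 10,
#'                                        n_pairs = 0, n_probe_pairs = 0))
#' validate_dataset(d)  # only the short-record warnings
validate_dataset <- function(dataset) {
  findings <- list()
  add <- function(neuron_id, rule, severity, message) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      neuron_id = neuron_id, rule = rule, severity = severity,
      message = message)
  }

  nominal <- protocol_nominal_red_ms(dataset$protocol)
  if (abs(nominal - dataset$protocol$red_train_ms) > 1e-9) {
    add(NA_character_, "red_train_nominal_mismatch", "warning",
        sprintf("stored red train %g ms vs %g ms implied by pulse arithmetic",
                dataset$protocol$red_train_ms, nominal))
  }

  ids <- vapply(dataset$neurons, function(n) n$neuron_id, character(1))
  if (anyDuplicated(ids)) {
    add(ids[duplicated(ids)][1], "duplicate_neuron_id", "error",
        "neuron ids must be unique")
  }

  pair_ids <- purrr::map_chr(dataset$neurons,
                             function(n) n$pair_id %||% NA_character_)
  tab <- table(pair_ids[!is.na(pair_ids)])
  for (pid in names(tab)[tab > 2]) {
    add(NA_character_, "pair_cardinality", "error",
        sprintf("pair_id '%s' shared by %d neurons (max 2)", pid, tab[[pid]]))
  }

  min_ms <- dataset$params$min_spont_record_min * 60 * 1000
  for (n in dataset$neurons) {
    for (i in seq_along(n$sweeps)) {
      s <- n$sweeps[[i]]
      if (length(s$samples) == 0) {
        add(n$neuron_id, "empty_sweep", "error",
            sprintf("sweep %d has no samples", i))
      }
    }
    spont_ms <- sum(vapply(n$sweeps, function(s)
      if (s$kind == "spontaneous") sweep_duration_ms(s) else 0, numeric(1)))
    has_spont <- any(vapply(n$sweeps, function(s) s$kind == "spontaneous",
                            logical(1)))
    if (has_spont && spont_ms < min_ms) {
      add(n$neuron_id, "short_spontaneous_record", "warning",
          sprintf("%.1f min of spontaneous data (< %g min)",
                  spont_ms / 60000, dataset$params$min_spont_record_min))
    }
  }
  if (length(findings) == 0) {
    return(tibble::tibble(neuron_id = character(), rule = character(),
                          severity = character(), message = character()))
  }
  dplyr::bind_rows(findings)
}
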