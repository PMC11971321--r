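#' Paired connectivity probe recording
#'
#' A set of paired current-clamp trials in which action potentials are driven
#' in a presynaptic neuron while the postsynaptic membrane potential is
#' recorded, used for monosynaptic connection calls.
#'
#' @param probe_id Unique identifier string.
#' @param pre_id,post_id Neuron ids of the pre- and postsynaptic cells.
#' @param direction Label such as `"chrim_to_none"` or `"none_to_chrim"`.
#' @param sample_rate Sampling rate (Hz) shared by all trial traces.
#' @param trials List of trials, each `list(pre = <numeric mV>,
#'   post = <numeric mV>)`.
#' @param truth Optional generator ground truth
#'   (`list(connected =, epsp_mV =)`); `NULL` for recorded data.
#'
#' @return An object of class `connectivity_probe`.
#' @export
connectivity_probe <- function(probe_id, pre_id, post_id, direction,
                               sample_rate = 10000, trials = list(),
                               truth = NULL) {
  abort_if(length(trials) == 0, "connectivity_probe: at least one trial")
  ok <- vapply(trials, function(tr) {
    is.list(tr) && is.numeric(tr$pre) && is.numeric(tr$post) &&
      length(tr$pre) == length(tr$post) && length(tr$pre) > 0
  }, logical(1))
  abort_if(!all(ok),
           "connectivity_probe: trials must be lists of equal-length pre/post traces")
  structure(list(probe_id = probe_id, pre_id = pre_id, post_id = post_id,
                 direction = direction, sample_rate = sample_rate,
                 trials = trials, truth = truth),
            class = "connectivity_probe")
}

# ---------------------------------------------------------------------------
# On-disk container: one directory holding a JSON metadata sidecar plus one
# CSV of sweep columns per neuron (and per probe). Values are written with
# full double precision, so read(write(d)) reproduces d exactly.

#' Write a dataset to a directory container
#'
#' The container is a directory holding `dataset.json` (all metadata:
#' protocol, analysis parameters, provenance, per-neuron and per-sweep
#' fields) plus `sweeps/<neuron_id>.csv` with one column per sweep (header
#' row = sweep ids, units mV) and `probes/<probe_id>.csv` with paired
#' `pre_k`/`post_k` columns. Two writes of the same dataset produce
#' byte-identical sidecars.
#'
#' @param dataset An [ephys_dataset()].
#' @param path Directory to create or overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  abort_if(!inherits(dataset, "ephys_dataset"),
           "write_dataset: not an ephys_dataset")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(path), paste0("write_dataset: cannot create ", path))
  dir.create(file.path(path, "sweeps"), showWarnings = FALSE)
  if (length(dataset$probes)) {
    dir.create(file.path(path, "probes"), showWarnings = FALSE)
  }

  meta <- list(
    format = "replaytrace-dataset",
    format_version = 1L,
    protocol = unclass(dataset$protocol),
    params = unclass(dataset$params),
    provenance = dataset$provenance,
    neurons = purrr::map(unname(dataset$neurons), function(n) {
      list(neuron_id = n$neuron_id, condition = n$condition, opsin = n$opsin,
           pair_id = n$pair_id, is_pe = n$is_pe,
           sweeps = purrr::imap(n$sweeps, function(s, i) {
             list(sweep_id = paste0("s", i), kind = s$kind,
                  sample_rate = s$sample_rate, t0 = s$t0,
                  stim_onset = s$stim_onset, n_samples = length(s$samples))
           }))
    }),
    probes = purrr::map(dataset$probes, function(p) {
      list(probe_id = p$probe_id, pre_id = p$pre_id, post_id = p$post_id,
           direction = p$direction, sample_rate = p$sample_rate,
           n_trials = length(p$trials),
           n_samples = length(p$trials[[1]]$pre), truth = p$truth)
    })
  )
  jsonlite::write_json(meta, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  for (n in dataset$neurons) {
    cols <- purrr::map(n$sweeps, "samples")
    names(cols) <- paste0("s", seq_along(cols))
    len <- max(vapply(cols, length, integer(1)))
    cols <- purrr::map(cols, function(x) c(x, rep(NA_real_, len - length(x))))
    readr::write_csv(tibble::as_tibble(cols),
                     file.path(path, "sweeps", paste0(n$neuron_id, ".csv")),
                     progress = FALSE)
  }
  for (p in dataset$probes) {
    cols <- list()
    for (i in seq_along(p$trials)) {
      cols[[paste0("pre_", i)]] <- p$trials[[i]]$pre
      cols[[paste0("post_", i)]] <- p$trials[[i]]$post
    }
    readr::write_csv(tibble::as_tibble(cols),
                     file.path(path, "probes", paste0(p$probe_id, ".csv")),
                     progress = FALSE)
  }
  invisible(path)
}

#' Read a dataset container from disk
#'
#' Inverse of [write_dataset()]. The returned dataset is validated; a
#' missing sidecar is a format error and a sweep whose stored length
#' disagrees with its CSV column is a validation error naming the sweep.
#'
#' @param path Container directory.
#' @return An [ephys_dataset()].
#' @export
read_dataset <- function(path) {
  sidecar <- file.path(path, "dataset.json")
  abort_if(!dir.exists(path), paste0("read_dataset: no such directory: ", path))
  abort_if(!file.exists(sidecar),
           paste0("read_dataset: missing metadata sidecar dataset.json in ", path))
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  abort_if(!identical(meta$format, "replaytrace-dataset"),
           "read_dataset: not a replaytrace dataset container")

  neurons <- purrr::map(meta$neurons, function(nm) {
    f <- file.path(path, "sweeps", paste0(nm$neuron_id, ".csv"))
    abort_if(!file.exists(f),
             paste0("read_dataset: missing sweep file for neuron ", nm$neuron_id))
    mat <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    sweeps <- purrr::imap(nm$sweeps, function(sm, i) {
      col <- mat[[sm$sweep_id]]
      abort_if(is.null(col),
               sprintf("read_dataset: neuron %s sweep %s absent from CSV",
                       nm$neuron_id, sm$sweep_id))
      x <- col[!is.na(col)]
      abort_if(length(x) != sm$n_samples,
               sprintf("read_dataset: neuron %s sweep %s has %d samples, sidecar says %d",
                       nm$neuron_id, sm$sweep_id, length(x), sm$n_samples))
      voltage_sweep(x, sample_rate = sm$sample_rate, t0 = sm$t0,
                    stim_onset = sm$stim_onset, kind = sm$kind)
    })
    neuron_record(nm$neuron_id, condition = nm$condition, opsin = nm$opsin,
                  sweeps = sweeps, pair_id = nm$pair_id,
                  is_pe = nm$is_pe %||% NA)
  })

  probes <- purrr::map(meta$probes, function(pm) {
    f <- file.path(path, "probes", paste0(pm$probe_id, ".csv"))
    abort_if(!file.exists(f),
             paste0("read_dataset: missing probe file ", pm$probe_id))
    mat <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    trials <- purrr::map(seq_len(pm$n_trials), function(i) {
      list(pre = mat[[paste0("pre_", i)]], post = mat[[paste0("post_", i)]])
    })
    truth <- pm$truth
    connectivity_probe(pm$probe_id, pm$pre_id, pm$post_id, pm$direction,
                       sample_rate = pm$sample_rate, trials = trials,
                       truth = truth)
  })

  ephys_dataset(neurons, probes = probes,
                protocol = do.call(stimulus_protocol, meta$protocol),
                params = do.call(analysis_params, meta$params),
                provenance = meta$provenance)
}
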