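# broom-style tidiers for the fitted/derived result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prediction-error classification
#'
#' @param x A `pe_result` from [classify_pe()].
#' @param ... Unused.
#' @return Tibble with one row per classified neuron: `neuron_id`, `auc`,
#'   `threshold`, `is_pe`.
#' @method tidy pe_result
#' @export
tidy.pe_result <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron_id, auc = x$auc,
                 threshold = attr(x, "threshold"), is_pe = x$is_pe)
}

#' @rdname tidy.pe_result
#' @return For `glance()`: one row with `n_classified`, `n_pe`,
#'   `pe_fraction`, `threshold`.
#' @method glance pe_result
#' @export
glance.pe_result <- function(x, ...) {
  tibble::tibble(n_classified = attr(x, "n_classified"),
                 n_pe = sum(x$is_pe),
                 pe_fraction = attr(x, "pe_fraction"),
                 threshold = attr(x, "threshold"))
}

#' Tidy a replay correlation result
#'
#' @param x A `replay_result` from [replay_matrices()].
#' @param ... Unused.
#' @return Tibble of all correlation values: `comparison`, `type`
#'   (intra/inter), `r`.
#' @method tidy replay_result
#' @export
tidy.replay_result <- function(x, ...) x$values

#' @rdname tidy.replay_result
#' @return For `glance()`: the per-condition summary tibble.
#' @method glance replay_result
#' @export
glance.replay_result <- function(x, ...) x$summary

#' Tidy paired-dynamics results
#'
#' @param x A `paired_result` from [paired_dynamics()].
#' @param ... Unused.
#' @return Tibble without the cross-correlation list-column.
#' @method tidy paired_result
#' @export
tidy.paired_result <- function(x, ...) {
  tibble::as_tibble(x[, setdiff(names(x), "xcorr")])
}

#' @rdname tidy.paired_result
#' @method glance paired_result
#' @export
glance.paired_result <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_r2 = mean(.data$mean_r2, na.rm = TRUE),
                     sem_r2 = sem(.data$mean_r2),
                     mean_peak_lag_ms = mean(.data$peak_lag_ms, na.rm = TRUE),
                     sem_peak_lag_ms = sem(.data$peak_lag_ms),
                     mean_peak_r2 = mean(.data$peak_r2, na.rm = TRUE),
                     n_pairs = dplyr::n(), .groups = "drop")
}
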