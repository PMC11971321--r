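# ggplot2 views of the result objects. All plots return the ggplot object
# so callers can restyle them.

#' Plot group-mean traces with SEM ribbons
#'
#' Mean +/- SEM of evoked or spontaneous analysis windows per training
#' condition, mirroring the group-average trace panels of the study.
#'
#' @param dataset An [ephys_dataset()].
#' @param context `"evoked"` or `"spontaneous"`.
#' @param params Analysis parameters; defaults to the dataset's own.
#' @return A ggplot.
#' @export
plot_mean_traces <- function(dataset, context = c("evoked", "spontaneous"),
                             params = NULL) {
  context <- match.arg(context)
  params <- params %||% dataset$params
  nt <- neuron_table(dataset)
  ids <- nt$neuron_id[is.na(nt$pair_id)]
  df <- purrr::map_dfr(ids, function(id) {
    n <- dataset$neurons[[id]]
    m <- mean_activity(n, context, params)
    if (is.null(m)) return(NULL)
    tibble::tibble(neuron_id = id, condition = n$condition,
                   t_ms = (seq_along(m) - 1) *
                     ms_per_sample(attr(m, "sample_rate")),
                   v_mV = as.numeric(m))
  })
  df <- df |>
    dplyr::group_by(.data$condition, .data$t_ms) |>
    dplyr::summarise(mean = mean(.data$v_mV), sem = sem(.data$v_mV),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$mean,
                                   color = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from onset (ms)",
                  y = "membrane potential above baseline (mV)",
                  title = paste("group mean", context, "activity")) +
    ggplot2::theme_minimal()
}

#' Heatmaps of the replay correlation matrices
#' @param object A result object.
#' @param ... Unused.
#' @method autoplot replay_result
#' @export
autoplot.replay_result <- function(object, ...) {
  df <- purrr::imap_dfr(object$matrices, function(m, nm) {
    tibble::tibble(comparison = nm,
                   evoked = rep(rownames(m), ncol(m)),
                   spontaneous = rep(colnames(m), each = nrow(m)),
                   r = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$spontaneous, .data$evoked,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~comparison, scales = "free") +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank()) +
    ggplot2::labs(title = "mean evoked x mean spontaneous correlation")
}

#' Cross-correlation functions per pair
#' @param object A result object.
#' @param ... Unused.
#' @method autoplot paired_result
#' @export
autoplot.paired_result <- function(object, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    f <- object$xcorr[[i]]
    if (is.null(f)) return(NULL)
    dplyr::mutate(f, pair_id = object$pair_id[i],
                  condition = object$condition[i])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_ms, .data$r,
                                   group = .data$pair_id,
                                   color = .data$condition)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "lag (ms)", y = "cross-correlation",
                  title = "spontaneous-event cross-correlation by pair") +
    ggplot2::theme_minimal()
}

#' Prediction-error statistic per neuron with the population threshold
#' @param object A result object.
#' @param ... Unused.
#' @method autoplot pe_result
#' @export
autoplot.pe_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "neurons", y = .data$auc,
                                   color = .data$is_pe)) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "CS - CSUS area (mV*ms)",
                  title = "timed prediction-error classification") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
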