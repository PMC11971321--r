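# Pipeline orchestration: run every analysis stage on a dataset, compute
# the group-level statistics the study reports, and write CSV/JSON outputs.

#' Two-group comparison statistics
#'
#' Two-sided Mann-Whitney U (midranks for ties; exact p when both samples
#' have n < 20 and no ties, normal approximation with continuity correction
#' otherwise) and the two-sample Kolmogorov-Smirnov statistic, plus sample
#' medians, means and SEMs. Delegated to [stats::wilcox.test()] and
#' [stats::ks.test()].
#'
#' @param a,b Numeric samples (non-empty).
#' @return List: `U` (for the first sample), `p_u`, `u_method`, `ks`,
#'   `p_ks`, `median_a`, `median_b`, `mean_a`, `mean_b`, `sem_a`, `sem_b`,
#'   `n_a`, `n_b`, `reliable` (`FALSE` when either n < 2).
#' @export
#' @examples
#' group_stats(c(1, 2, 3), c(4, 5, 6))$U  # fully separated ranks: 0
group_stats <- function(a, b) {
  abort_if(length(a) == 0 || length(b) == 0,
           "group_stats: both samples must be non-empty")
  a <- as.numeric(a); b <- as.numeric(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- max(length(a), length(b)) < 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(U = unname(wt$statistic), p_u = wt$p.value,
       u_method = if (exact) "exact" else "normal_approx",
       ks = unname(ks$statistic), p_ks = ks$p.value,
       median_a = stats::median(a), median_b = stats::median(b),
       mean_a = mean(a), mean_b = mean(b),
       sem_a = sem(a), sem_b = sem(b),
       n_a = length(a), n_b = length(b),
       reliable = length(a) >= 2 && length(b) >= 2)
}

#' Alias for [simulate_dataset()]
#' @inheritParams simulate_dataset
#' @export
generate_dataset <- function(cfg = generator_config()) simulate_dataset(cfg)

pipeline_stages <- c("detect", "features", "replay", "paired", "pe",
                     "connectivity")

# Feature-table group comparison: Early vs Late per context and feature.
feature_group_stats <- function(features) {
  grid <- tidyr::expand_grid(
    context = unique(features$context),
    feature = c("median_event_time_ms", "median_peak_time_ms",
                "mean_cog_ms"))
  purrr::pmap_dfr(grid, function(context, feature) {
    e <- features[features$context == context &
                    features$condition == "early", ][[feature]]
    l <- features[features$context == context &
                    features$condition == "late", ][[feature]]
    e <- e[!is.na(e)]; l <- l[!is.na(l)]
    if (length(e) == 0 || length(l) == 0) return(NULL)
    gs <- group_stats(e, l)
    tibble::tibble(context = context, feature = feature,
                   mean_early = gs$mean_a, sem_early = gs$sem_a,
                   mean_late = gs$mean_b, sem_late = gs$sem_b,
                   median_early = gs$median_a, median_late = gs$median_b,
                   n_early = gs$n_a, n_late = gs$n_b,
                   U = gs$U, p_u = gs$p_u, ks = gs$ks, p_ks = gs$p_ks)
  })
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes the requested stages in dependency order: spontaneous event
#' detection, temporal features (evoked and spontaneous), peak-time CDFs
#' with Early-vs-Late group statistics, replay correlation, paired
#' dynamics, prediction-error classification, and connectivity. Stages
#' whose inputs are absent from the dataset (no pairs, no probes, no CSUS
#' sweeps) are skipped with a logged reason. The result is deterministic
#' for a fixed dataset and parameters.
#'
#' @param dataset An [ephys_dataset()], or a [generator_config()] to
#'   simulate first.
#' @param stages Character vector of stages to run (default all):
#'   `"detect"`, `"features"`, `"replay"`, `"paired"`, `"pe"`,
#'   `"connectivity"`. Dependencies are enforced before any computation:
#'   features require detection; replay requires features.
#' @param params Optional [analysis_params()] override.
#' @return Object of class `pipeline_result`: list with one element per
#'   completed stage (`events`, `features`, `feature_stats`, `cdf`,
#'   `replay`, `paired`, `pe`, `connectivity`), plus `skipped` (named
#'   reasons) and `summary` (nested list mirroring the group-level
#'   numbers).
#' @export
run_pipeline <- function(dataset, stages = pipeline_stages, params = NULL) {
  if (inherits(dataset, "generator_config")) {
    dataset <- simulate_dataset(dataset)
  }
  abort_if(!inherits(dataset, "ephys_dataset"),
           "run_pipeline: need an ephys_dataset or generator_config")
  bad <- setdiff(stages, pipeline_stages)
  abort_if(length(bad) > 0,
           paste0("run_pipeline: unknown stages: ", paste(bad, collapse = ", ")))
  abort_if("features" %in% stages && !"detect" %in% stages,
           "run_pipeline: stage 'features' requires 'detect'")
  abort_if("replay" %in% stages && !"features" %in% stages,
           "run_pipeline: stage 'replay' requires 'features'")
  params <- params %||% dataset$params

  res <- list(skipped = list())
  nt <- neuron_table(dataset)
  unpaired <- nt$neuron_id[is.na(nt$pair_id)]

  if ("detect" %in% stages) {
    res$events <- detect_events(dataset, params)
  }

  if ("features" %in% stages) {
    sub <- dataset
    sub$neurons <- dataset$neurons[unpaired]
    res$features <- temporal_features(sub, params = params)
    res$feature_stats <- feature_group_stats(res$features)
    res$cdf <- purrr::compact(purrr::map(
      c(evoked = "evoked", spontaneous = "spontaneous"),
      function(ctx) {
        groups <- purrr::map(c(early = "early", late = "late"), function(cond) {
          recs <- Filter(function(n) n$condition == cond,
                         sub$neurons)
          traces <- purrr::map(recs, function(n) {
            if (ctx == "evoked") neuron_evoked_windows(n, params)
            else neuron_spont_windows(n, params)
          })
          Filter(function(tr) length(tr) > 0, traces)
        })
        if (any(lengths(groups) == 0)) return(NULL)
        peak_time_cdf(groups, params)
      }))
  }

  if ("replay" %in% stages) {
    have <- nt$condition[nt$neuron_id %in% unpaired]
    if (sum(have == "early") >= 2 && sum(have == "late") >= 2) {
      sub <- dataset
      sub$neurons <- dataset$neurons[unpaired]
      res$replay <- replay_matrices(sub, c("early", "late"), params)
    } else {
      res$skipped$replay <- "fewer than 2 early or late neurons"
    }
  }

  if ("paired" %in% stages) {
    if (any(!is.na(nt$pair_id))) {
      res$paired <- paired_dynamics(dataset, params)
    } else {
      res$skipped$paired <- "dataset has no paired recordings"
    }
  }

  if ("pe" %in% stages) {
    n_csus <- sum(sweep_table(dataset)$kind == "evoked_csus")
    if (n_csus > 0) {
      res$pe <- tryCatch(classify_pe(dataset, params),
                         error = function(e) NULL)
      if (is.null(res$pe)) {
        res$skipped$pe <- "fewer than 3 classifiable neurons"
      }
    } else {
      res$skipped$pe <- "dataset has no red+blue (CSUS) sweeps"
    }
  }

  if ("connectivity" %in% stages) {
    if (length(dataset$probes) > 0) {
      res$connectivity <- connectivity_calls(dataset, params)
      res$connectivity_summary <- direction_summary(res$connectivity)
    } else {
      res$skipped$connectivity <- "dataset has no connectivity probes"
    }
  }

  res$summary <- pipeline_summary(res)
  structure(res, class = "pipeline_result")
}

# Nested, JSON-ready summary of the group-level numbers.
pipeline_summary <- function(res) {
  s <- list()
  if (!is.null(res$feature_stats) && nrow(res$feature_stats)) {
    s$features <- purrr::map(seq_len(nrow(res$feature_stats)), function(i) {
      as.list(res$feature_stats[i, ])
    })
  }
  if (!is.null(res$cdf)) {
    s$peak_time_ks <- purrr::imap(res$cdf, function(x, ctx) {
      list(ks = x$ks_stat, p = x$ks_p)
    })
  }
  if (!is.null(res$replay)) {
    s$replay <- purrr::map(seq_len(nrow(res$replay$summary)), function(i) {
      as.list(res$replay$summary[i, ])
    })
  }
  if (!is.null(res$paired) && nrow(res$paired)) {
    by_cond <- res$paired |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(mean_r2 = mean(.data$mean_r2, na.rm = TRUE),
                       mean_peak_lag_ms = mean(.data$peak_lag_ms,
                                               na.rm = TRUE),
                       mean_peak_r2 = mean(.data$peak_r2, na.rm = TRUE),
                       n_pairs = dplyr::n(), .groups = "drop")
    s$paired <- purrr::map(seq_len(nrow(by_cond)),
                           function(i) as.list(by_cond[i, ]))
  }
  if (!is.null(res$pe)) {
    s$prediction_error <- list(
      n_classified = attr(res$pe, "n_classified"),
      n_pe = sum(res$pe$is_pe),
      pe_fraction = attr(res$pe, "pe_fraction"),
      threshold_mV_ms = attr(res$pe, "threshold"))
  }
  if (!is.null(res$connectivity_summary)) {
    bd <- res$connectivity_summary$by_direction
    s$connectivity <- list(
      by_direction = purrr::map(seq_len(nrow(bd)),
                                function(i) as.list(bd[i, ])),
      amplitude_t_p = res$connectivity_summary$amplitude_t_p,
      probability_p = res$connectivity_summary$probability_p)
  }
  if (length(res$skipped)) s$skipped <- res$skipped
  s
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  done <- intersect(c("events", "features", "replay", "paired", "pe",
                      "connectivity"), names(x))
  cat("  stages completed:", paste(done, collapse = ", "), "\n")
  if (length(x$skipped)) {
    for (nm in names(x$skipped)) {
      cat("  skipped ", nm, ": ", x$skipped[[nm]], "\n", sep = "")
    }
  }
  if (!is.null(x$feature_stats) && nrow(x$feature_stats)) {
    cat("  Early vs Late feature comparisons:\n")
    print(x$feature_stats[, c("context", "feature", "mean_early",
                              "mean_late", "U", "p_u")])
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' One CSV per tabular stage (events, features, replay values, paired
#' results, prediction-error table, connectivity calls, cross-correlation
#' functions) and `summary.json` with the group-level numbers. Writing the
#' same result twice produces byte-identical files.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name, drop = character(0)) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    df <- df[, setdiff(names(df), drop), drop = FALSE]
    readr::write_csv(df, file.path(dir, name), progress = FALSE)
  }
  w(result$events, "events.csv")
  w(result$features, "features.csv", drop = "per_trace")
  w(result$feature_stats, "feature_stats.csv")
  if (!is.null(result$replay)) {
    w(result$replay$values, "replay_values.csv")
    w(result$replay$summary, "replay_summary.csv")
  }
  if (!is.null(result$paired)) {
    w(as.data.frame(result$paired[, setdiff(names(result$paired), "xcorr")]),
      "paired.csv")
    xc <- purrr::map_dfr(seq_len(nrow(result$paired)), function(i) {
      f <- result$paired$xcorr[[i]]
      if (is.null(f)) return(NULL)
      dplyr::mutate(f, pair_id = result$paired$pair_id[i], .before = 1)
    })
    w(xc, "xcorr_functions.csv")
  }
  if (!is.null(result$pe)) {
    pe <- as.data.frame(result$pe[, setdiff(names(result$pe), "traces")])
    pe$threshold <- attr(result$pe, "threshold")
    w(pe, "prediction_error.csv")
  }
  w(result$connectivity, "connectivity_calls.csv")
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
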