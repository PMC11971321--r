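#' Analysis parameters
#'
#' All numeric constants used by the analysis stages, with the values used by
#' the original study where the study states them. Units are milliseconds,
#' millivolts, or counts as indicated by the suffix.
#'
#' @param spont_threshold_mV Voltage threshold above resting potential for
#'   spontaneous network-event detection (mV).
#' @param min_event_ms Minimum duration an event must remain above threshold,
#'   internal dips included (ms).
#' @param max_dip_ms Sub-threshold dips shorter than this are merged into the
#'   surrounding event (ms). Strictly less-than comparison.
#' @param baseline_ms Baseline window preceding an event onset (ms).
#' @param window_ms Analysis window following an event onset or stimulus
#'   onset (ms).
#' @param smooth_ms Moving-average smoothing window (ms).
#' @param median_window_ms Sliding-median spike-filter window (ms). The
#'   study never defines its spike filter; a 5 ms median removes 1-3 ms
#'   action potentials while preserving 100-ms-scale envelopes.
#' @param slope_window_ms Sliding window for voltage-slope computation (ms).
#' @param slope_sd_mult Slope threshold in units of the within-trace slope SD.
#' @param spont_downsample Down-sampling factor for spontaneous event
#'   analysis.
#' @param paired_downsample Down-sampling factor for paired (two-neuron)
#'   analysis.
#' @param paired_segment_ms Paired-analysis segment length, baseline
#'   included (ms).
#' @param xcorr_trim_ms Trim applied after onset and before offset when
#'   cross-correlating paired segments (ms).
#' @param xcorr_max_lag_ms Cross-correlation lag search half-range (ms).
#' @param pe_sem_mult Prediction-error threshold in units of the
#'   population SEM.
#' @param conn_sd_mult Connection call threshold in units of the baseline SD.
#' @param conn_min_trials Trials below which a connection call is flagged
#'   low-confidence.
#' @param cdf_n_sweeps Traces per neuron entering peak-time cumulative
#'   distributions.
#' @param min_spont_record_min Minimum spontaneous record length (minutes);
#'   shorter records raise a validation warning, not an error.
#' @param epsp_baseline_from_ms,epsp_baseline_to_ms EPSP baseline window
#'   relative to the presynaptic action-potential peak (ms; half-open).
#' @param epsp_search_from_ms,epsp_search_to_ms EPSP peak search window
#'   relative to the presynaptic action-potential peak (ms; half-open).
#' @param ap_threshold_mV Absolute voltage whose upward crossing marks a
#'   presynaptic action potential (mV).
#'
#' @return A list of class `analysis_params`.
#' @export
#' @examples
#' p <- analysis_params()
#' p$spont_threshold_mV
analysis_params <- function(spont_threshold_mV = 5,
                            min_event_ms = 100,
                            max_dip_ms = 25,
                            baseline_ms = 100,
                            window_ms = 1000,
                            smooth_ms = 10,
                            median_window_ms = 5,
                            slope_window_ms = 10,
                            slope_sd_mult = 3,
                            spont_downsample = 10,
                            paired_downsample = 50,
                            paired_segment_ms = 1100,
                            xcorr_trim_ms = 50,
                            xcorr_max_lag_ms = 500,
                            pe_sem_mult = 3,
                            conn_sd_mult = 3,
                            conn_min_trials = 5,
                            cdf_n_sweeps = 5,
                            min_spont_record_min = 5,
                            epsp_baseline_from_ms = -50,
                            epsp_baseline_to_ms = -2,
                            epsp_search_from_ms = 1.5,
                            epsp_search_to_ms = 15,
                            ap_threshold_mV = 0) {
  p <- as.list(environment())
  pos <- c("spont_threshold_mV", "min_event_ms", "max_dip_ms", "baseline_ms",
           "window_ms", "smooth_ms", "median_window_ms", "slope_window_ms",
           "slope_sd_mult", "spont_downsample", "paired_downsample",
           "paired_segment_ms", "xcorr_trim_ms", "xcorr_max_lag_ms",
           "pe_sem_mult", "conn_sd_mult", "conn_min_trials", "cdf_n_sweeps",
           "min_spont_record_min")
  for (nm in pos) {
    abort_if(!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0,
             paste0("analysis_params: `", nm, "` must be a positive scalar"))
  }
  abort_if(p$max_dip_ms >= p$min_event_ms,
           "analysis_params: max_dip_ms must be < min_event_ms")
  abort_if(p$window_ms < p$min_event_ms,
           "analysis_params: window_ms must be >= min_event_ms")
  structure(p, class = "analysis_params")
}

#' Optogenetic training protocol constants
#'
#' Pulse-train structure of the red (conditioned) and blue (unconditioned)
#' light stimuli and the two trained interstimulus intervals. The stored red
#' train duration is the printed 440 ms even though the pulse arithmetic
#' ((12 - 1) / 25 Hz + 5 ms = 445 ms) disagrees by 5 ms; [validate_dataset()]
#' warns about the discrepancy but does not fail.
#'
#' @param red_n_pulses,red_pulse_ms,red_rate_hz,red_train_ms Red (625 nm)
#'   train: pulse count, pulse width (ms), rate (Hz), train duration (ms).
#' @param blue_n_pulses,blue_pulse_ms,blue_rate_hz,blue_train_ms Blue
#'   (455 nm) train: same fields.
#' @param isi_ms Interval between red-train onset and blue-train onset (ms);
#'   10 for the Early condition, 370 for the Late condition. Arbitrary values
#'   are allowed for simulation.
#' @param iti_s Inter-trial interval during training (s).
#'
#' @return A list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(red_n_pulses = 12, red_pulse_ms = 5,
                              red_rate_hz = 25, red_train_ms = 440,
                              blue_n_pulses = 5, blue_pulse_ms = 5,
                              blue_rate_hz = 50, blue_train_ms = 80,
                              isi_ms = 370, iti_s = 20) {
  p <- as.list(environment())
  for (nm in names(p)) {
    abort_if(!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0,
             paste0("stimulus_protocol: `", nm, "` must be a positive scalar"))
  }
  structure(p, class = "stimulus_protocol")
}

# Nominal red-train envelope implied by pulse arithmetic; used by the
# validator to warn when it disagrees with the stored train duration.
protocol_nominal_red_ms <- function(p) {
  (p$red_n_pulses - 1) / p$red_rate_hz * 1000 + p$red_pulse_ms
}
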