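#' Simulation configuration for a synthetic FES-therapy cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator.
#' Defaults emulate the study conditions: 17 participants with cervical SCI,
#' 4--10 target muscles each, one 1-min rest trial plus three 5-s maximal
#' voluntary contraction (MVC) trials per muscle recorded at 4 kHz,
#' ~30 therapy sessions of manual muscle testing (MMT) per muscle, ~33%
#' responder prevalence and an AIS grade distribution of A/B/C/D = 2/5/2/8
#' out of 17.
#'
#' @param n_participants number of participants.
#' @param muscles_min,muscles_max range of target muscles per participant.
#' @param mvc_trials number of MVC trials per muscle (3 by default; set 4 to
#'   emulate muscles with a fourth attempt).
#' @param fs sampling rate, Hz.
#' @param mvc_duration MVC trial duration, s.
#' @param rest_duration rest trial duration, s.
#' @param n_sessions number of therapy sessions with an MMT score.
#' @param responder_prevalence expected proportion of responder muscles.
#' @param ais_distribution named proportions over AIS grades A--D; must sum
#'   to 1.
#' @param effect_medf_shift planted upward shift of the responder MVC
#'   spectral centre, Hz.
#' @param effect_amp_gain planted responder MVC amplitude ratio (>= 1 means
#'   responders contract with proportionally larger sEMG amplitude).
#' @param spectral_center_base mean MVC spectral centre for non-responders,
#'   Hz.
#' @param spectral_center_sd between-muscle SD of the spectral centre, Hz.
#' @param mvc_bandwidth width of the band-shaped MVC spectrum, Hz.
#' @param mvc_amp_base baseline MVC amplitude (RMS of the muscle component
#'   at strength 0), mV.
#' @param mvc_amp_per_grade additional MVC amplitude per baseline MMT grade,
#'   mV.
#' @param line_noise_amp amplitude of the 60 Hz mains component, mV.
#' @param sensor_noise_sd SD of additive white sensor noise, mV.
#' @param jitter_prob probability of a +/-1 MMT fluctuation at any session.
#' @param responder_gain MMT grades a responder gains over the therapy
#'   cycle (before the ceiling at 5).
#' @param seed integer seed fixing all randomness end-to-end.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 17,
                       muscles_min = 4, muscles_max = 10,
                       mvc_trials = 3,
                       fs = 4000,
                       mvc_duration = 5,
                       rest_duration = 60,
                       n_sessions = 30,
                       responder_prevalence = 0.33,
                       ais_distribution = c(A = 2, B = 5, C = 2, D = 8) / 17,
                       effect_medf_shift = 30,
                       effect_amp_gain = 1.5,
                       spectral_center_base = 100,
                       spectral_center_sd = 10,
                       mvc_bandwidth = 120,
                       mvc_amp_base = 0.05,
                       mvc_amp_per_grade = 0.05,
                       line_noise_amp = 0.02,
                       sensor_noise_sd = 0.01,
                       jitter_prob = 0.1,
                       responder_gain = 2,
                       seed = 1L) {
  cfg <- list(
    n_participants = n_participants, muscles_min = muscles_min,
    muscles_max = muscles_max, mvc_trials = mvc_trials, fs = fs,
    mvc_duration = mvc_duration, rest_duration = rest_duration,
    n_sessions = n_sessions, responder_prevalence = responder_prevalence,
    ais_distribution = ais_distribution,
    effect_medf_shift = effect_medf_shift,
    effect_amp_gain = effect_amp_gain,
    spectral_center_base = spectral_center_base,
    spectral_center_sd = spectral_center_sd,
    mvc_bandwidth = mvc_bandwidth,
    mvc_amp_base = mvc_amp_base,
    mvc_amp_per_grade = mvc_amp_per_grade,
    line_noise_amp = line_noise_amp,
    sensor_noise_sd = sensor_noise_sd,
    jitter_prob = jitter_prob, responder_gain = responder_gain,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1,
    cfg$muscles_min >= 1, cfg$muscles_max >= cfg$muscles_min,
    cfg$mvc_trials >= 1,
    cfg$fs > 0, cfg$mvc_duration > 0, cfg$rest_duration > 0,
    cfg$n_sessions >= 2
  )
  if (cfg$responder_prevalence < 0 || cfg$responder_prevalence > 1)
    stop("responder_prevalence must lie in [0, 1]")
  if (cfg$jitter_prob < 0 || cfg$jitter_prob > 1)
    stop("jitter_prob must lie in [0, 1]")
  ais <- cfg$ais_distribution
  if (!setequal(names(ais), c("A", "B", "C", "D")))
    stop("ais_distribution must be named over grades A, B, C, D")
  if (any(ais < 0) || abs(sum(ais) - 1) > 1e-8)
    stop("ais_distribution entries must be non-negative and sum to 1")
  if (cfg$sensor_noise_sd < 0 || cfg$line_noise_amp < 0)
    stop("noise amplitudes must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d (AIS %s)\n", x$n_participants,
              paste(sprintf("%s=%.2f", names(x$ais_distribution),
                            x$ais_distribution), collapse = " ")))
  cat(sprintf("  muscles/participant: %d-%d; %d MVC trial(s) of %gs + %gs rest @ %g Hz\n",
              x$muscles_min, x$muscles_max, x$mvc_trials,
              x$mvc_duration, x$rest_duration, x$fs))
  cat(sprintf("  sessions: %d; responder prevalence %.2f; planted effects: +%g Hz, x%g amplitude\n",
              x$n_sessions, x$responder_prevalence,
              x$effect_medf_shift, x$effect_amp_gain))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
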