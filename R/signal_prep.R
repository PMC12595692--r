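#' Preprocessing configuration
#'
#' @param band_low,band_high bandpass edges, Hz (20 and 450 by default,
#'   matching standard sEMG acquisition bandwidth).
#' @param notch_freq mains notch frequency, Hz.
#' @param notch_q notch quality factor (centre frequency / -3 dB width).
#' @param window_s steady-state analysis window length, s.
#' @param hop_s stride of the steady-state window search, s.
#' @return object of class `prep_config`.
#' @export
prep_config <- function(band_low = 20, band_high = 450, notch_freq = 60,
                        notch_q = 30, window_s = 3, hop_s = 0.05) {
  cfg <- list(band_low = band_low, band_high = band_high,
              notch_freq = notch_freq, notch_q = notch_q,
              window_s = window_s, hop_s = hop_s)
  if (band_low <= 0 || band_high <= band_low)
    stop("need 0 < band_low < band_high")
  if (notch_freq <= band_low || notch_freq >= band_high)
    stop("notch frequency must lie within the passband")
  if (window_s <= 0 || hop_s <= 0) stop("window_s and hop_s must be positive")
  class(cfg) <- "prep_config"
  cfg
}

#' Preprocess a raw sEMG trial
#'
#' Offset removal (mean subtraction), zero-phase Butterworth bandpass
#' (forward-backward, 4th order overall) between `band_low` and `band_high`,
#' and a zero-phase second-order IIR notch at `notch_freq` to suppress mains
#' interference. Output has the same length as the input.
#'
#' @param trial an [emg_trial()].
#' @param cfg a [prep_config()].
#' @return the filtered [emg_trial()].
#' @export
preprocess <- function(trial, cfg = prep_config()) {
  stopifnot(inherits(trial, "emg_trial"))
  fs <- trial$fs
  if (cfg$band_high >= fs / 2)
    stop("band_high must be below the Nyquist frequency")
  x <- trial$samples - mean(trial$samples)
  if (length(x) < 24) stop("trial shorter than filter warm-up")
  bf <- signal::butter(2, c(cfg$band_low, cfg$band_high) / (fs / 2), type = "pass")
  x <- filtfilt_padded(bf$b, bf$a, x, fs)
  nc <- notch_coef(cfg$notch_freq, fs, cfg$notch_q)
  x <- filtfilt_padded(nc$b, nc$a, x, fs)
  out <- trial
  out$samples <- as.numeric(x - mean(x))
  out
}

# Zero-phase filtering with odd-symmetric edge reflection, suppressing the
# start/end transients that plain forward-backward filtering leaves (the
# notch at Q = 30 has an impulse response of ~0.5 s).
filtfilt_padded <- function(b, a, x, fs) {
  n <- length(x)
  pad <- min(n - 1, as.integer(round(fs)))
  head_ref <- 2 * x[1] - x[(pad + 1):2]
  tail_ref <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(signal::Arma(b = b, a = a),
                        c(head_ref, x, tail_ref))
  y[(pad + 1):(pad + n)]
}

#' Extract the steady-state segment of an MVC trial
#'
#' Scans `window_s`-long windows at `hop_s` stride and returns the window
#' with the lowest sample standard deviation; ties are broken by the
#' earliest start. This targets the plateau of the contraction, away from
#' onset/offset transients.
#'
#' @param trial a (preprocessed) [emg_trial()].
#' @param cfg a [prep_config()].
#' @return object of class `steady_segment`: list with `samples`,
#'   `start_index` (0-based sample offset into the trial), `fs`,
#'   `muscle_id`, `trial_index`.
#' @export
extract_steady_segment <- function(trial, cfg = prep_config()) {
  stopifnot(inherits(trial, "emg_trial"))
  n <- length(trial$samples)
  win <- round(cfg$window_s * trial$fs)
  if (win < 2) stop("window too short")
  if (n < win) stop("segment-too-short: trial shorter than the analysis window")
  hop <- max(1L, round(cfg$hop_s * trial$fs))
  starts <- seq(1L, n - win + 1L, by = hop)
  # ensure the final window is a candidate even if the stride overshoots
  if (starts[length(starts)] != n - win + 1L) starts <- c(starts, n - win + 1L)
  # rolling mean/second moment via cumulative sums -> SD per candidate window
  cs <- cumsum(c(0, trial$samples))
  cs2 <- cumsum(c(0, trial$samples^2))
  s1 <- cs[starts + win] - cs[starts]
  s2 <- cs2[starts + win] - cs2[starts]
  v <- pmax((s2 - s1^2 / win) / (win - 1), 0)
  best <- starts[which.min(v)]  # which.min takes the first minimum: earliest tie wins
  structure(list(samples = trial$samples[best:(best + win - 1L)],
                 start_index = best - 1L, fs = trial$fs,
                 muscle_id = trial$muscle_id, trial_index = trial$trial_index),
            class = "steady_segment")
}

#' @export
print.steady_segment <- function(x, ...) {
  cat(sprintf("Steady-state segment %s/trial %d: %d samples @ %g Hz, start %d, SD %.4f mV\n",
              x$muscle_id, x$trial_index, length(x$samples), x$fs,
              x$start_index, stats::sd(x$samples)))
  invisible(x)
}

#' Write steady-state segments and their index to disk
#'
#' @param segments list of `steady_segment` objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- do.call(rbind, lapply(segments, function(s) {
    fn <- sprintf("%s_trial%d_segment.txt", s$muscle_id, s$trial_index)
    utils::write.table(
      data.frame(time_s = (seq_along(s$samples) - 1) / s$fs,
                 amplitude_mV = s$samples),
      file.path(dir, fn), sep = "\t", row.names = FALSE, quote = FALSE)
    data.frame(muscle_id = s$muscle_id, trial_index = s$trial_index,
               start_index = s$start_index)
  }))
  utils::write.csv(idx, file.path(dir, "segments.csv"), row.names = FALSE)
  invisible(dir)
}
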