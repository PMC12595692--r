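#' Feature extraction configuration
#'
#' Tunables of the 24-feature sEMG bank. Defaults follow common
#' myoelectric-control practice: a shared 10 uV dead-zone for the threshold
#' counts, a 9-bin amplitude histogram spanning +/-3 SD, Yule-Walker AR(4)
#' with AR-derived cepstrum, and Welch spectra from 1024-sample Hann blocks
#' at 50% overlap.
#'
#' @param deadzone_eps threshold (mV) shared by ZERC, SSC and wAmp.
#' @param hist_bins number of amplitude histogram bins.
#' @param hist_range_sigmas histogram half-range in SD units.
#' @param ar_order autoregressive model order (fixed at 4).
#' @param cepstrum_order number of cepstral coefficients (fixed at 4).
#' @param welch_nperseg Welch block length, samples.
#' @param welch_overlap fractional Welch block overlap.
#' @param card_tol amplitude tolerance (mV) identifying near-equal samples
#'   for the cardinality count.
#' @param log_floor lower guard (mV) for the log-detector.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(deadzone_eps = 0.01, hist_bins = 9,
                           hist_range_sigmas = 3, ar_order = 4,
                           cepstrum_order = 4, welch_nperseg = 1024,
                           welch_overlap = 0.5, card_tol = 1e-6,
                           log_floor = 1e-12) {
  if (ar_order != 4 || cepstrum_order != 4)
    stop("AR and cepstrum orders are fixed at 4 in this feature bank")
  stopifnot(deadzone_eps >= 0, hist_bins >= 1, hist_range_sigmas > 0,
            welch_nperseg >= 2, welch_overlap >= 0, welch_overlap < 1,
            card_tol >= 0, log_floor > 0)
  structure(list(deadzone_eps = deadzone_eps, hist_bins = hist_bins,
                 hist_range_sigmas = hist_range_sigmas, ar_order = ar_order,
                 cepstrum_order = cepstrum_order,
                 welch_nperseg = welch_nperseg, welch_overlap = welch_overlap,
                 card_tol = card_tol, log_floor = log_floor),
            class = "feature_config")
}

seg_samples <- function(segment) {
  if (inherits(segment, "steady_segment")) segment$samples else as.numeric(segment)
}
seg_fs <- function(segment, fs = NULL) {
  if (inherits(segment, "steady_segment")) segment$fs
  else if (!is.null(fs)) fs
  else stop("sampling rate required for spectral features on a bare vector")
}

#' Amplitude and energy features
#'
#' Peak-to-peak (p2p), mean absolute value (MAV), root mean square (RMS),
#' variance (VAR, mean-subtracted, N-1 normalised) and the log-detector
#' (logD = exp(mean log |x|), floored to avoid log 0).
#'
#' @param segment a `steady_segment` or numeric vector.
#' @param cfg a [feature_config()].
#' @return named numeric vector.
#' @export
amplitude_features <- function(segment, cfg = feature_config()) {
  x <- seg_samples(segment)
  if (length(x) < 2) stop("segment must contain at least 2 samples")
  c(p2p = max(x) - min(x),
    MAV = mean(abs(x)),
    RMS = sqrt(mean(x^2)),
    VAR = stats::var(x),
    logD = exp(mean(log(pmax(abs(x), cfg$log_floor)))))
}

#' First-difference features
#'
#' Waveform length (wLen = sum |dx|), difference absolute mean value
#' (DAMV = wLen/(N-1)), difference variance (DVARV = sum dx^2 / (N-2)) and
#' the second-order spectral moment (M2 = sum dx^2), all over consecutive
#' sample differences dx.
#'
#' @inheritParams amplitude_features
#' @return named numeric vector.
#' @export
difference_features <- function(segment, cfg = feature_config()) {
  x <- seg_samples(segment)
  n <- length(x)
  if (n < 3) stop("segment must contain at least 3 samples")
  dx <- diff(x)
  m2 <- sum(dx^2)
  c(DAMV = sum(abs(dx)) / (n - 1),
    DVARV = m2 / (n - 2),
    wLen = sum(abs(dx)),
    M2 = m2)
}

#' Dead-zoned threshold counts
#'
#' Zero crossings (ZERC), slope sign changes (SSC) and Willison amplitude
#' (wAmp), each counting only excursions at least `deadzone_eps` in size so
#' that low-level noise does not inflate the counts.
#'
#' @inheritParams amplitude_features
#' @return named integer vector.
#' @export
threshold_counts <- function(segment, cfg = feature_config()) {
  x <- seg_samples(segment)
  n <- length(x)
  if (n < 3) stop("segment must contain at least 3 samples")
  eps <- cfg$deadzone_eps
  x1 <- x[-n]; x2 <- x[-1]
  zerc <- sum(x1 * x2 < 0 & abs(x1 - x2) >= eps)
  mid <- x[2:(n - 1)]
  ssc <- sum((mid - x[1:(n - 2)]) * (mid - x[3:n]) >= eps)
  wamp <- sum(abs(diff(x)) >= eps)
  c(ZERC = zerc, SSC = ssc, wAmp = wamp)
}

#' Spectral features from the Welch periodogram
#'
#' Mean frequency (power-weighted spectral centroid) and median frequency
#' (frequency splitting total Welch power in half).
#'
#' @inheritParams amplitude_features
#' @param fs sampling rate, Hz (taken from the segment when available).
#' @return named numeric vector `c(MeanF=, MedF=)` in Hz.
#' @export
spectral_features <- function(segment, cfg = feature_config(), fs = NULL) {
  x <- seg_samples(segment)
  fs <- seg_fs(segment, fs)
  if (length(x) < cfg$welch_nperseg)
    stop("segment shorter than one Welch block")
  w <- welch_psd(x, fs, cfg$welch_nperseg, cfg$welch_overlap)
  tot <- sum(w$psd)
  if (tot <= 0) return(c(MeanF = 0, MedF = 0))
  meanf <- sum(w$freq * w$psd) / tot
  medf <- w$freq[which(cumsum(w$psd) >= tot / 2)[1]]
  c(MeanF = meanf, MedF = medf)
}

# AR(4) predictor-form coefficients (x_t = sum a_k x_{t-k} + e) by
# Yule-Walker, plus the first 4 cepstral coefficients of the implied AR
# model spectrum via the standard log-derivative recursion. The recursion
# is stated over the polynomial-convention coefficients alpha_k = -a_k:
# c_1 = -alpha_1, c_n = -alpha_n - sum_{m<n} (m/n) c_m alpha_{n-m},
# which matches the inverse transform of the log AR spectrum (checked in
# the test suite against that spectral-path oracle).
ar_cepstrum_from_coef <- function(a, p) {
  alpha <- -a
  cc <- numeric(p)
  for (n in seq_len(p)) {
    s <- 0
    if (n > 1) {
      m <- 1:(n - 1)
      s <- sum((m / n) * cc[m] * alpha[n - m])
    }
    cc[n] <- -alpha[n] - s
  }
  cc
}

#' Autoregressive and cepstral coefficients
#'
#' Fits a Yule-Walker AR(4) model (predictor convention
#' `x_t = sum a_k x_(t-k) + e_t`) and derives the first four cepstral
#' coefficients of the AR model spectrum.
#'
#' @inheritParams amplitude_features
#' @return named numeric vector `ARCO1..ARCO4, Ceps1..Ceps4`.
#' @export
ar_and_cepstrum <- function(segment, cfg = feature_config()) {
  x <- seg_samples(segment)
  p <- cfg$ar_order
  if (length(x) <= 4 * p) stop("segment too short for AR(4) estimation")
  if (stats::var(x) == 0) stop("degenerate input: zero-variance segment")
  fit <- stats::ar.yw(x, aic = FALSE, order.max = p, demean = TRUE)
  a <- as.numeric(fit$ar)
  cc <- ar_cepstrum_from_coef(a, p)
  stats::setNames(c(a, cc), c(paste0("ARCO", 1:p), paste0("Ceps", 1:p)))
}

#' Amplitude histogram (EMGH)
#'
#' Normalised counts over `hist_bins` equal-width bins spanning
#' +/- `hist_range_sigmas` * SD(x) around zero; out-of-range samples are
#' excluded, so bin masses sum to at most 1. A zero-SD segment places all
#' mass in the centre bin by convention.
#'
#' @inheritParams amplitude_features
#' @return numeric vector `EMGH_1..EMGH_k`.
#' @export
emg_histogram <- function(segment, cfg = feature_config()) {
  x <- seg_samples(segment)
  if (length(x) < 2) stop("segment must contain at least 2 samples")
  k <- cfg$hist_bins
  s <- stats::sd(x)
  h <- numeric(k)
  if (s == 0) {
    h[ceiling(k / 2)] <- 1
  } else {
    r <- cfg$hist_range_sigmas * s
    breaks <- seq(-r, r, length.out = k + 1)
    idx <- findInterval(x, breaks, rightmost.closed = TRUE)
    idx <- idx[idx >= 1 & idx <= k]
    h <- tabulate(idx, nbins = k) / length(x)
  }
  stats::setNames(h, paste0("EMGH_", seq_len(k)))
}

#' Cardinality
#'
#' Number of distinct sample values, identifying values within `card_tol`
#' of each other: after sorting, a new distinct value starts whenever a
#' sample exceeds the previous distinct value by more than the tolerance.
#'
#' @inheritParams amplitude_features
#' @return integer count.
#' @export
cardinality <- function(segment, cfg = feature_config()) {
  x <- sort(seg_samples(segment))
  if (length(x) < 1) stop("empty segment")
  tol <- cfg$card_tol
  count <- 1L
  anchor <- x[1]
  for (v in x[-1]) {
    if (v - anchor > tol) {
      count <- count + 1L
      anchor <- v
    }
  }
  c(Card = count)
}

#' Extract the full 24-feature vector
#'
#' Assembles the complete feature bank from one steady-state segment:
#' amplitude features (p2p, MAV, RMS, VAR, logD), difference features
#' (DVARV, DAMV, wLen, M2), threshold counts (ZERC, SSC, wAmp), spectral
#' features (MeanF, MedF), cardinality, AR and cepstral coefficients, and
#' the amplitude histogram expanded to `EMGH_1..EMGH_k`.
#'
#' @inheritParams spectral_features
#' @return named numeric vector of 23 scalars + `hist_bins` histogram bins.
#' @export
extract_feature_vector <- function(segment, cfg = feature_config(), fs = NULL) {
  a <- amplitude_features(segment, cfg)
  d <- difference_features(segment, cfg)
  tc <- threshold_counts(segment, cfg)
  sp <- spectral_features(segment, cfg, fs)
  arc <- ar_and_cepstrum(segment, cfg)
  h <- emg_histogram(segment, cfg)
  cd <- cardinality(segment, cfg)
  c(a["p2p"], a["MAV"], a["RMS"], a["VAR"],
    d["DVARV"], d["DAMV"], a["logD"],
    tc, d["wLen"], d["M2"], sp, cd, arc, h)
}

#' Names of the expanded Full feature columns
#' @param cfg a [feature_config()].
#' @return character vector of column names in canonical order.
#' @export
feature_names <- function(cfg = feature_config()) {
  c("p2p", "MAV", "RMS", "VAR", "DVARV", "DAMV", "logD",
    "ZERC", "SSC", "wAmp", "wLen", "M2", "MeanF", "MedF", "Card",
    paste0("ARCO", 1:4), paste0("Ceps", 1:4),
    paste0("EMGH_", seq_len(cfg$hist_bins)))
}
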