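#' @keywords internal
"_PACKAGE"

## Internal numeric helpers shared across modules.

# Half-up rounding to `digits` decimals. base::round() rounds half to even,
# which disagrees with how clinical tables are conventionally rounded.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Derive a 31-bit seed from a base seed plus integer ids, so every
# participant/muscle/trial gets its own reproducible RNG stream.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  acc <- 0
  for (v in ids) {
    acc <- (acc * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  }
  as.integer(acc)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Second-order IIR notch (biquad) coefficients at f0 with quality factor Q.
notch_coef <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hann-windowed, overlapping,
#' per-segment demeaned blocks; one-sided density scaling.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param nperseg samples per block.
#' @param overlap fractional overlap between consecutive blocks in [0, 1).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 1024, overlap = 0.5) {
  n <- length(x)
  if (n < nperseg) stop("signal shorter than one Welch block")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / nperseg))
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nfreq])^2
    acc <- acc + sp
  }
  psd <- scale * acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  if (nperseg %% 2 == 0) {
    psd[2:(nfreq - 1)] <- 2 * psd[2:(nfreq - 1)]
  } else {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  list(freq = (0:(nfreq - 1)) * fs / nperseg, psd = psd)
}
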