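cfg0 <- feature_config(deadzone_eps = 0)

test_that("hand-computed 4-sample oracle values are reproduced", {
  x <- c(1, -2, 3, -4)
  a <- amplitude_features(x, cfg0)
  expect_equal(unname(a["p2p"]), 7)
  expect_equal(unname(a["MAV"]), 2.5)
  expect_equal(unname(a["RMS"]), sqrt(mean(x^2)))
  expect_equal(unname(a["VAR"]), var(x))
  d <- difference_features(x, cfg0)
  expect_equal(unname(d["wLen"]), 15)
  expect_equal(unname(d["M2"]), 83)
  expect_equal(unname(d["DAMV"]), 5)
  expect_equal(unname(d["DVARV"]), 41.5)
  tc <- threshold_counts(x, cfg0)
  expect_equal(unname(tc["ZERC"]), 3)
  expect_equal(unname(tc["SSC"]), 2)
  expect_equal(unname(tc["wAmp"]), 3)
})

test_that("degenerate segments behave as documented", {
  z <- rep(0, 100)
  a <- amplitude_features(z, cfg0)
  expect_equal(unname(a["p2p"]), 0)
  expect_equal(unname(a["MAV"]), 0)
  expect_equal(unname(a["logD"]), feature_config()$log_floor)
  expect_equal(unname(difference_features(z, cfg0)), rep(0, 4))
  ramp <- seq(0, 1, length.out = 50)
  tc <- threshold_counts(ramp, cfg0)
  expect_equal(unname(tc["ZERC"]), 0)
  expect_equal(unname(tc["SSC"]), 0)
  expect_error(amplitude_features(numeric(0), cfg0), "2 samples")
})

test_that("amplitude features are homogeneous in signal scale", {
  x <- noise_segment(500)
  a1 <- amplitude_features(x, cfg0)
  a2 <- amplitude_features(2 * x, cfg0)
  expect_equal(unname(a2[c("p2p", "MAV", "RMS")]),
               2 * unname(a1[c("p2p", "MAV", "RMS")]))
  expect_equal(unname(a2["VAR"]), 4 * unname(a1["VAR"]))
})

test_that("M2 of a unit sinusoid approaches its closed-form limit", {
  fs <- 4000
  for (f in c(50, 100, 250)) {
    x <- sin(2 * pi * f * (0:79999) / fs)
    m2 <- difference_features(x, cfg0)["M2"]
    expect_equal(unname(m2) / length(x), 2 * sin(pi * f / fs)^2,
                 tolerance = 1e-3)
  }
})

test_that("a dead zone larger than the signal silences all counts", {
  x <- noise_segment(1000, sd = 0.05)
  big <- feature_config(deadzone_eps = max(x) - min(x) + 1)
  tc <- threshold_counts(x, big)
  expect_equal(unname(tc), c(0, 0, 0))
  # counts are non-increasing in the dead zone
  eps_grid <- c(0, 0.01, 0.05, 0.1, 0.3)
  counts <- sapply(eps_grid, function(e)
    threshold_counts(x, feature_config(deadzone_eps = e)))
  expect_true(all(apply(counts, 1, function(r) all(diff(r) <= 0))))
})

test_that("spectral features locate sinusoidal content", {
  fs <- 4000
  binw <- fs / 1024
  t <- (0:19999) / fs
  sf <- spectral_features(sin(2 * pi * 120 * t), fs = fs)
  expect_lt(abs(sf["MeanF"] - 120), binw)
  expect_lt(abs(sf["MedF"] - 120), binw)
  two <- sin(2 * pi * 100 * t) + sin(2 * pi * 200 * t)
  expect_lt(abs(spectral_features(two, fs = fs)["MeanF"] - 150), binw)
})

test_that("Welch median frequency matches a direct periodogram oracle", {
  fs <- 4000
  set.seed(21)
  x <- rnorm(40000)
  bf <- signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, x))
  medf <- spectral_features(x, fs = fs)["MedF"]
  # oracle: single full-length periodogram, no windowing
  n <- length(x)
  p <- abs(fft(x - mean(x))[1:(n / 2 + 1)])^2
  fr <- (0:(n / 2)) * fs / n
  medf_oracle <- fr[which(cumsum(p) >= sum(p) / 2)[1]]
  expect_lt(abs(medf - medf_oracle), 10)
})

test_that("Yule-Walker AR(4) recovers simulated process parameters", {
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.9), 50000))
  arc <- ar_and_cepstrum(x)
  expect_lt(abs(arc["ARCO1"] - 0.9), 0.02)
  expect_true(all(abs(arc[c("ARCO2", "ARCO3", "ARCO4")]) < 0.05))
  w <- rnorm(50000)
  expect_true(all(abs(ar_and_cepstrum(w)[1:4]) < 0.05))
  expect_error(ar_and_cepstrum(rep(1, 1000)), "degenerate")
})

test_that("cepstral coefficients match the log-AR-spectrum oracle", {
  set.seed(8)
  fixtures <- list(
    as.numeric(arima.sim(list(ar = c(0.6, -0.3, 0.1, 0.05)), 20000)),
    as.numeric(signal::filtfilt(signal::butter(2, c(0.05, 0.3)), rnorm(20000))))
  for (x in fixtures) {
    arc <- ar_and_cepstrum(x)
    a <- unname(arc[1:4])
    N <- 8192
    w <- 2 * pi * (0:(N - 1)) / N
    A <- 1 + 0i * w
    for (k in 1:4) A <- A - a[k] * exp(-1i * k * w)
    rc <- Re(fft(log(1 / Mod(A)^2), inverse = TRUE)) / N
    expect_equal(unname(arc[5:8]), rc[2:5], tolerance = 1e-6)
  }
})

test_that("amplitude histogram matches the normal-CDF oracle", {
  set.seed(13)
  x <- rnorm(200000)
  h <- emg_histogram(x, feature_config())
  s <- sd(x)
  edges <- seq(-3 * s, 3 * s, length.out = 10)
  p_exp <- diff(pnorm(edges))  # true sigma = 1
  se <- sqrt(p_exp * (1 - p_exp) / length(x))
  expect_true(all(abs(h - p_exp) < 3 * se + 1e-4))
  expect_true(sum(h) <= 1)
})

test_that("histogram conventions: constant signal and mirror symmetry", {
  h <- emg_histogram(rep(2.5, 50), feature_config())
  expect_equal(unname(h[5]), 1)
  expect_equal(sum(h), 1)
  x <- noise_segment(2000)
  expect_equal(unname(emg_histogram(-x, feature_config())),
               rev(unname(emg_histogram(x, feature_config()))))
})

test_that("cardinality identifies values within tolerance", {
  expect_equal(unname(cardinality(rep(3, 100), feature_config())), 1)
  expect_equal(unname(cardinality(c(0, 0.5, 1.0),
                                  feature_config(card_tol = 0.6))), 2)
  x <- seq(0, 1, by = 0.01)
  expect_equal(unname(cardinality(x, feature_config(card_tol = 0.001))),
               length(x))
})

test_that("the assembled feature vector composes its parts and keeps shape invariances", {
  set.seed(3)
  fs <- 4000
  x <- as.numeric(signal::filtfilt(signal::butter(2, c(0.02, 0.2)), rnorm(13000)))
  seg <- structure(list(samples = x, start_index = 0L, fs = fs,
                        muscle_id = "m", trial_index = 1L),
                   class = "steady_segment")
  fv <- extract_feature_vector(seg, cfg0)
  expect_equal(names(fv), feature_names(cfg0))
  expect_equal(unname(fv["MAV"]), unname(amplitude_features(x, cfg0)["MAV"]))
  expect_equal(unname(fv["M2"]), unname(difference_features(x, cfg0)["M2"]))
  expect_equal(unname(fv["Card"]), unname(cardinality(x, cfg0)))
  expect_true(all(is.finite(fv)))
  # doubling the signal: shape features unchanged, amplitude features doubled
  seg2 <- seg; seg2$samples <- 2 * x
  fv2 <- extract_feature_vector(seg2, cfg0)
  shape <- c("ZERC", "SSC", "MedF", "MeanF", paste0("ARCO", 1:4),
             paste0("Ceps", 1:4))
  expect_equal(unname(fv2[shape]), unname(fv[shape]), tolerance = 1e-8)
  expect_equal(unname(fv2[c("MAV", "RMS", "p2p")]),
               2 * unname(fv[c("MAV", "RMS", "p2p")]))
})

test_that("feature-bank invariants hold on random band-limited segments", {
  set.seed(77)
  for (i in 1:10) {
    x <- as.numeric(signal::filtfilt(signal::butter(2, c(0.01, 0.225)),
                                     rnorm(6000, sd = runif(1, 0.01, 1))))
    x <- x - mean(x)
    a <- amplitude_features(x, cfg0)
    expect_lte(a[["MAV"]], a[["RMS"]])
    expect_lte(a[["RMS"]], a[["p2p"]])
    d <- difference_features(x, cfg0)
    expect_equal(d[["M2"]], (length(x) - 2) * d[["DVARV"]])
    medf <- spectral_features(x, fs = 4000)[["MedF"]]
    expect_gte(medf, 20)
    expect_lte(medf, 450)
  }
})
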