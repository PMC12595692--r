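#' Construct a raw sEMG trial
#'
#' @param samples numeric amplitude series in mV.
#' @param fs sampling rate, Hz.
#' @param condition `"rest"` or `"mvc"`.
#' @param trial_index trial number (0 for the rest trial by convention).
#' @param muscle_id,participant_id identifiers.
#' @return object of class `emg_trial`.
#' @export
emg_trial <- function(samples, fs, condition = c("mvc", "rest"),
                      trial_index = 1L, muscle_id = NA_character_,
                      participant_id = NA_character_) {
  condition <- match.arg(condition)
  if (length(samples) < 1L) stop("trial must contain at least one sample")
  if (!all(is.finite(samples))) stop("trial samples must be finite")
  if (fs <= 0) stop("sampling rate must be positive")
  structure(list(samples = as.numeric(samples), fs = fs,
                 condition = condition, trial_index = as.integer(trial_index),
                 muscle_id = muscle_id, participant_id = participant_id),
            class = "emg_trial")
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("sEMG trial [%s] %s/%s: %d samples @ %g Hz (%.2f s), RMS %.4f mV\n",
              x$condition, x$participant_id, x$muscle_id, length(x$samples),
              x$fs, length(x$samples) / x$fs, sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Construct a manual muscle testing (MMT) trajectory
#'
#' @param sessions strictly increasing integer session indices starting at 1.
#' @param scores integer MMT scores in 0..5, same length as `sessions`.
#' @return object of class `mmt_trajectory`.
#' @export
mmt_trajectory <- function(sessions, scores) {
  if (length(sessions) != length(scores) || length(scores) < 2L)
    stop("trajectory needs >= 2 (session, score) pairs of equal length")
  if (any(diff(sessions) <= 0)) stop("sessions must be strictly increasing")
  if (any(scores < 0 | scores > 5)) stop("MMT scores must lie in 0..5")
  structure(list(sessions = as.integer(sessions), scores = as.integer(scores)),
            class = "mmt_trajectory")
}

# Band edges for the MVC spectrum; low edge floored at 10 Hz to keep the
# Butterworth design valid for low spectral centres.
mvc_band <- function(spectral_center, bandwidth, fs) {
  lo <- max(spectral_center - bandwidth / 2, 10)
  hi <- min(spectral_center + bandwidth / 2, 0.95 * fs / 2)
  c(lo, hi)
}

#' Simulate one sEMG trial
#'
#' MVC trials are band-shaped Gaussian noise (4th-order Butterworth band
#' centred on `spectral_center`) whose RMS amplitude grows with baseline
#' strength, plus white sensor noise and a 60 Hz mains sinusoid. Rest trials
#' contain sensor noise and the mains component only. The band-shaped noise
#' model is a stand-in for physiological motor-unit activity: it is simple
#' but drives every feature in the extraction bank.
#'
#' @param strength baseline MMT grade in 0..5.
#' @param condition `"mvc"` or `"rest"`.
#' @param spectral_center centre of the MVC band, Hz; must lie in (20, 450).
#' @param cfg a [sim_config()].
#' @param amp_ratio multiplicative amplitude effect (planted responder
#'   effect; 1 for non-responders).
#' @param seed RNG seed for this trial (derived per-trial by
#'   [generate_cohort()]).
#' @inheritParams emg_trial
#' @return an [emg_trial()].
#' @export
simulate_emg_trial <- function(strength, condition = c("mvc", "rest"),
                               spectral_center, cfg, amp_ratio = 1,
                               seed = cfg$seed, trial_index = 1L,
                               muscle_id = NA_character_,
                               participant_id = NA_character_) {
  condition <- match.arg(condition)
  validate_sim_config(cfg)
  if (strength < 0 || strength > 5) stop("strength must be an MMT grade in 0..5")
  if (condition == "mvc" && (spectral_center <= 20 || spectral_center >= 450))
    stop("spectral_center must lie strictly inside (20, 450) Hz")
  dur <- if (condition == "mvc") cfg$mvc_duration else cfg$rest_duration
  n <- round(dur * cfg$fs)
  if (n < 1) stop("non-positive trial duration")
  t <- (0:(n - 1)) / cfg$fs
  x <- with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    line <- cfg$line_noise_amp * sin(2 * pi * 60 * t + phase)
    sensor <- stats::rnorm(n, sd = cfg$sensor_noise_sd)
    if (condition == "rest") {
      sensor + line
    } else {
      band <- mvc_band(spectral_center, cfg$mvc_bandwidth, cfg$fs)
      bf <- signal::butter(2, band / (cfg$fs / 2), type = "pass")
      muscle <- signal::filter(bf, stats::rnorm(n))
      amp <- (cfg$mvc_amp_base + cfg$mvc_amp_per_grade * strength) * amp_ratio
      muscle <- muscle / sqrt(mean(muscle^2)) * amp
      as.numeric(muscle) + sensor + line
    }
  })
  emg_trial(x, cfg$fs, condition, trial_index, muscle_id, participant_id)
}

#' Simulate an MMT trajectory with a planted label
#'
#' Responders follow a monotone staircase gaining `responder_gain` grades
#' over the therapy cycle (capped at 5); non-responders stay at baseline.
#' Both are perturbed by session-wise +/-1 fluctuations at `jitter_prob`,
#' emulating inter-rater MMT noise.
#'
#' @param label `"responder"` or `"non_responder"`.
#' @param baseline baseline MMT grade in 0..4.
#' @param cfg a [sim_config()].
#' @param seed RNG seed for this trajectory.
#' @return an [mmt_trajectory()].
#' @export
simulate_mmt_trajectory <- function(label = c("responder", "non_responder"),
                                    baseline, cfg, seed = cfg$seed) {
  label <- match.arg(label)
  validate_sim_config(cfg)
  if (baseline < 0 || baseline > 4)
    stop("baseline MMT for a target muscle must lie in 0..4 (5 is excluded at ceiling)")
  n <- cfg$n_sessions
  base <- if (label == "responder") {
    baseline + floor(cfg$responder_gain * (0:(n - 1)) / (n - 1) + 1e-9)
  } else {
    rep(baseline, n)
  }
  base <- pmin(base, 5)
  scores <- with_seed(seed, {
    flip <- stats::runif(n) < cfg$jitter_prob
    delta <- ifelse(flip, sample(c(-1L, 1L), n, replace = TRUE), 0L)
    pmin(pmax(base + delta, 0L), 5L)
  })
  mmt_trajectory(1:n, scores)
}

# Largest-remainder apportionment of n items over proportions p.
apportion <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    idx <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[idx] <- k[idx] + 1
  }
  k
}

# Responder probability per AIS grade: prevalence scaled so that the
# responder fraction rises from A to D while the cohort-level expectation
# stays at cfg$responder_prevalence (mirrors the clinically observed trend).
ais_responder_prob <- function(cfg) {
  w <- c(A = 0.55, B = 0.8, C = 1.05, D = 1.2)
  z <- sum(cfg$ais_distribution[names(w)] * w)
  pmin(cfg$responder_prevalence * w / z, 1)
}

#' Generate a synthetic FES-therapy cohort
#'
#' Builds participants (AIS grade, neurological level of injury, months post
#' injury), their target muscles (myotome, distance to the injury level,
#' proximity, baseline MMT), per-muscle sEMG trials (one rest + `mvc_trials`
#' MVC trials) and longitudinal MMT trajectories, with responder structure
#' planted jointly in the MVC spectrum (upward spectral shift) and amplitude
#' (gain ratio). All randomness is keyed by `cfg$seed` through per-entity
#' derived streams, so the same configuration reproduces the same cohort
#' byte for byte.
#'
#' @param cfg a [sim_config()].
#' @return object of class `fes_cohort`: list with `participants` and
#'   `muscles` data frames, `trials` (list of [emg_trial()] lists per
#'   muscle), `trajectories` (list of [mmt_trajectory()] per muscle), and
#'   the generating `cfg`.
#' @export
generate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  grades <- c("A", "B", "C", "D")
  n_ais <- apportion(cfg$n_participants, cfg$ais_distribution[grades])
  ais_pool <- rep(grades, n_ais)
  nli_levels <- paste0("C", 2:6)
  nli_prob <- c(1, 5, 7, 2, 2) / 17
  myo_levels <- paste0("C", 5:8)
  myo_prob <- c(18, 48, 20, 46) / 132
  mmt_prob <- c(16, 33, 21, 31, 31) / 132
  lmn_levels <- c("no_activation", "damaged_lmn", "inconclusive")
  p_resp <- ais_responder_prob(cfg)

  participants <- with_seed(derive_seed(cfg$seed, 101), {
    data.frame(
      participant_id = sprintf("P%02d", seq_len(cfg$n_participants)),
      ais = sample(ais_pool),
      nli = sample(nli_levels, cfg$n_participants, replace = TRUE, prob = nli_prob),
      months_post_injury = round(stats::rlnorm(cfg$n_participants,
                                               meanlog = 2.99, sdlog = 1.04), 1),
      stringsAsFactors = FALSE
    )
  })

  muscles <- list()
  trials <- list()
  trajectories <- list()
  for (pi in seq_len(cfg$n_participants)) {
    pid <- participants$participant_id[pi]
    nli_num <- as.integer(sub("C", "", participants$nli[pi]))
    pseed <- derive_seed(cfg$seed, 202, pi)
    n_musc <- with_seed(pseed, sample(cfg$muscles_min:cfg$muscles_max, 1))
    for (mi in seq_len(n_musc)) {
      mid <- sprintf("%s_M%02d", pid, mi)
      mseed <- derive_seed(cfg$seed, 303, pi, mi)
      m <- with_seed(mseed, {
        ok <- as.integer(sub("C", "", myo_levels)) >= nli_num
        myo <- sample(myo_levels[ok], 1, prob = myo_prob[ok] / sum(myo_prob[ok]))
        base_mmt <- sample(0:4, 1, prob = mmt_prob)
        resp <- stats::runif(1) < p_resp[[participants$ais[pi]]]
        center <- cfg$spectral_center_base +
          stats::rnorm(1, sd = cfg$spectral_center_sd) +
          if (resp) cfg$effect_medf_shift else 0
        center <- min(max(center, 30), 420)
        lmn <- if (stats::runif(1) < 0.3)
          sample(lmn_levels, 1, prob = c(8, 14, 17) / 39) else NA_character_
        list(myo = myo, base_mmt = base_mmt, resp = resp, center = center,
             prox = sample(1:4, 1), lmn = lmn)
      })
      myo_num <- as.integer(sub("C", "", m$myo))
      label <- if (m$resp) "responder" else "non_responder"
      muscles[[mid]] <- data.frame(
        muscle_id = mid, participant_id = pid, myotome = m$myo,
        distance = myo_num - nli_num, proximity = m$prox,
        baseline_mmt = m$base_mmt, planted_label = label,
        spectral_center = m$center, lmn_category = m$lmn,
        stringsAsFactors = FALSE
      )
      amp_ratio <- if (m$resp) cfg$effect_amp_gain else 1
      tr <- list()
      tr[["rest"]] <- simulate_emg_trial(
        m$base_mmt, "rest", cfg$spectral_center_base, cfg, amp_ratio,
        seed = derive_seed(cfg$seed, 404, pi, mi, 0), trial_index = 0L,
        muscle_id = mid, participant_id = pid)
      for (ti in seq_len(cfg$mvc_trials)) {
        tr[[paste0("mvc", ti)]] <- simulate_emg_trial(
          m$base_mmt, "mvc", m$center, cfg, amp_ratio,
          seed = derive_seed(cfg$seed, 404, pi, mi, ti), trial_index = ti,
          muscle_id = mid, participant_id = pid)
      }
      trials[[mid]] <- tr
      trajectories[[mid]] <- simulate_mmt_trajectory(
        label, m$base_mmt, cfg, seed = derive_seed(cfg$seed, 505, pi, mi))
    }
  }
  muscles <- do.call(rbind, muscles)
  rownames(muscles) <- NULL
  structure(list(participants = participants, muscles = muscles,
                 trials = trials, trajectories = trajectories, cfg = cfg),
            class = "fes_cohort")
}

#' @export
print.fes_cohort <- function(x, ...) {
  n_resp <- sum(x$muscles$planted_label == "responder")
  cat(sprintf("Synthetic FES-therapy cohort: %d participants, %d muscles (%d planted responders, %.0f%%)\n",
              nrow(x$participants), nrow(x$muscles), n_resp,
              100 * n_resp / nrow(x$muscles)))
  cat("  AIS:", paste(sprintf("%s=%d", names(table(x$participants$ais)),
                              table(x$participants$ais)), collapse = " "), "\n")
  cat(sprintf("  trials per muscle: 1 rest + %d MVC @ %g Hz\n",
              x$cfg$mvc_trials, x$cfg$fs))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Writes `manifest.json`, `participants.csv`, `muscles.csv`, `mmt_log.csv`
#' (columns muscle_id, session, score) and one two-column delimited text
#' file per trial (`time_s`, `amplitude_mV`) under `dir/trials/`.
#'
#' @param cohort an `fes_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$muscles, file.path(dir, "muscles.csv"),
                   row.names = FALSE)
  mmt <- do.call(rbind, lapply(names(cohort$trajectories), function(mid) {
    tj <- cohort$trajectories[[mid]]
    data.frame(muscle_id = mid, session = tj$sessions, score = tj$scores)
  }))
  utils::write.csv(mmt, file.path(dir, "mmt_log.csv"), row.names = FALSE)
  for (mid in names(cohort$trials)) {
    for (tr in cohort$trials[[mid]]) {
      fn <- file.path(dir, "trials",
                      sprintf("%s_trial%d_%s.txt", mid, tr$trial_index, tr$condition))
      utils::write.table(
        data.frame(time_s = (seq_along(tr$samples) - 1) / tr$fs,
                   amplitude_mV = tr$samples),
        fn, sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  manifest <- list(
    n_participants = nrow(cohort$participants),
    n_muscles = nrow(cohort$muscles),
    fs = cohort$cfg$fs, mvc_trials = cohort$cfg$mvc_trials,
    seed = cohort$cfg$seed,
    files = c("participants.csv", "muscles.csv", "mmt_log.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
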