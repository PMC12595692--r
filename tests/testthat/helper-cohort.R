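# Shared fixtures: cohorts are expensive to simulate, so build each one
# lazily and cache it for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small cohort with a strong planted effect: quick to simulate, cleanly
# separable, used by harness tests.
strong_cohort <- function() {
  fixture("strong_cohort", function() {
    cfg <- sim_config(n_participants = 8, muscles_min = 3, muscles_max = 5,
                      rest_duration = 2, effect_medf_shift = 60, seed = 11)
    co <- generate_cohort(cfg)
    list(cohort = co, features = build_feature_table(co))
  })
}

# Deterministic pseudo-EMG vector for feature unit tests.
noise_segment <- function(n = 6000, seed = 7, sd = 0.1) {
  set.seed(seed)
  rnorm(n, sd = sd)
}

# Independent brute-force Kendall helpers used as oracles.
oracle_kendall_s <- function(scores, sessions = seq_along(scores)) {
  s <- 0
  n <- length(scores)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(scores[j] - scores[i]) * sign(sessions[j] - sessions[i])
  }
  s
}

oracle_tau_b <- function(scores, sessions = seq_along(scores)) {
  n <- length(scores)
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  s <- oracle_kendall_s(scores, sessions)
  s / sqrt((n0 - tie_pairs(scores)) * (n0 - tie_pairs(sessions)))
}
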