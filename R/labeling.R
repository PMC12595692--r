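#' Responder labeling configuration
#'
#' @param alpha significance level for the Kendall-tau trend test.
#' @param p_method `"auto"` (exact permutation below `exact_n`, asymptotic
#'   tie-corrected normal approximation otherwise), `"exact_permutation"`,
#'   or `"asymptotic_tie_corrected"`.
#' @param exact_n session-count threshold below which the exact permutation
#'   p-value is used under `"auto"`.
#' @return object of class `label_config`.
#' @export
label_config <- function(alpha = 0.01,
                         p_method = c("auto", "exact_permutation",
                                      "asymptotic_tie_corrected"),
                         exact_n = 10) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(alpha = alpha, p_method = match.arg(p_method),
                 exact_n = exact_n),
            class = "label_config")
}

#' Ceiling exclusion
#'
#' Muscles already at the maximum MMT grade (5) at baseline cannot improve
#' and are excluded from responder analysis.
#'
#' @param baseline_mmt baseline MMT grade in 0..5.
#' @return logical: `TRUE` if the muscle is excluded.
#' @export
exclude_ceiling <- function(baseline_mmt) {
  if (any(baseline_mmt < 0 | baseline_mmt > 5 |
          baseline_mmt != round(baseline_mmt)))
    stop("baseline MMT must be an integer grade in 0..5")
  baseline_mmt == 5
}

# Kendall S statistic (concordant minus discordant pairs) between scores
# and strictly increasing sessions.
kendall_s <- function(scores) {
  n <- length(scores)
  s <- 0
  for (i in 1:(n - 1)) {
    s <- s + sum(sign(scores[(i + 1):n] - scores[i]))
  }
  s
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Between MMT scores and session numbers. Heavily tied ordinal scores make
#' the tie correction essential; a fully tied (constant) trajectory is
#' defined as tau = 0.
#'
#' @param trajectory an [mmt_trajectory()] or integer score vector
#'   (sessions then taken as `1..n`).
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_tau_b <- function(trajectory) {
  scores <- if (inherits(trajectory, "mmt_trajectory")) trajectory$scores
            else as.numeric(trajectory)
  sessions <- if (inherits(trajectory, "mmt_trajectory")) trajectory$sessions
              else seq_along(scores)
  if (length(scores) < 2) stop("trajectory must have at least 2 sessions")
  if (stats::sd(scores) == 0) return(0)
  unname(stats::cor(scores, sessions, method = "kendall"))
}

#' P-value of the Kendall trend test
#'
#' Two-sided p-value for the null of no association between scores and
#' session order. Small trajectories use exact enumeration over all
#' score permutations; larger ones use the normal approximation with the
#' full tie-corrected variance of the S statistic.
#'
#' @inheritParams kendall_tau_b
#' @param cfg a [label_config()].
#' @return p-value in `[0, 1]`.
#' @export
tau_p_value <- function(trajectory, cfg = label_config()) {
  scores <- if (inherits(trajectory, "mmt_trajectory")) trajectory$scores
            else as.numeric(trajectory)
  n <- length(scores)
  if (n < 2) stop("trajectory must have at least 2 sessions")
  if (stats::sd(scores) == 0) return(1)
  method <- cfg$p_method
  if (method == "auto")
    method <- if (n < cfg$exact_n) "exact_permutation" else "asymptotic_tie_corrected"
  if (method == "exact_permutation") {
    tau_p_exact(scores)
  } else {
    tau_p_asymptotic(scores)
  }
}

# Exact two-sided permutation p: enumerate all orderings of the scores
# against fixed sessions; p = P(|S_perm| >= |S_obs|).
tau_p_exact <- function(scores) {
  n <- length(scores)
  s_obs <- kendall_s(scores)
  perms <- permutations_of(n)
  pairs <- utils::combn(n, 2)
  i1 <- pairs[1, ]; i2 <- pairs[2, ]
  s_all <- apply(perms, 1, function(p) {
    sp <- scores[p]
    sum(sign(sp[i2] - sp[i1]))
  })
  mean(abs(s_all) >= abs(s_obs))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in 1:n) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE] else NULL
    out[r + seq_len(nrow(sub)), ] <- cbind(left, rep(n, nrow(sub)), right)
    r <- r + nrow(sub)
  }
  out
}

# Normal approximation with full tie correction for var(S); sessions are
# untied, so only the score-side tie terms remain.
tau_p_asymptotic <- function(scores) {
  n <- length(scores)
  s <- kendall_s(scores)
  t_counts <- as.numeric(table(scores))
  vt <- sum(t_counts * (t_counts - 1) * (2 * t_counts + 5))
  v0 <- n * (n - 1) * (2 * n + 5)
  var_s <- (v0 - vt) / 18
  if (var_s <= 0) return(1)
  z <- s / sqrt(var_s)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Classify a muscle as responder or non-responder
#'
#' Applies the ceiling exclusion, then the trend rule: a muscle is a
#' responder iff its Kendall tau is positive with p below `alpha`. A
#' positive tau necessarily implies at least one score increase across
#' sessions.
#'
#' @inheritParams tau_p_value
#' @param baseline_mmt baseline MMT grade in 0..5.
#' @return object of class `label_result`: list with `tau`, `p_value`,
#'   `label`, `excluded`, `exclude_reason`.
#' @export
classify_responder <- function(trajectory, baseline_mmt, cfg = label_config()) {
  excluded <- exclude_ceiling(baseline_mmt)
  tau <- kendall_tau_b(trajectory)
  p <- tau_p_value(trajectory, cfg)
  label <- if (!excluded && tau > 0 && p < cfg$alpha) "responder" else "non_responder"
  structure(list(tau = tau, p_value = p, label = label, excluded = excluded,
                 exclude_reason = if (excluded) "baseline MMT at ceiling (5)" else NA_character_),
            class = "label_result")
}

#' @export
print.label_result <- function(x, ...) {
  cat(sprintf("%s (tau = %.3f, p = %.4g%s)\n", x$label, x$tau, x$p_value,
              if (x$excluded) ", excluded" else ""))
  invisible(x)
}

#' Label every muscle of a cohort
#'
#' @param cohort an `fes_cohort`.
#' @param cfg a [label_config()].
#' @return data frame with one row per muscle: `muscle_id`, `tau`,
#'   `p_value`, `label`, `excluded`.
#' @export
label_cohort <- function(cohort, cfg = label_config()) {
  out <- lapply(seq_len(nrow(cohort$muscles)), function(i) {
    mid <- cohort$muscles$muscle_id[i]
    res <- classify_responder(cohort$trajectories[[mid]],
                              cohort$muscles$baseline_mmt[i], cfg)
    data.frame(muscle_id = mid, tau = res$tau, p_value = res$p_value,
               label = res$label, excluded = res$excluded,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
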