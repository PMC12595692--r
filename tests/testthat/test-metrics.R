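rec <- function(truth, pred) {
  data.frame(true_label = truth, final_label = pred,
             stringsAsFactors = FALSE)
}
R <- "responder"; N <- "non_responder"

test_that("confusion counts match a manual tally and swap symmetrically", {
  truth <- c(R, R, R, N, N, N, N, R, N, N)
  pred  <- c(R, N, R, N, R, N, N, N, N, R)
  cc <- confusion(rec(truth, pred))
  expect_equal(cc$TP, 2); expect_equal(cc$FN, 2)
  expect_equal(cc$FP, 2); expect_equal(cc$TN, 4)
  swapped <- confusion(rec(ifelse(truth == R, N, R), pred))
  expect_equal(swapped$TP, cc$FP); expect_equal(swapped$FN, cc$TN)
  expect_error(confusion(rec(character(0), character(0))), "no prediction")
})

test_that("MCC follows its defining formula with the zero-denominator convention", {
  expect_equal(mcc(confusion_counts(1, 0, 0, 1)), 1)
  expect_equal(mcc(confusion_counts(0, 0, 5, 5)), 0)  # all-negative predictions
  c_fwd <- confusion_counts(18, 7, 25, 82)
  expect_equal(mcc(c_fwd),
               (18 * 82 - 7 * 25) / sqrt(25 * 43 * 89 * 107),
               tolerance = 1e-12)
  # label-swap symmetry of the formula
  expect_equal(mcc(c_fwd), mcc(confusion_counts(82, 25, 7, 18)))
})

test_that("the metric suite reproduces hand-computed values", {
  m <- metric_suite(confusion_counts(18, 7, 25, 82))
  expect_equal(m$accuracy, 100 / 132)
  expect_equal(m$precision, 18 / 25)
  expect_equal(m$recall_tpr, 18 / 43)
  expect_equal(m$tnr, 82 / 89)
  expect_equal(m$macro_f1, (36 / 68 + 164 / 196) / 2)
  perfect <- metric_suite(confusion_counts(4, 0, 0, 6))
  expect_true(all(unlist(perfect[c("mcc", "macro_f1", "accuracy",
                                   "precision", "recall_tpr", "tnr")]) == 1))
  # participant with no responders and no positive predictions
  m0 <- metric_suite(confusion_counts(0, 0, 0, 8))
  expect_equal(m0$recall_tpr, 0)
  expect_equal(m0$tnr, 1)
})

test_that("participant-level confusions add up to the overall confusion", {
  set.seed(6)
  n <- 40
  records <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:8), each = 5),
    true_label = sample(c(R, N), n, replace = TRUE, prob = c(0.3, 0.7)),
    final_label = sample(c(R, N), n, replace = TRUE),
    stringsAsFactors = FALSE)
  per <- participant_metrics(records)
  overall <- metric_suite(confusion(records))
  expect_equal(sum(vapply(per, function(m) m$n * m$accuracy, 1)),
               overall$n * overall$accuracy)
  expect_equal(sum(vapply(per, `[[`, 1, "n_pos")), overall$n_pos)
})

test_that("AIS breakdown partitions the records", {
  participants <- data.frame(participant_id = sprintf("P%02d", 1:8),
                             ais = rep(c("A", "B", "C", "D"), each = 2))
  set.seed(8)
  records <- data.frame(
    participant_id = rep(participants$participant_id, each = 4),
    true_label = sample(c(R, N), 32, replace = TRUE),
    final_label = sample(c(R, N), 32, replace = TRUE),
    stringsAsFactors = FALSE)
  br <- ais_breakdown(records, participants)
  expect_setequal(names(br), c("A", "B", "C", "D"))
  expect_equal(sum(vapply(br, `[[`, 1, "n")), nrow(records))
  one <- ais_breakdown(records[records$participant_id %in% c("P01", "P02"), ],
                       participants)
  expect_length(one, 1)
})

test_that("chance baseline closed forms match the printed convention and Monte Carlo", {
  cb <- chance_baseline(132, 43)
  p <- 43 / 132
  expect_equal(cb$accuracy, p^2 + (1 - p)^2)
  expect_equal(cb$precision, p)
  expect_equal(cb$recall_tpr, p)
  expect_equal(cb$tnr, 1 - p)
  expect_equal(cb$macro_f1, 0.5)
  expect_equal(cb$mcc, 0)
  expect_equal(chance_baseline(10, 5)$accuracy, 0.5)
  expect_error(chance_baseline(10, 0), "degenerate")
  # Monte-Carlo oracle: predictor labels each muscle responder independently
  # with probability p; TP ~ Bin(43, p), TN ~ Bin(89, 1-p).
  set.seed(99)
  nrep <- 1e5
  tp <- rbinom(nrep, 43, p); tn <- rbinom(nrep, 89, 1 - p)
  acc <- (tp + tn) / 132
  expect_lt(abs(mean(acc) - cb$accuracy), 3 * sd(acc) / sqrt(nrep))
  recall <- tp / 43
  expect_lt(abs(mean(recall) - cb$recall_tpr), 3 * sd(recall) / sqrt(nrep))
  tnr <- tn / 89
  expect_lt(abs(mean(tnr) - cb$tnr), 3 * sd(tnr) / sqrt(nrep))
  # nonlinear metrics: evaluate at the Monte-Carlo mean confusion counts
  mc <- metric_suite(confusion_counts(round(mean(tp)), round(89 - mean(tn)),
                                      round(43 - mean(tp)), round(mean(tn))))
  expect_lt(abs(mc$precision - cb$precision), 0.01)
  expect_lt(abs(mc$macro_f1 - cb$macro_f1), 0.01)
  expect_lt(abs(mc$mcc), 0.01)
})

test_that("confusion matrices are uniquely reconstructed from printed metrics", {
  c_fwd <- reconstruct_confusion(132, 43, 0.72, 0.42, 0.92)
  expect_equal(unlist(c_fwd[c("TP", "FP", "FN", "TN")]),
               c(TP = 18, FP = 7, FN = 25, TN = 82))
  c_clin <- reconstruct_confusion(132, 43, 0.69, 0.21, 0.96)
  expect_equal(unlist(c_clin[c("TP", "FP", "FN", "TN")]),
               c(TP = 9, FP = 4, FN = 34, TN = 85))
  c_perf <- reconstruct_confusion(132, 43, 1.00, 1.00, 1.00)
  expect_equal(c_perf$TP, 43); expect_equal(c_perf$TN, 89)
  expect_error(reconstruct_confusion(132, 43, 0.99, 0.99, 0.01), "no integer")
})
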