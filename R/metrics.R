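#' Confusion counts from prediction records
#'
#' Tallies muscle-level (not trial-level) predictions. The positive class
#' is `"responder"`.
#'
#' @param records data frame with columns `true_label` and `final_label`
#'   (values `"responder"` / `"non_responder"`), one row per muscle.
#' @return object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion <- function(records) {
  if (NROW(records) == 0) stop("no prediction records")
  truth <- records$true_label == "responder"
  pred <- records$final_label == "responder"
  confusion_counts(TP = sum(truth & pred), FP = sum(!truth & pred),
                   FN = sum(truth & !pred), TN = sum(!truth & !pred))
}

#' @rdname confusion
#' @param TP,FP,FN,TN non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  cts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(cts < 0) || any(cts != round(cts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(cts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion (n = %d): TP %d  FP %d  FN %d  TN %d\n",
              x$TP + x$FP + x$FN + x$TN, x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with any
#' zero factor in the denominator giving MCC = 0 (the no-information
#' convention).
#'
#' @param c a [confusion_counts()].
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(c) {
  num <- c$TP * c$TN - c$FP * c$FN
  fac <- c(c$TP + c$FP, c$TP + c$FN, c$TN + c$FP, c$TN + c$FN)
  if (any(fac == 0)) return(0)
  num / sqrt(prod(fac))
}

#' Full metric suite from a confusion matrix
#'
#' Accuracy, precision, recall (TPR), specificity (TNR), macro F1 (mean of
#' the per-class F1 scores) and MCC. Ratios with a zero denominator are
#' defined as 0, matching the convention used for participants with no
#' responder muscles.
#'
#' @param c a [confusion_counts()].
#' @param granularity tag recording the evaluation level.
#' @return object of class `metrics_report` (named list of scalars).
#' @export
metric_suite <- function(c, granularity = "overall") {
  n <- c$TP + c$FP + c$FN + c$TN
  if (n == 0) stop("empty confusion matrix")
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  precision <- safe_div(c$TP, c$TP + c$FP)
  recall <- safe_div(c$TP, c$TP + c$FN)
  tnr <- safe_div(c$TN, c$TN + c$FP)
  f1_pos <- safe_div(2 * c$TP, 2 * c$TP + c$FP + c$FN)
  f1_neg <- safe_div(2 * c$TN, 2 * c$TN + c$FN + c$FP)
  structure(list(mcc = mcc(c), macro_f1 = (f1_pos + f1_neg) / 2,
                 accuracy = (c$TP + c$TN) / n, precision = precision,
                 recall_tpr = recall, tnr = tnr, n = n,
                 n_pos = c$TP + c$FN, granularity = granularity),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics [%s] (n = %d, %d responders):\n", x$granularity,
              x$n, x$n_pos))
  cat(sprintf("  MCC %.2f | macro F1 %.2f | accuracy %.0f%% | precision %.2f | recall %.2f | TNR %.2f\n",
              x$mcc, x$macro_f1, 100 * x$accuracy, x$precision,
              x$recall_tpr, x$tnr))
  invisible(x)
}

#' Per-participant metric reports
#'
#' @param records muscle-level prediction records with a `participant_id`
#'   column.
#' @return named list of [metric_suite()] reports, one per participant.
#' @export
participant_metrics <- function(records) {
  by_p <- split(records, records$participant_id)
  lapply(by_p, function(r) metric_suite(confusion(r), granularity = "participant"))
}

#' Per-AIS-grade metric reports
#'
#' Evaluates predictions separately within each AIS grade (model trained on
#' everyone, graded per severity stratum).
#'
#' @param records muscle-level prediction records with `participant_id`.
#' @param participants data frame with `participant_id` and `ais`.
#' @return named list of [metric_suite()] reports over grades present.
#' @export
ais_breakdown <- function(records, participants) {
  ais <- participants$ais[match(records$participant_id,
                                participants$participant_id)]
  if (anyNA(ais)) stop("records reference unknown participants")
  by_g <- split(records, ais)
  lapply(by_g, function(r) metric_suite(confusion(r), granularity = "ais_grade"))
}

#' Analytic chance baseline
#'
#' Expected metrics of a prevalence-matched random predictor that labels
#' each muscle responder independently with probability `pi = n_pos / n`:
#' accuracy `pi^2 + (1-pi)^2`, precision = recall = `pi`, TNR = `1-pi`,
#' macro F1 = 0.5 and MCC = 0.
#'
#' @param n total number of muscles.
#' @param n_pos number of true responders (must satisfy `0 < n_pos < n`).
#' @return a `metrics_report`.
#' @export
chance_baseline <- function(n, n_pos) {
  if (n_pos <= 0 || n_pos >= n)
    stop("degenerate prevalence: need 0 < n_pos < n")
  p <- n_pos / n
  structure(list(mcc = 0, macro_f1 = 0.5,
                 accuracy = p^2 + (1 - p)^2, precision = p,
                 recall_tpr = p, tnr = 1 - p, n = n, n_pos = n_pos,
                 granularity = "chance"),
            class = "metrics_report")
}

#' Reconstruct a confusion matrix from printed metrics
#'
#' Exhaustive search over integer `TP` and `FP` for the confusion matrix
#' whose precision, recall and TNR round (half-up, 2 decimals) to the
#' printed values. Used to recover full confusion matrices, and hence MCC,
#' macro F1 and accuracy, from a published results table.
#'
#' @param n total muscles; `n_pos` true positives in the data.
#' @param n_pos number of positive-class muscles.
#' @param precision_2dp,recall_2dp,tnr_2dp printed 2-decimal metrics.
#' @return unique [confusion_counts()]; errors if no or multiple integer
#'   solutions exist.
#' @export
reconstruct_confusion <- function(n, n_pos, precision_2dp, recall_2dp, tnr_2dp) {
  n_neg <- n - n_pos
  hits <- list()
  for (tp in 0:n_pos) {
    fn <- n_pos - tp
    for (fp in 0:n_neg) {
      tn <- n_neg - fp
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec <- tp / n_pos
      tnr <- tn / n_neg
      if (round_half_up(prec) == precision_2dp &&
          round_half_up(rec) == recall_2dp &&
          round_half_up(tnr) == tnr_2dp) {
        hits[[length(hits) + 1]] <- confusion_counts(tp, fp, fn, tn)
      }
    }
  }
  if (length(hits) == 0)
    stop("no integer confusion matrix matches the printed metrics")
  if (length(hits) > 1)
    stop(sprintf("ambiguous: %d confusion matrices match the printed metrics",
                 length(hits)))
  hits[[1]]
}
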