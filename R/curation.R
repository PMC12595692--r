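#' Curated feature set definitions
#'
#' The five feature sets compared in the pipeline:
#' \itemize{
#'   \item \strong{Full}: all 24 sEMG features (histogram expanded to bins).
#'   \item \strong{Hudgins}: MAV, ZERC, SSC, wLen -- the classic
#'     myoelectric-control set.
#'   \item \strong{MD}: ZERC, SSC, wAmp, MedF, EMGH, ARCO3 -- features that
#'     separate motor-neuron damage phenotypes after SCI.
#'   \item \strong{PCA}: Full set reduced by principal components retaining
#'     90\% of training variance.
#'   \item \strong{FWD}: Full set reduced by greedy forward selection.
#'   \item \strong{Clinical}: candidate clinical variables (months post
#'     injury, AIS, NLI, myotome, distance, baseline MMT, proximity),
#'     typically combined with forward selection.
#' }
#'
#' @param name one of `"Full"`, `"Hudgins"`, `"MD"`, `"PCA"`, `"FWD"`,
#'   `"Clinical"`.
#' @param cfg a [feature_config()] (fixes the histogram bin count).
#' @return object of class `feature_set_spec`: list with `name`, `columns`
#'   (explicit columns, or the Full columns for PCA/FWD) and `transform`
#'   (`"none"`, `"pca"` or `"forward_selection"`).
#' @export
feature_set_spec <- function(name = c("Full", "Hudgins", "MD", "PCA", "FWD",
                                      "Clinical"),
                             cfg = feature_config()) {
  name <- match.arg(name)
  emgh <- paste0("EMGH_", seq_len(cfg$hist_bins))
  full <- feature_names(cfg)
  def <- switch(name,
    Full = list(columns = full, transform = "none"),
    Hudgins = list(columns = c("MAV", "ZERC", "SSC", "wLen"), transform = "none"),
    MD = list(columns = c("ZERC", "SSC", "wAmp", "MedF", emgh, "ARCO3"),
              transform = "none"),
    PCA = list(columns = full, transform = "pca"),
    FWD = list(columns = full, transform = "forward_selection"),
    Clinical = list(columns = clinical_variables(), transform = "forward_selection")
  )
  structure(c(list(name = name), def, list(var_frac = 0.90)),
            class = "feature_set_spec")
}

#' Candidate clinical variable names
#' @return character vector of the ordinal/numeric clinical covariates.
#' @export
clinical_variables <- function() {
  c("months_post_injury", "ais", "nli", "myotome", "distance",
    "baseline_mmt", "proximity")
}

#' Select the named columns of a feature set
#'
#' @param feature_matrix data frame or matrix holding (at least) the
#'   requested columns; `EMGH` is expected already expanded to its bins.
#' @param spec a [feature_set_spec()] (or character vector of columns).
#' @return the column subset, in spec order.
#' @export
select_named_set <- function(feature_matrix, spec) {
  cols <- if (inherits(spec, "feature_set_spec")) spec$columns else spec
  missing <- setdiff(cols, colnames(feature_matrix))
  if (length(missing) > 0)
    stop("feature matrix is missing columns: ", paste(missing, collapse = ", "))
  feature_matrix[, cols, drop = FALSE]
}

#' PCA reduction fitted on training rows only
#'
#' Columns are z-scored by training statistics, principal components are
#' fitted on training rows, and the smallest number of components whose
#' cumulative explained variance reaches `var_frac` is retained. Evaluation
#' rows are projected with the training loadings -- no evaluation-fold
#' leakage. Zero-variance training columns are dropped with a warning.
#'
#' @param train_matrix,eval_matrix numeric matrices/data frames with the
#'   same columns.
#' @param var_frac fraction of variance to retain (default 0.90).
#' @return list with `scores_train`, `scores_eval`, `n_components`,
#'   `explained` (cumulative variance fractions) and the fitted `prcomp`
#'   object.
#' @export
pca_reduce <- function(train_matrix, eval_matrix = NULL, var_frac = 0.90) {
  tr <- as.matrix(train_matrix)
  keep <- apply(tr, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(tr)[!keep], collapse = ", "))
    tr <- tr[, keep, drop = FALSE]
  }
  fit <- stats::prcomp(tr, center = TRUE, scale. = TRUE)
  cum <- cumsum(fit$sdev^2) / sum(fit$sdev^2)
  k <- which(cum >= var_frac - 1e-12)[1]
  scores_train <- fit$x[, seq_len(k), drop = FALSE]
  scores_eval <- NULL
  if (!is.null(eval_matrix)) {
    ev <- as.matrix(eval_matrix)[, keep, drop = FALSE]
    scores_eval <- stats::predict(fit, ev)[, seq_len(k), drop = FALSE]
  }
  list(scores_train = scores_train, scores_eval = scores_eval,
       n_components = k, explained = cum, fit = fit, kept_columns = keep)
}

#' Greedy forward feature selection under grouped cross-validation
#'
#' Starting from the empty set, repeatedly adds the column that maximises
#' leave-one-group-out MCC of the model built by `model_factory`, stopping
#' when no candidate strictly improves the criterion. Ties are broken by
#' column order, so selection is deterministic. Selection only ever sees
#' the rows it is given, keeping it leakage-safe when run inside an outer
#' cross-validation training partition.
#'
#' @param train_data data frame/matrix of candidate columns.
#' @param labels factor/character labels (`"responder"`/`"non_responder"`).
#' @param groups grouping vector (participant ids) for the nested
#'   leave-one-group-out evaluation.
#' @param model_factory function `(x, y)` returning an object with a
#'   `predict(object, newx)` method yielding labels; defaults to
#'   logistic regression.
#' @param min_gain minimal strict improvement in nested MCC to accept a
#'   further column.
#' @return list with `selected` (ordered column names), `path` (nested MCC
#'   after each accepted column) and `criterion`.
#' @export
forward_select <- function(train_data, labels, groups,
                           model_factory = NULL, min_gain = 1e-8) {
  x <- as.data.frame(train_data)
  y <- as.character(labels)
  if (length(unique(y)) < 2)
    stop("forward selection needs both classes in the training labels")
  if (length(unique(groups)) < 2)
    stop("forward selection needs at least 2 groups")
  if (is.null(model_factory))
    model_factory <- function(xx, yy) responder_model(xx, yy, model_config("logistic"))
  nested_mcc <- function(cols) {
    records <- data.frame(true_label = y, final_label = NA_character_,
                          stringsAsFactors = FALSE)
    for (g in unique(groups)) {
      te <- groups == g
      ytr <- y[!te]
      if (length(unique(ytr)) < 2) next
      fit <- model_factory(x[!te, cols, drop = FALSE], ytr)
      records$final_label[te] <-
        as.character(stats::predict(fit, x[te, cols, drop = FALSE]))
    }
    ok <- !is.na(records$final_label)
    if (!any(ok)) return(-Inf)
    mcc(confusion(records[ok, ]))
  }
  selected <- character(0)
  best <- -Inf
  path <- numeric(0)
  remaining <- colnames(x)
  repeat {
    scores <- vapply(remaining, function(col) nested_mcc(c(selected, col)),
                     numeric(1))
    if (length(scores) == 0) break
    top <- which.max(scores)  # first maximum: lexical (column-order) tie-break
    if (scores[top] <= best + min_gain) break
    best <- scores[top]
    selected <- c(selected, remaining[top])
    path <- c(path, best)
    remaining <- remaining[-top]
  }
  list(selected = selected, path = path, criterion = "nested LOGO MCC")
}
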