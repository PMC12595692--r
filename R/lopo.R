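#' Build the per-trial feature table of a cohort
#'
#' Runs the full front end on every MVC trial: preprocessing (offset
#' removal, bandpass, notch), steady-state segment extraction, and the
#' 24-feature bank; attaches ordinally encoded clinical covariates
#' (AIS A<B<C<D, NLI C2<..<C6, myotome C5<..<C8) and the Kendall-tau
#' responder label derived from the muscle's MMT trajectory.
#'
#' @param cohort an `fes_cohort`.
#' @param prep_cfg a [prep_config()].
#' @param feat_cfg a [feature_config()].
#' @param label_cfg a [label_config()].
#' @return data frame with identifier columns (`muscle_id`,
#'   `participant_id`, `trial_index`), `true_label`, `excluded`, clinical
#'   columns and one column per expanded feature.
#' @export
build_feature_table <- function(cohort, prep_cfg = prep_config(),
                                feat_cfg = feature_config(),
                                label_cfg = label_config()) {
  labels <- label_cohort(cohort, label_cfg)
  pidx <- match(cohort$muscles$participant_id,
                cohort$participants$participant_id)
  rows <- list()
  for (i in seq_len(nrow(cohort$muscles))) {
    mid <- cohort$muscles$muscle_id[i]
    lab <- labels[labels$muscle_id == mid, ]
    clin <- data.frame(
      months_post_injury = cohort$participants$months_post_injury[pidx[i]],
      ais = match(cohort$participants$ais[pidx[i]], c("A", "B", "C", "D")),
      nli = as.integer(sub("C", "", cohort$participants$nli[pidx[i]])),
      myotome = as.integer(sub("C", "", cohort$muscles$myotome[i])),
      distance = cohort$muscles$distance[i],
      baseline_mmt = cohort$muscles$baseline_mmt[i],
      proximity = cohort$muscles$proximity[i]
    )
    for (tr in cohort$trials[[mid]]) {
      if (tr$condition != "mvc") next
      seg <- extract_steady_segment(preprocess(tr, prep_cfg), prep_cfg)
      fv <- extract_feature_vector(seg, feat_cfg)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(muscle_id = mid,
                   participant_id = cohort$muscles$participant_id[i],
                   trial_index = tr$trial_index,
                   true_label = lab$label, excluded = lab$excluded,
                   stringsAsFactors = FALSE),
        clin, as.data.frame(as.list(fv)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table as delimited text
#' @param features feature table from [build_feature_table()].
#' @param path output CSV path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Leave-one-participant-out folds
#'
#' @param participant_ids vector of participant ids, one entry per row of
#'   the data being folded (or an `fes_cohort`, folded over its muscles).
#' @return list of folds, each with `participant`, `train` and `test`
#'   row indices.
#' @export
lopo_folds <- function(participant_ids) {
  if (inherits(participant_ids, "fes_cohort"))
    participant_ids <- participant_ids$muscles$participant_id
  ids <- unique(participant_ids)
  if (length(ids) < 2) stop("LOPO needs at least 2 participants")
  lapply(ids, function(p) {
    list(participant = p,
         train = which(participant_ids != p),
         test = which(participant_ids == p))
  })
}

#' Aggregate trial votes into a muscle label
#'
#' Majority vote over per-trial predicted labels; an exact tie is resolved
#' to `"non_responder"` (conservative toward the majority class).
#'
#' @param trial_votes character vector of per-trial labels.
#' @return single label.
#' @export
aggregate_votes <- function(trial_votes) {
  if (length(trial_votes) == 0) stop("no trial votes to aggregate")
  n_resp <- sum(trial_votes == "responder")
  if (n_resp > length(trial_votes) / 2) "responder" else "non_responder"
}

# Curate train/test feature matrices for one fold according to the spec.
curate_fold <- function(spec, train_x, test_x, train_y, train_groups,
                        fwd_factory = NULL) {
  if (spec$transform == "none") {
    cols <- spec$columns
    list(train = select_named_set(train_x, cols),
         test = select_named_set(test_x, cols),
         info = list(columns = cols))
  } else if (spec$transform == "pca") {
    red <- suppressWarnings(
      pca_reduce(select_named_set(train_x, spec$columns),
                 select_named_set(test_x, spec$columns), spec$var_frac))
    list(train = as.data.frame(red$scores_train),
         test = as.data.frame(red$scores_eval),
         info = list(n_components = red$n_components))
  } else {
    sel <- forward_select(select_named_set(train_x, spec$columns),
                          train_y, train_groups, model_factory = fwd_factory)
    cols <- sel$selected
    if (length(cols) == 0) cols <- spec$columns[1]
    list(train = train_x[, cols, drop = FALSE],
         test = test_x[, cols, drop = FALSE],
         info = list(columns = cols, path = sel$path))
  }
}

# Muscle-level MCC of predictions on a feature-table subset.
muscle_mcc <- function(tbl, pred) {
  by_m <- split(seq_len(nrow(tbl)), tbl$muscle_id)
  rec <- data.frame(
    true_label = vapply(by_m, function(ix) tbl$true_label[ix[1]], ""),
    final_label = vapply(by_m, function(ix) aggregate_votes(pred[ix]), ""))
  mcc(confusion(rec))
}

#' Evaluate a classifier family under LOPO cross-validation
#'
#' For each held-out participant: the feature-set curation (column subset,
#' PCA, or forward selection) is fitted on the training participants only;
#' each grid configuration of the family is scored by nested
#' leave-one-participant-out MCC inside the training partition and the
#' winner refitted on all training trials; all of the held-out
#' participant's trials are predicted and per-muscle labels obtained by
#' trial-vote aggregation.
#'
#' @param features feature table from [build_feature_table()] (excluded
#'   muscles are dropped automatically).
#' @param featureset a [feature_set_spec()] or its name.
#' @param family classifier family (see [model_config()]).
#' @param seed seed controlling stochastic fits.
#' @param select_on_test if `TRUE`, mirror the optimistic literal protocol
#'   of picking the grid configuration on held-out-fold performance instead
#'   of nested training-side MCC.
#' @param fwd_factory model factory for nested forward selection (default:
#'   logistic regression).
#' @param feat_cfg a [feature_config()] (column naming for named sets).
#' @return object of class `lopo_result` with muscle-level `records`,
#'   trial-level `trial_votes`, and per-fold curation/grid info.
#' @export
run_lopo <- function(features, featureset = "Full", family = "rf",
                     seed = 1L, select_on_test = FALSE, fwd_factory = NULL,
                     feat_cfg = feature_config()) {
  if (is.character(featureset)) featureset <- feature_set_spec(featureset, feat_cfg)
  tbl <- features[!features$excluded, , drop = FALSE]
  if (nrow(tbl) == 0) stop("no non-excluded muscles in the feature table")
  grid <- model_grid(family, seed)
  folds <- lopo_folds(tbl$participant_id)
  records <- list(); trial_votes <- list(); fold_info <- list()

  for (f in folds) {
    tr <- tbl[f$train, , drop = FALSE]
    te <- tbl[f$test, , drop = FALSE]
    if (length(unique(tr$true_label)) < 2) {
      fold_info[[f$participant]] <- list(skipped = "single-class training fold")
      next
    }
    cur <- curate_fold(featureset, tr, te, tr$true_label, tr$participant_id,
                       fwd_factory)
    pick <- 1L
    if (length(grid) > 1) {
      scores <- vapply(grid, function(cfg) {
        if (select_on_test) {
          fit <- responder_model(cur$train, tr$true_label, cfg)
          muscle_mcc(te, stats::predict(fit, cur$test))
        } else {
          inner <- lopo_folds(tr$participant_id)
          preds <- rep(NA_character_, nrow(tr))
          for (g in inner) {
            ytr <- tr$true_label[g$train]
            if (length(unique(ytr)) < 2) next
            fit <- responder_model(cur$train[g$train, , drop = FALSE], ytr, cfg)
            preds[g$test] <- stats::predict(fit, cur$train[g$test, , drop = FALSE])
          }
          ok <- !is.na(preds)
          if (!any(ok)) return(-Inf)
          muscle_mcc(tr[ok, , drop = FALSE], preds[ok])
        }
      }, numeric(1))
      pick <- which.max(scores)  # first maximum: listed grid order breaks ties
    }
    cfg <- grid[[pick]]
    fit <- responder_model(cur$train, tr$true_label, cfg)
    pred <- stats::predict(fit, cur$test)
    by_m <- split(seq_len(nrow(te)), te$muscle_id)
    for (mid in names(by_m)) {
      ix <- by_m[[mid]]
      records[[mid]] <- data.frame(
        muscle_id = mid, participant_id = f$participant,
        true_label = te$true_label[ix[1]],
        final_label = aggregate_votes(pred[ix]),
        n_trials = length(ix), stringsAsFactors = FALSE)
      trial_votes[[mid]] <- data.frame(
        muscle_id = mid, trial_index = te$trial_index[ix],
        vote = pred[ix], stringsAsFactors = FALSE)
    }
    fold_info[[f$participant]] <- c(cur$info, list(grid_pick = pick,
                                                   config = cfg))
  }
  if (length(records) == 0) stop("every fold was skipped")
  structure(list(records = do.call(rbind, c(records, make.row.names = FALSE)),
                 trial_votes = do.call(rbind, c(trial_votes,
                                                make.row.names = FALSE)),
                 fold_info = fold_info, featureset = featureset$name,
                 family = family, seed = seed),
            class = "lopo_result")
}

#' Run LOPO within an AIS motor-completeness subgroup
#'
#' Restricts training and evaluation to the participants of one stratum:
#' `"A-B"` (motor complete), `"C-D"` (motor incomplete), or `"A-D"` (all
#' participants; identical to [run_lopo()] on the full table).
#'
#' @param features feature table.
#' @param participants participant data frame with `participant_id`, `ais`.
#' @param subgroup `"A-B"`, `"C-D"` or `"A-D"`.
#' @param ... passed to [run_lopo()].
#' @return an `lopo_result`.
#' @export
subgroup_run <- function(features, participants,
                         subgroup = c("A-D", "A-B", "C-D"), ...) {
  subgroup <- match.arg(subgroup)
  grades <- switch(subgroup, "A-B" = c("A", "B"), "C-D" = c("C", "D"),
                   "A-D" = c("A", "B", "C", "D"))
  keep_p <- participants$participant_id[participants$ais %in% grades]
  if (length(keep_p) < 2)
    stop("subgroup contains fewer than 2 participants")
  out <- run_lopo(features[features$participant_id %in% keep_p, , drop = FALSE],
                  ...)
  out$subgroup <- subgroup
  out
}

#' @export
print.lopo_result <- function(x, ...) {
  rep <- metric_suite(confusion(x$records))
  cat(sprintf("LOPO evaluation: %s feature set, %s classifier%s\n",
              x$featureset, x$family,
              if (!is.null(x$subgroup)) paste0(", subgroup ", x$subgroup) else ""))
  cat(sprintf("  %d muscles from %d participants\n", nrow(x$records),
              length(unique(x$records$participant_id))))
  print(rep)
  invisible(x)
}

#' @export
summary.lopo_result <- function(object, participants = NULL, ...) {
  out <- list(overall = metric_suite(confusion(object$records)),
              per_participant = participant_metrics(object$records))
  if (!is.null(participants))
    out$per_ais <- ais_breakdown(object$records, participants)
  class(out) <- "summary.lopo_result"
  out
}

#' @export
print.summary.lopo_result <- function(x, ...) {
  print(x$overall)
  cat(sprintf("Per-participant MCC: mean %.2f (SD %.2f) over %d participants\n",
              mean(vapply(x$per_participant, `[[`, 1, "mcc")),
              stats::sd(vapply(x$per_participant, `[[`, 1, "mcc")),
              length(x$per_participant)))
  if (!is.null(x$per_ais)) {
    for (g in names(x$per_ais)) {
      cat(sprintf("AIS %s: ", g)); print(x$per_ais[[g]])
    }
  }
  invisible(x)
}
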