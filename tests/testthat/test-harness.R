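test_that("LOPO folds partition muscles by participant", {
  ids <- rep(sprintf("P%02d", 1:17), times = sample(4:10, 17, replace = TRUE))
  folds <- lopo_folds(ids)
  expect_length(folds, 17)
  test_idx <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(test_idx, seq_along(ids))  # every row in exactly one test fold
  expect_equal(sum(lengths(lapply(folds, `[[`, "test"))), length(ids))
  for (f in folds) {
    expect_length(intersect(ids[f$train], ids[f$test]), 0)
  }
  expect_error(lopo_folds(rep("P01", 5)), "at least 2")
})

test_that("trial votes aggregate by majority with a conservative tie rule", {
  R <- "responder"; N <- "non_responder"
  expect_equal(aggregate_votes(c(R, R, N)), R)
  expect_equal(aggregate_votes(c(R, N)), N)          # exact tie -> negative class
  expect_equal(aggregate_votes(c(N, N, N, R)), N)
  expect_equal(aggregate_votes(R), R)
  expect_error(aggregate_votes(character(0)), "no trial votes")
})

make_harness_data <- function(n = 60, seed = 14) {
  set.seed(seed)
  y <- rep(c("responder", "non_responder"), length.out = n)
  x <- data.frame(f1 = ifelse(y == "responder", 1.5, -1.5) + rnorm(n, sd = 0.4),
                  f2 = rnorm(n), f3 = rnorm(n))
  list(x = x, y = y)
}

test_that("classifier wrappers fit, predict, and respect determinism", {
  d <- make_harness_data()
  for (family in c("knn", "rf", "gb", "svm", "logistic")) {
    cfg <- model_grid(family, seed = 4)[[1]]
    fit <- responder_model(d$x, d$y, cfg)
    pred <- predict(fit, d$x)
    expect_true(all(pred %in% c("responder", "non_responder")))
    expect_gt(mean(pred == d$y), 0.8)  # separable training data
    fit2 <- responder_model(d$x, d$y, cfg)
    expect_identical(pred, predict(fit2, d$x))
  }
  expect_error(responder_model(d$x, rep("responder", nrow(d$x))),
               "single class")
})

test_that("LOPO runs are deterministic and leakage-free", {
  ft <- strong_cohort()$features
  r1 <- run_lopo(ft, "Hudgins", "logistic", seed = 3)
  r2 <- run_lopo(ft, "Hudgins", "logistic", seed = 3)
  expect_identical(r1$records, r2$records)
  # no-leakage: the fold model must equal a model fitted manually on the
  # training participants only
  p <- r1$records$participant_id[1]
  tr <- ft[!ft$excluded & ft$participant_id != p, ]
  te <- ft[!ft$excluded & ft$participant_id == p, ]
  cols <- feature_set_spec("Hudgins")$columns
  fit <- responder_model(tr[, cols], tr$true_label, model_config("logistic", seed = 3))
  manual <- vapply(split(seq_len(nrow(te)), te$muscle_id), function(ix)
    aggregate_votes(predict(fit, te[ix, cols])), character(1))
  got <- r1$records$final_label[match(names(manual), r1$records$muscle_id)]
  expect_equal(unname(manual), got)
})

test_that("stochastic families are reproducible under a fixed seed", {
  ft <- strong_cohort()$features
  r1 <- run_lopo(ft, "Full", "rf", seed = 5)
  r2 <- run_lopo(ft, "Full", "rf", seed = 5)
  expect_identical(r1$records, r2$records)
  expect_identical(vapply(r1$fold_info, `[[`, 1L, "grid_pick"),
                   vapply(r2$fold_info, `[[`, 1L, "grid_pick"))
})

test_that("subgroup A-D equals the full run and strata cover the cohort", {
  sc <- strong_cohort()
  ft <- sc$features
  participants <- sc$cohort$participants
  full <- run_lopo(ft, "Hudgins", "logistic", seed = 2)
  ad <- subgroup_run(ft, participants, "A-D", featureset = "Hudgins",
                     family = "logistic", seed = 2)
  expect_equal(ad$records, full$records)
  ab <- subgroup_run(ft, participants, "A-B", featureset = "Hudgins",
                     family = "logistic", seed = 2)
  cd <- subgroup_run(ft, participants, "C-D", featureset = "Hudgins",
                     family = "logistic", seed = 2)
  expect_setequal(c(ab$records$muscle_id, cd$records$muscle_id),
                  full$records$muscle_id)
})

test_that("curated feature sets run end to end inside the harness", {
  ft <- strong_cohort()$features
  pca <- run_lopo(ft, "PCA", "logistic", seed = 6)
  expect_true(all(vapply(pca$fold_info, function(i)
    is.numeric(i$n_components) && i$n_components >= 1, logical(1))))
  fwd <- run_lopo(ft, "FWD", "logistic", seed = 6)
  expect_true(all(vapply(fwd$fold_info, function(i)
    length(i$columns) >= 1, logical(1))))
  expect_gt(metric_suite(confusion(fwd$records))$mcc, 0.3)
  clin <- run_lopo(ft, "Clinical", "logistic", seed = 6)
  expect_true(all(unlist(lapply(clin$fold_info, `[[`, "columns")) %in%
                  clinical_variables()))
})

test_that("grid selection reports the chosen configuration per fold", {
  ft <- strong_cohort()$features
  res <- run_lopo(ft, "Hudgins", "svm", seed = 9)
  picks <- vapply(res$fold_info, `[[`, 1L, "grid_pick")
  expect_true(all(picks %in% 1:2))
  res_t <- run_lopo(ft, "Hudgins", "svm", seed = 9, select_on_test = TRUE)
  expect_s3_class(res_t, "lopo_result")
})
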