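CLASS_LEVELS <- c("non_responder", "responder")

#' Classifier configuration
#'
#' One point of the (deliberately small) hyperparameter space explored per
#' classifier family: k-nearest neighbours with k in 2..7 under euclidean
#' or cosine distance with distance weighting; random forest and gradient
#' boosting with 100 or 200 estimators; support vector machines with linear
#' or gaussian kernel; plain logistic regression.
#'
#' @param family `"knn"`, `"rf"`, `"gb"`, `"svm"` or `"logistic"`.
#' @param k neighbours (knn only).
#' @param metric `"euclidean"` or `"cosine"` (knn only).
#' @param n_estimators trees/boosting rounds (rf/gb only).
#' @param kernel `"linear"` or `"gaussian"` (svm only).
#' @param seed seed fixing stochastic fits.
#' @param standardize z-score features with training statistics before
#'   distance/margin classifiers (trees always consume raw features).
#' @return object of class `model_config`.
#' @export
model_config <- function(family = c("knn", "rf", "gb", "svm", "logistic"),
                         k = 5, metric = c("euclidean", "cosine"),
                         n_estimators = 100,
                         kernel = c("linear", "gaussian"),
                         seed = 1L, standardize = TRUE) {
  family <- match.arg(family)
  structure(list(family = family, k = k, metric = match.arg(metric),
                 n_estimators = n_estimators, kernel = match.arg(kernel),
                 seed = as.integer(seed), standardize = standardize),
            class = "model_config")
}

#' Hyperparameter grid of a classifier family
#'
#' @param family classifier family name.
#' @param seed seed propagated to every grid point.
#' @return list of [model_config()] objects in canonical grid order.
#' @export
model_grid <- function(family = c("knn", "rf", "gb", "svm", "logistic"),
                       seed = 1L) {
  family <- match.arg(family)
  switch(family,
    knn = {
      g <- expand.grid(k = 2:7, metric = c("euclidean", "cosine"),
                       stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i)
        model_config("knn", k = g$k[i], metric = g$metric[i], seed = seed))
    },
    rf = lapply(c(100, 200), function(n)
      model_config("rf", n_estimators = n, seed = seed)),
    gb = lapply(c(100, 200), function(n)
      model_config("gb", n_estimators = n, seed = seed)),
    svm = lapply(c("linear", "gaussian"), function(k)
      model_config("svm", kernel = k, seed = seed)),
    logistic = list(model_config("logistic", seed = seed))
  )
}

#' Fit a responder/non-responder classifier
#'
#' Thin uniform wrapper over the supported classifier families. Distance-
#' and margin-based families (knn, svm, logistic) see z-scored features
#' (training statistics); tree ensembles (rf, gb) see raw features.
#'
#' @param x training feature matrix / data frame (numeric columns).
#' @param y labels (`"responder"` / `"non_responder"`).
#' @param config a [model_config()].
#' @return object of class `responder_model` with a [predict] method.
#' @export
responder_model <- function(x, y, config = model_config("logistic")) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  y <- factor(as.character(y), levels = CLASS_LEVELS)
  if (anyNA(y)) stop("labels must be 'responder' or 'non_responder'")
  if (nlevels(droplevels(y)) < 2)
    stop("training data contains a single class")
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  needs_std <- config$standardize && config$family %in% c("knn", "svm", "logistic")
  if (needs_std) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale, "/")
  }
  fit <- switch(config$family,
    knn = list(x = x, y = y),
    svm = with_seed(config$seed,
      e1071::svm(x, y, kernel = if (config$kernel == "gaussian") "radial" else "linear",
                 scale = FALSE)),
    rf = with_seed(config$seed,
      randomForest::randomForest(x, y, ntree = config$n_estimators)),
    gb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y) - 1)
      with_seed(config$seed,
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         nthread = 1),
                           data = dtrain, nrounds = config$n_estimators,
                           verbose = 0))
    },
    logistic = {
      cf <- suppressWarnings(
        stats::glm.fit(cbind(1, x), as.numeric(y) - 1,
                       family = stats::binomial())$coefficients)
      cf[is.na(cf)] <- 0  # collinear columns contribute nothing
      cf
    }
  )
  structure(list(fit = fit, config = config, center = center, scale = scale,
                 standardized = needs_std, columns = colnames(x)),
            class = "responder_model")
}

#' @export
print.responder_model <- function(x, ...) {
  cfg <- x$config
  extra <- switch(cfg$family,
    knn = sprintf(" (k = %d, %s, distance-weighted)", cfg$k, cfg$metric),
    rf = sprintf(" (%d trees)", cfg$n_estimators),
    gb = sprintf(" (%d rounds)", cfg$n_estimators),
    svm = sprintf(" (%s kernel)", cfg$kernel),
    logistic = "")
  cat(sprintf("Responder classifier: %s%s, %d feature(s)\n",
              cfg$family, extra, length(x$columns)))
  invisible(x)
}

# Distance-weighted kNN vote; zero-distance neighbours dominate.
knn_predict <- function(fit, newx, k, metric) {
  tr <- fit$x
  apply(newx, 1, function(q) {
    d <- if (metric == "euclidean") {
      sqrt(colSums((t(tr) - q)^2))
    } else {
      qn <- sqrt(sum(q^2))
      tn <- sqrt(rowSums(tr^2))
      denom <- pmax(tn * qn, 1e-300)
      1 - as.numeric(tr %*% q) / denom
    }
    ord <- order(d)[seq_len(min(k, length(d)))]
    dn <- d[ord]
    if (any(dn < 1e-12)) {
      hit <- fit$y[ord][dn < 1e-12]
      return(names(which.max(table(hit))))
    }
    w <- 1 / dn
    votes <- tapply(w, fit$y[ord], sum, default = 0)
    CLASS_LEVELS[which.max(votes[CLASS_LEVELS])]
  })
}

#' Predict labels for new trials
#'
#' @param object a [responder_model()].
#' @param newdata feature matrix / data frame with the training columns.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.responder_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$columns, drop = FALSE])
  storage.mode(x) <- "double"
  if (object$standardized)
    x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  cfg <- object$config
  out <- switch(cfg$family,
    knn = knn_predict(object$fit, x, cfg$k, cfg$metric),
    svm = as.character(stats::predict(object$fit, x)),
    rf = as.character(stats::predict(object$fit, x)),
    gb = {
      p <- stats::predict(object$fit, xgboost::xgb.DMatrix(x))
      ifelse(p > 0.5, "responder", "non_responder")
    },
    logistic = {
      eta <- as.numeric(cbind(1, x) %*% object$fit)
      ifelse(eta > 0, "responder", "non_responder")
    }
  )
  unname(out)
}
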