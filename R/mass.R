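#' Split footprint records into training and test sets
#'
#' Random, seeded, disjoint and exhaustive 70/30 partition (by default) of the
#' records carrying a known body mass. `by = "subject"` (default) keeps all of
#' a subject's repeated prints on the same side of the split, avoiding leakage
#' of subject identity into the test set; `by = "print"` partitions rows
#' directly, in which case the training size is `round(fraction * n)`.
#'
#' @param records Footprint table with `body_mass_kg` known.
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed Optional integer seed.
#' @param by `"subject"` or `"print"`.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(records, fraction = 0.70, seed = NULL,
                             by = c("subject", "print")) {
  by <- match.arg(by)
  records <- records[!is.na(records$body_mass_kg), , drop = FALSE]
  n <- nrow(records)
  if (n < 10) stop("need at least 10 records with known body mass", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1 (both sets non-empty)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (by == "print") {
    n_train <- round(fraction * n)
    if (n_train == 0 || n_train == n) {
      stop("degenerate split: one partition is empty", call. = FALSE)
    }
    idx <- sample(n, n_train)
  } else {
    subs <- sample(unique(records$subject_id))
    counts <- vapply(subs, function(s) sum(records$subject_id == s), integer(1))
    cum <- cumsum(counts)
    target <- fraction * n
    k <- which.min(abs(cum - target))
    if (k == length(subs)) k <- length(subs) - 1
    if (k < 1) k <- 1
    idx <- which(records$subject_id %in% subs[seq_len(k)])
    if (length(idx) == 0 || length(idx) == n) {
      stop("degenerate split: one partition is empty", call. = FALSE)
    }
  }
  list(train = records[idx, , drop = FALSE],
       test = records[-idx, , drop = FALSE])
}

#' Fit the bagged regression-tree body-mass model
#'
#' An ensemble of `n_trees` regression trees (default 500), each grown on a
#' bootstrap sample (n draws with replacement) of the training prints, using
#' the five external print dimensions as predictors. Predictions are means
#' over trees and are therefore bounded by the training response range.
#' Out-of-bag (OOB) predictions — from trees whose bootstrap missed a given
#' print — give an internal error estimate; for n = 343 training prints the
#' expected unique in-bag count is n(1 - (1 - 1/n)^n), about 217, leaving
#' about 126 OOB.
#'
#' @param train Footprint table with the five predictor columns and
#'   `body_mass_kg`.
#' @param n_trees Number of trees (default 500).
#' @param mtry Predictors tried per split (default `ceiling(p/3)` = 2).
#' @param nodesize Minimum terminal node size (default 5).
#' @param seed Optional integer bootstrap seed, recorded in the model.
#' @return Object of class `mass_model`.
#' @export
fit_mass_model <- function(train, n_trees = 500, mtry = ceiling(5 / 3),
                           nodesize = 5, seed = NULL) {
  preds <- measurement_columns()
  missing_cols <- setdiff(c(preds, "body_mass_kg"), names(train))
  if (length(missing_cols) > 0) {
    stop("training data missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  train <- train[stats::complete.cases(train[, c(preds, "body_mass_kg")]), ,
                 drop = FALSE]
  if (nrow(train) < 2) stop("too few complete training records", call. = FALSE)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  x <- train[, preds, drop = FALSE]
  y <- train$body_mass_kg
  if (all(vapply(x, function(v) length(unique(v)) == 1, logical(1)))) {
    stop("uninformative training data: all predictors are constant",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                                   nodesize = nodesize, replace = TRUE,
                                   keep.inbag = TRUE, keep.forest = TRUE)
  inbag_unique <- colSums(rf$inbag > 0)
  oob <- rf$predicted
  rmse_oob <- sqrt(mean((oob - y)^2, na.rm = TRUE))
  structure(list(forest = rf, predictors = preds,
                 n_train = nrow(train), n_trees = n_trees,
                 training_response_range = range(y),
                 inbag_unique = inbag_unique,
                 oob_counts = nrow(train) - inbag_unique,
                 rmse_oob = rmse_oob, seed = seed),
            class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat("Bagged regression-tree body-mass model\n")
  cat(sprintf("  trees: %d   training prints: %d\n", x$n_trees, x$n_train))
  cat(sprintf("  mean unique in-bag / OOB per tree: %.1f / %.1f\n",
              mean(x$inbag_unique), mean(x$oob_counts)))
  cat(sprintf("  OOB RMSE: %.2f kg   response range: %.1f-%.1f kg\n",
              x$rmse_oob, x$training_response_range[1],
              x$training_response_range[2]))
  invisible(x)
}

#' Predict body mass from footprint measurements
#'
#' Mean over the per-tree predictions of the ensemble; always within the
#' training response range.
#'
#' @param object,model A fitted [fit_mass_model()] object.
#' @param newdata,measurements Data frame (or named vector) with the five
#'   predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted masses (kg).
#' @export
predict.mass_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols) > 0) {
    stop("measurements missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as.numeric(stats::predict(object$forest,
                            newdata[, object$predictors, drop = FALSE]))
}

#' @rdname predict.mass_model
#' @export
predict_mass <- function(model, measurements) {
  stopifnot(inherits(model, "mass_model"))
  stats::predict(model, measurements)
}

#' Predict body mass for a whole trackway
#'
#' The trackway's prints are first averaged predictor-by-predictor and the
#' model is applied once to the average print dimensions.
#'
#' @param model A fitted [fit_mass_model()].
#' @param trackway Footprint table of the trackway's prints.
#' @return Single predicted mass (kg).
#' @export
predict_trackway_mass <- function(model, trackway) {
  stopifnot(inherits(model, "mass_model"))
  preds <- model$predictors
  missing_cols <- setdiff(preds, names(trackway))
  if (length(missing_cols) > 0) {
    stop("trackway missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(trackway[, preds, drop = FALSE])
  if (!any(ok)) stop("trackway has no prints with complete measurements",
                     call. = FALSE)
  avg <- as.data.frame(as.list(colMeans(trackway[ok, preds, drop = FALSE])))
  stats::predict(model, avg)
}

#' Length-only linear benchmark
#'
#' Ordinary least-squares regression of body mass on heel-to-hallux print
#' length, the traditional single-predictor alternative to the tree ensemble.
#'
#' @param train Footprint table with `heel_to_hallux_length_cm` and
#'   `body_mass_kg`.
#' @return Object of class `length_model` wrapping the `lm` fit.
#' @export
fit_length_regression <- function(train) {
  need <- c("heel_to_hallux_length_cm", "body_mass_kg")
  train <- train[stats::complete.cases(train[, need]), , drop = FALSE]
  if (nrow(train) < 2) stop("need at least 2 records", call. = FALSE)
  if (nrow(train) < 3) {
    warning("length regression fitted on 2 points: zero residual degrees of freedom",
            call. = FALSE)
  }
  if (stats::var(train$heel_to_hallux_length_cm) == 0) {
    stop("zero variance in footprint length", call. = FALSE)
  }
  fit <- stats::lm(body_mass_kg ~ heel_to_hallux_length_cm, data = train)
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 n_train = nrow(train)),
            class = "length_model")
}

#' @export
print.length_model <- function(x, ...) {
  cat(sprintf("Length-only mass regression: mass = %.3f + %.3f * length (n = %d)\n",
              x$coefficients[1], x$coefficients[2], x$n_train))
  invisible(x)
}

#' @export
predict.length_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- as.data.frame(as.list(newdata))
  as.numeric(stats::predict(object$fit, newdata))
}

rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

#' Evaluate the ensemble against the length-only benchmark
#'
#' Computes test-set RMSE of the tree ensemble and of the length-only linear
#' regression on the identical test rows, together with the ensemble's OOB
#' RMSE.
#'
#' @param model A [fit_mass_model()] fit.
#' @param linear_model A [fit_length_regression()] fit.
#' @param test Test footprint table (disjoint from training).
#' @return Object of class `mass_evaluation` with fields `rmse_oob`,
#'   `rmse_test`, `rmse_linear_test`, `n_train`, `n_test`.
#' @export
evaluate_mass_models <- function(model, linear_model, test) {
  stopifnot(inherits(model, "mass_model"), inherits(linear_model, "length_model"))
  keep <- stats::complete.cases(test[, c(model$predictors, "body_mass_kg")])
  test <- test[keep, , drop = FALSE]
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  y <- test$body_mass_kg
  structure(list(rmse_oob = model$rmse_oob,
                 rmse_test = rmse(stats::predict(model, test), y),
                 rmse_linear_test = rmse(stats::predict(linear_model, test), y),
                 n_train = model$n_train, n_test = nrow(test)),
            class = "mass_evaluation")
}

#' @export
print.mass_evaluation <- function(x, ...) {
  cat("Body-mass model evaluation\n")
  cat(sprintf("  n train / test: %d / %d\n", x$n_train, x$n_test))
  cat(sprintf("  ensemble test RMSE:     %.2f kg (OOB %.2f kg)\n",
              x$rmse_test, x$rmse_oob))
  cat(sprintf("  length-only test RMSE:  %.2f kg\n", x$rmse_linear_test))
  invisible(x)
}
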