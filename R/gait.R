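#' Fit the walking/running gait classifier
#'
#' A bagged classification-tree ensemble on the five external print dimensions
#' plus the 14 regional depths (19 features), used to gait-match the human
#' comparison pool before the trackway resampling comparison. The out-of-bag
#' error rate is reported with the fit.
#'
#' @param records Footprint table with a `gait` column (`"walking"` /
#'   `"running"`, both classes present), the measurement columns and the 14
#'   depth columns.
#' @param n_trees Number of trees (default 500).
#' @param seed Optional integer seed.
#' @return Object of class `gait_classifier`.
#' @export
fit_gait_classifier <- function(records, n_trees = 500, seed = NULL) {
  features <- c(measurement_columns(), depth_columns())
  missing_cols <- setdiff(c(features, "gait"), names(records))
  if (length(missing_cols) > 0) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(records[, features]) &
    records$gait %in% c("walking", "running")
  records <- records[keep, , drop = FALSE]
  y <- factor(records$gait, levels = c("walking", "running"))
  if (nlevels(droplevels(y)) < 2) {
    stop("gait classifier needs both walking and running examples",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = records[, features, drop = FALSE],
                                   y = y, ntree = n_trees)
  structure(list(forest = rf, features = features,
                 n_train = nrow(records), n_trees = n_trees,
                 oob_error = as.numeric(rf$err.rate[n_trees, "OOB"]),
                 seed = seed),
            class = "gait_classifier")
}

#' @export
print.gait_classifier <- function(x, ...) {
  cat(sprintf("Gait classifier: %d trees, %d training prints, OOB error %.1f%%\n",
              x$n_trees, x$n_train, 100 * x$oob_error))
  invisible(x)
}

#' Predict the gait of a trackway
#'
#' Each print is classified individually; the trackway label is the majority
#' vote across prints, with ties broken toward walking (and noted). The
#' reported probability is the winning vote fraction, hence in [0.5, 1].
#'
#' @param classifier A fitted [fit_gait_classifier()].
#' @param trackway Footprint table of the trackway's prints (all 19 feature
#'   columns required).
#' @return Object of class `gait_label`: `value`, `probability`, `n_prints`,
#'   `tie`.
#' @export
predict_gait <- function(classifier, trackway) {
  stopifnot(inherits(classifier, "gait_classifier"))
  missing_cols <- setdiff(classifier$features, names(trackway))
  if (length(missing_cols) > 0) {
    stop("trackway missing feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- stats::complete.cases(trackway[, classifier$features, drop = FALSE])
  if (!any(ok)) stop("trackway has no prints with complete features",
                     call. = FALSE)
  per_print <- stats::predict(classifier$forest,
                              trackway[ok, classifier$features, drop = FALSE])
  n_walk <- sum(per_print == "walking")
  n <- length(per_print)
  tie <- (n_walk * 2 == n)
  value <- if (n_walk * 2 >= n) "walking" else "running"
  if (tie) {
    message("gait vote tied for trackway; defaulting to walking")
  }
  structure(list(value = value,
                 probability = max(n_walk, n - n_walk) / n,
                 n_prints = n, tie = tie),
            class = "gait_label")
}

#' @export
print.gait_label <- function(x, ...) {
  cat(sprintf("Predicted gait: %s (vote fraction %.2f over %d prints%s)\n",
              x$value, x$probability, x$n_prints,
              if (x$tie) ", tie broken toward walking" else ""))
  invisible(x)
}
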