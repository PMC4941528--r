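# Normalise depth-profile input (table with canonical depth columns, matrix
# with region-named columns, or list of named vectors) to an n x 14 matrix.
as_profile_matrix <- function(x) {
  regions <- depth_regions()
  if (is.list(x) && !is.data.frame(x) && is.null(dim(x))) {
    x <- do.call(rbind, lapply(x, function(p) p[regions]))
  }
  if (is.data.frame(x)) {
    m <- depth_matrix(x)
    if (is.null(m)) {
      if (all(regions %in% names(x))) {
        m <- as.matrix(x[, regions, drop = FALSE])
      } else {
        stop("no 14-region depth columns found in input", call. = FALSE)
      }
    }
    x <- m
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x)) && all(regions %in% colnames(x))) {
    x <- x[, regions, drop = FALSE]
  }
  if (ncol(x) != 14) stop("depth profiles must have 14 regions", call. = FALSE)
  colnames(x) <- regions
  x
}

#' Average footprint topography
#'
#' Element-wise mean of a set of 14-region depth profiles: the "average
#' topography" entering every Mahalanobis comparison.
#'
#' @param profiles Profiles as a footprint table (canonical depth columns),
#'   a numeric matrix, or a list of named 14-vectors.
#' @return Named numeric 14-vector.
#' @export
mean_profile <- function(profiles) {
  m <- as_profile_matrix(profiles)
  if (nrow(m) == 0) stop("cannot average an empty set of profiles", call. = FALSE)
  colMeans(m)
}

#' Covariance of a profile pool
#'
#' Sample covariance, or Ledoit-Wolf shrinkage toward the scaled identity:
#' `(1 - lambda) S + lambda mu I` with the analytic shrinkage intensity.
#' Shrinkage guards against ill-conditioned estimates when a gait-matched
#' pool is small relative to the 14 dimensions.
#'
#' @param x Profile matrix or table (rows = prints).
#' @param estimator `"sample"` or `"shrinkage"`.
#' @return 14 x 14 covariance matrix.
#' @export
cov_profiles <- function(x, estimator = c("sample", "shrinkage")) {
  estimator <- match.arg(estimator)
  X <- as_profile_matrix(x)
  S <- stats::cov(X)
  if (estimator == "sample") return(S)
  n <- nrow(X)
  p <- ncol(X)
  mu <- sum(diag(S)) / p
  delta2 <- sum((S - mu * diag(p))^2) / p
  Xc <- sweep(X, 2, colMeans(X))
  beta2 <- 0
  for (k in seq_len(n)) {
    beta2 <- beta2 + sum((tcrossprod(Xc[k, ]) - S)^2)
  }
  beta2 <- beta2 / (n^2 * p)
  lambda <- if (delta2 > 0) min(1, beta2 / delta2) else 1
  (1 - lambda) * S + lambda * mu * diag(p)
}

#' Mahalanobis distance between depth topographies
#'
#' `sqrt((x - center)' cov^{-1} (x - center))`, computed via the Cholesky
#' factor of the covariance. A singular (or non-positive-definite) covariance
#' raises an error naming the regions dominating the deficient directions;
#' use the shrinkage estimator in [cov_profiles()] to regularise small pools.
#'
#' @param x,center Named numeric vectors (same regions).
#' @param cov Symmetric positive-definite covariance matrix.
#' @return Non-negative distance (dimensionless, covariance-scaled).
#' @export
mahalanobis_distance <- function(x, center, cov) {
  x <- as.numeric(x); center <- as.numeric(center)
  if (length(x) != length(center) || length(x) != nrow(cov)) {
    stop("dimension mismatch between profiles and covariance", call. = FALSE)
  }
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("covariance matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(x - center)) == 0) return(0)  # coincident points: distance 0
  R <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(R)) {
    ev <- eigen(cov, symmetric = TRUE)
    tol <- 1e-10 * max(abs(ev$values))
    bad <- which(ev$values <= tol)
    dirs <- vapply(bad, function(j) {
      v <- ev$vectors[, j]
      nm <- if (!is.null(rownames(cov))) rownames(cov) else
        paste0("dim", seq_len(nrow(cov)))
      nm[which.max(abs(v))]
    }, character(1))
    stop("singular covariance: deficient direction(s) dominated by ",
         paste(unique(dirs), collapse = ", "),
         " (consider the shrinkage estimator)", call. = FALSE)
  }
  z <- backsolve(R, x - center, transpose = TRUE)
  sqrt(sum(z^2))
}

#' Subject-level resampling null distribution
#'
#' Builds the null distribution of Mahalanobis distances that random human
#' samples, equivalent in size to a fossil trackway, fall from the average
#' out-of-sample human footprint. Per iteration: (1) draw one subject
#' uniformly among eligible subjects; (2) sample `n_prints` of that subject's
#' prints (without replacement by default; subjects with too few prints are
#' ineligible in that mode); (3) average their topographies; (4) compute the
#' mean and covariance of all prints of the *remaining* subjects; (5) record
#' the Mahalanobis distance of the sampled average from that out-of-sample
#' mean.
#'
#' @param pool Footprint table with `subject_id` and the 14 depth columns.
#' @param n_prints Sample size per iteration (the fossil trackway's print
#'   count).
#' @param n_iterations Number of resampling iterations (default 10000).
#' @param seed Optional integer seed.
#' @param within Within-subject sampling: `"without_replacement"` (default)
#'   or `"with_replacement"`.
#' @param cov_mode `"leave_subject_out"` (default; mean and covariance
#'   recomputed from the other subjects' prints for each sampled subject) or
#'   `"pooled"` (covariance of the full pool reused; mean still
#'   leave-subject-out).
#' @param mean_mode `"per_print"` (default: grand mean over out-of-sample
#'   prints) or `"per_subject"` (mean of out-of-sample subject means).
#' @param estimator Covariance estimator, see [cov_profiles()].
#' @return Numeric vector of `n_iterations` distances, with attributes
#'   `n_prints`, `n_subjects_eligible` and `seed`.
#' @export
resample_null <- function(pool, n_prints, n_iterations = 10000, seed = NULL,
                          within = c("without_replacement", "with_replacement"),
                          cov_mode = c("leave_subject_out", "pooled"),
                          mean_mode = c("per_print", "per_subject"),
                          estimator = c("sample", "shrinkage")) {
  within <- match.arg(within)
  cov_mode <- match.arg(cov_mode)
  mean_mode <- match.arg(mean_mode)
  estimator <- match.arg(estimator)
  stopifnot(n_prints >= 1, n_iterations >= 1)
  X <- as_profile_matrix(pool)
  subj <- as.character(pool$subject_id)
  if (is.null(subj)) stop("pool must carry subject_id", call. = FALSE)
  rows_by_subject <- split(seq_len(nrow(X)), subj)
  if (length(rows_by_subject) < 3) {
    stop("resampling needs at least 3 subjects in the pool", call. = FALSE)
  }
  sizes <- lengths(rows_by_subject)
  eligible <- if (within == "without_replacement") {
    names(rows_by_subject)[sizes >= n_prints]
  } else names(rows_by_subject)
  if (length(eligible) == 0) {
    stop("no subject has enough prints (", n_prints,
         ") for without-replacement sampling", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pooled_cov <- if (cov_mode == "pooled") cov_profiles(X, estimator) else NULL
  # per-subject out-of-sample mean and Cholesky factor, precomputed
  stats_by_subject <- lapply(eligible, function(s) {
    out <- setdiff(seq_len(nrow(X)), rows_by_subject[[s]])
    mu <- if (mean_mode == "per_print") {
      colMeans(X[out, , drop = FALSE])
    } else {
      others <- setdiff(names(rows_by_subject), s)
      colMeans(do.call(rbind, lapply(others, function(o) {
        colMeans(X[rows_by_subject[[o]], , drop = FALSE])
      })))
    }
    S <- if (cov_mode == "pooled") pooled_cov
         else cov_profiles(X[out, , drop = FALSE], estimator)
    # singular covariance: fall back to the checked slow path, which returns 0
    # for exactly coincident profiles and otherwise raises the informative
    # singularity error
    R <- tryCatch(chol(S), error = function(e) NULL)
    list(mu = mu, R = R, S = S, rows = rows_by_subject[[s]])
  })
  names(stats_by_subject) <- eligible
  replace <- within == "with_replacement"
  distances <- numeric(n_iterations)
  pick <- sample(length(eligible), n_iterations, replace = TRUE)
  for (i in seq_len(n_iterations)) {
    st <- stats_by_subject[[pick[i]]]
    rows <- if (length(st$rows) == 1) rep(st$rows, n_prints)
            else sample(st$rows, n_prints, replace = replace)
    m <- if (length(rows) == 1) X[rows, ] else colMeans(X[rows, , drop = FALSE])
    if (is.null(st$R)) {
      distances[i] <- mahalanobis_distance(m, st$mu, st$S)
    } else {
      z <- backsolve(st$R, m - st$mu, transpose = TRUE)
      distances[i] <- sqrt(sum(z^2))
    }
  }
  attr(distances, "n_prints") <- n_prints
  attr(distances, "n_subjects_eligible") <- length(eligible)
  attr(distances, "seed") <- seed
  distances
}

#' Compare a fossil trackway with the human pool
#'
#' Implements the trackway similarity test: the human pool is optionally
#' restricted to prints of the same gait as the trackway (supplied or
#' predicted via [predict_gait()]); the fossil trackway's mean topography is
#' compared, by Mahalanobis distance, to the average human footprint of the
#' pool; and the probability of sampling at least as large a distance from
#' within the resampled human data set is read off the subject-level null of
#' [resample_null()] run at the trackway's print count.
#'
#' @param fossil Footprint table (or matrix) of the fossil trackway's depth
#'   profiles, >= 1 row.
#' @param pool Human footprint table with `subject_id`, depth columns, and a
#'   `gait` column when gait matching is enabled.
#' @param gait Optional gait label (`"walking"`/`"running"` or a
#'   [predict_gait()] result) for pool matching.
#' @param classifier Optional [fit_gait_classifier()]; used to predict the
#'   trackway's gait when `gait` is not supplied.
#' @param gait_match Restrict the pool to the matching gait (default TRUE;
#'   disabled automatically, with a message, when no gait can be determined).
#' @param n_iterations,seed,within,cov_mode,mean_mode,estimator Passed to
#'   [resample_null()].
#' @param p_rule `"plus_one"` (default): p = (1 + #\{null >= d\}) /
#'   (1 + n_iterations), never exactly 0; or `"raw"`: the plain exceedance
#'   fraction.
#' @return Object of class `trackway_comparison` with fields
#'   `fossil_distance`, `null_distances`, `p_value`, `n_prints`, `gait_used`,
#'   `n_pool_prints`, `n_pool_subjects`, `seed`.
#' @export
compare_trackway <- function(fossil, pool, gait = NULL, classifier = NULL,
                             gait_match = TRUE, n_iterations = 10000,
                             seed = NULL,
                             within = c("without_replacement", "with_replacement"),
                             cov_mode = c("leave_subject_out", "pooled"),
                             mean_mode = c("per_print", "per_subject"),
                             estimator = c("sample", "shrinkage"),
                             p_rule = c("plus_one", "raw")) {
  p_rule <- match.arg(p_rule)
  F_mat <- as_profile_matrix(fossil)
  if (nrow(F_mat) < 1) stop("fossil trackway has no depth profiles", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gait_used <- NA_character_
  if (gait_match) {
    if (inherits(gait, "gait_label")) gait_used <- gait$value
    else if (is.character(gait)) gait_used <- gait
    else if (!is.null(classifier) && is.data.frame(fossil)) {
      pg <- tryCatch(predict_gait(classifier, fossil), error = function(e) NULL)
      if (!is.null(pg)) gait_used <- pg$value
    }
    if (is.na(gait_used)) {
      message("no gait available for trackway; comparing against the full pool")
      gait_match <- FALSE
    }
  }
  if (gait_match) {
    if (is.null(pool$gait)) stop("pool has no gait column for gait matching",
                                 call. = FALSE)
    pool <- pool[pool$gait == gait_used, , drop = FALSE]
    if (nrow(pool) == 0) stop("gait-matched pool is empty (gait = ", gait_used,
                              ")", call. = FALSE)
  }
  X <- as_profile_matrix(pool)
  mean_mode <- match.arg(mean_mode)
  mu <- if (mean_mode == "per_print") colMeans(X) else {
    subs <- split(seq_len(nrow(X)), as.character(pool$subject_id))
    colMeans(do.call(rbind, lapply(subs, function(r) {
      colMeans(X[r, , drop = FALSE])
    })))
  }
  estimator <- match.arg(estimator)
  S <- cov_profiles(X, estimator)
  d_f <- mahalanobis_distance(mean_profile(F_mat), mu, S)
  null <- resample_null(pool, n_prints = nrow(F_mat),
                        n_iterations = n_iterations, seed = NULL,
                        within = match.arg(within),
                        cov_mode = match.arg(cov_mode),
                        mean_mode = mean_mode, estimator = estimator)
  exceed <- sum(null >= d_f)
  p <- if (p_rule == "plus_one") (1 + exceed) / (1 + n_iterations)
       else exceed / n_iterations
  structure(list(fossil_distance = d_f, null_distances = as.numeric(null),
                 p_value = p, n_prints = nrow(F_mat),
                 gait_used = gait_used,
                 n_pool_prints = nrow(X),
                 n_pool_subjects = length(unique(pool$subject_id)),
                 n_iterations = n_iterations, p_rule = p_rule, seed = seed),
            class = "trackway_comparison")
}

#' @export
print.trackway_comparison <- function(x, ...) {
  cat("Trackway resampling comparison\n")
  cat(sprintf("  gait-matched pool: %d prints from %d subjects%s\n",
              x$n_pool_prints, x$n_pool_subjects,
              if (is.na(x$gait_used)) "" else paste0(" (", x$gait_used, ")")))
  cat(sprintf("  trackway prints: %d   iterations: %d\n",
              x$n_prints, x$n_iterations))
  cat(sprintf("  Mahalanobis distance: %.3f   null 95th pctile: %.3f\n",
              x$fossil_distance,
              as.numeric(stats::quantile(x$null_distances, 0.95))))
  cat(sprintf("  P(null >= distance): %.4g\n", x$p_value))
  invisible(x)
}
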