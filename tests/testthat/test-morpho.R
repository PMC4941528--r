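test_that("mean profile is the element-wise average", {
  p <- walk_template()$mean
  expect_equal(mean_profile(matrix(p, 1, dimnames = list(NULL, names(p)))), p)
  expect_equal(mean_profile(rbind(p, -p)),
               stats::setNames(rep(0, 14), names(p)))
  m <- matrix(0, 5, 14, dimnames = list(NULL, depth_regions()))
  m[, "mt1"] <- 1:5
  expect_equal(unname(mean_profile(m)["mt1"]), 3)
  expect_error(mean_profile(m[0, , drop = FALSE]), "empty")
})

test_that("Mahalanobis distance matches hand-computed and trivial cases", {
  mu <- stats::setNames(rep(0, 2), c("a", "b"))
  expect_equal(mahalanobis_distance(mu, mu, diag(2)), 0)
  x <- c(a = 1, b = 1)
  expect_equal(mahalanobis_distance(x, mu, diag(2)), sqrt(2))
  # hand inversion of a diagonal covariance: 1/2 + 1/0.5
  expect_equal(mahalanobis_distance(x, mu, diag(c(2, 0.5))), sqrt(2.5))
  expect_error(mahalanobis_distance(x, mu, matrix(c(1, 2, 0, 1), 2)),
               "not symmetric")
  expect_error(mahalanobis_distance(c(1, 2, 3), mu, diag(2)), "mismatch")
})

test_that("implementation agrees with explicit-inverse oracle on random SPD", {
  set.seed(41)
  for (rep in 1:25) {
    d <- sample(2:14, 1)
    S <- random_spd(d)
    x <- stats::rnorm(d)
    mu <- stats::rnorm(d)
    oracle <- sqrt(drop(t(x - mu) %*% solve(S) %*% (x - mu)))
    expect_equal(mahalanobis_distance(x, mu, S), oracle, tolerance = 1e-10)
    # second independent route: stats::mahalanobis (squared distance)
    expect_equal(mahalanobis_distance(x, mu, S)^2,
                 unname(stats::mahalanobis(rbind(x), mu, S)),
                 tolerance = 1e-8)
  }
})

test_that("singular covariances fail loudly, naming deficient directions", {
  pool <- simulate_depth_profiles(5, 4, seed = 3)
  X <- as.matrix(pool[, depth_columns()])
  colnames(X) <- depth_regions()
  X[, "toe5"] <- X[, "toe4"]          # rank-deficient: toe5 duplicates toe4
  S <- stats::cov(X)
  expect_error(mahalanobis_distance(X[1, ], colMeans(X), S),
               "singular covariance.*toe")
  # shrinkage restores positive definiteness
  Ssh <- cov_profiles(X, estimator = "shrinkage")
  expect_true(all(eigen(Ssh, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_true(is.finite(mahalanobis_distance(X[1, ], colMeans(X), Ssh)))
})

test_that("null distances are zero for a pool of identical prints", {
  p <- walk_template()$mean
  pool <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 4))
  prof <- as.data.frame(matrix(rep(p, 16), 16, byrow = TRUE))
  names(prof) <- depth_columns()
  pool <- cbind(pool, prof)
  null <- resample_null(pool, n_prints = 2, n_iterations = 50, seed = 1)
  expect_equal(as.numeric(null), rep(0, 50))
})

test_that("resampling is seeded and single-iteration reproducible", {
  pool <- simulate_depth_profiles(10, 8, seed = 5)
  n1 <- resample_null(pool, n_prints = 3, n_iterations = 1, seed = 77)
  n2 <- resample_null(pool, n_prints = 3, n_iterations = 1, seed = 77)
  expect_identical(as.numeric(n1), as.numeric(n2))
  expect_error(resample_null(pool, n_prints = 50, n_iterations = 10),
               "no subject has enough prints")
  expect_error(resample_null(pool[1:16, ], n_prints = 2, n_iterations = 10),
               "at least 3 subjects")
})

test_that("null distances shrink stochastically with trackway size", {
  pool <- simulate_depth_profiles(20, 12, seed = 6)
  n1 <- resample_null(pool, n_prints = 1, n_iterations = 3000, seed = 8)
  n10 <- resample_null(pool, n_prints = 10, n_iterations = 3000, seed = 9)
  expect_gt(mean(n1), mean(n10))
})

test_that("trackway comparison honours the exceedance-probability rules", {
  pool <- simulate_depth_profiles(15, 10, seed = 10)
  grand <- mean_profile(pool)
  fossil <- rbind(grand, grand, grand)
  cmp <- compare_trackway(fossil, pool, gait_match = FALSE,
                          n_iterations = 200, seed = 11)
  expect_equal(cmp$fossil_distance, 0, tolerance = 1e-10)
  expect_equal(cmp$p_value, 1)

  far <- fossil + 100
  cmp2 <- compare_trackway(far, pool, gait_match = FALSE,
                           n_iterations = 200, seed = 11, p_rule = "plus_one")
  expect_equal(cmp2$p_value, 1 / 201)
  cmp3 <- compare_trackway(far, pool, gait_match = FALSE,
                           n_iterations = 200, seed = 11, p_rule = "raw")
  expect_equal(cmp3$p_value, 0)

  # p is monotonically non-increasing in the fossil distance for a fixed null
  p_at <- function(d) (1 + sum(cmp$null_distances >= d)) / (1 + 200)
  ds <- seq(0, 5, by = 0.25)
  expect_true(all(diff(vapply(ds, p_at, numeric(1))) <= 0))
})

test_that("distances are invariant under affine maps of profile space", {
  pool <- simulate_depth_profiles(8, 6, seed = 12)
  fossil <- as.matrix(simulate_depth_profiles(1, 4, seed = 13)[, depth_columns()])
  set.seed(14)
  A <- matrix(stats::rnorm(196), 14)
  while (abs(det(A)) < 1e-3) A <- matrix(stats::rnorm(196), 14)
  b <- stats::rnorm(14)
  transform <- function(M) sweep(M %*% t(A), 2, -b)
  pool_t <- pool
  pool_t[, depth_columns()] <- transform(as.matrix(pool[, depth_columns()]))
  c0 <- compare_trackway(fossil, pool, gait_match = FALSE,
                         n_iterations = 100, seed = 15)
  c1 <- compare_trackway(transform(fossil), pool_t, gait_match = FALSE,
                         n_iterations = 100, seed = 15)
  expect_equal(c1$fossil_distance, c0$fossil_distance, tolerance = 1e-8)
  expect_equal(c1$null_distances, c0$null_distances, tolerance = 1e-8)
})

test_that("gait matching restricts the pool and empty matches fail", {
  fp <- reference_table()
  fossil <- fp[fp$gait == "walking", ][1:4, ]
  cmp <- compare_trackway(fossil, fp, gait = "walking", n_iterations = 100,
                          seed = 16)
  expect_identical(cmp$gait_used, "walking")
  expect_identical(cmp$n_pool_prints, sum(fp$gait == "walking"))
  nop <- fp
  nop$gait <- "walking"
  expect_error(compare_trackway(fossil, nop, gait = "running",
                                n_iterations = 10),
               "gait-matched pool is empty")
  expect_message(compare_trackway(fossil, fp[, c("subject_id", depth_columns())],
                                  gait_match = TRUE, n_iterations = 10,
                                  seed = 1),
                 "full pool")
})

test_that("held-out human trackways yield approximately uniform p-values", {
  r <- heldout_comparison_experiment(60, n_iterations = 400, seed = 17)
  ks <- suppressWarnings(stats::ks.test(r$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})
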