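test_that("train/test split is disjoint, exhaustive and seeded", {
  fp <- reference_table()[1:490, ]
  s1 <- split_train_test(fp, seed = 9, by = "print")
  expect_identical(nrow(s1$train), 343L)   # round(0.7 * 490)
  expect_identical(nrow(s1$test), 147L)
  expect_length(intersect(s1$train$footprint_id, s1$test$footprint_id), 0)
  expect_setequal(c(s1$train$footprint_id, s1$test$footprint_id),
                  fp$footprint_id)
  s2 <- split_train_test(fp, seed = 9, by = "print")
  expect_identical(s1, s2)
  expect_error(split_train_test(fp, fraction = 1.0), "strictly between")
  expect_error(split_train_test(fp[1:5, ]), "at least 10")
})

test_that("subject-wise split keeps each subject on one side", {
  fp <- reference_table()
  s <- split_train_test(fp, seed = 4, by = "subject")
  expect_length(intersect(unique(s$train$subject_id),
                          unique(s$test$subject_id)), 0)
  expect_identical(nrow(s$train) + nrow(s$test), nrow(fp))
  expect_lt(abs(nrow(s$train) / nrow(fp) - 0.7), 0.06)
})

test_that("bootstrap bookkeeping matches n(1-(1-1/n)^n) unique in-bag points", {
  fp <- reference_table()[1:490, ]
  tr <- split_train_test(fp, seed = 9, by = "print")$train   # n = 343
  m <- fit_mass_model(tr, n_trees = 300, seed = 12)
  expected <- 343 * (1 - (1 - 1 / 343)^343)                  # ~217
  expect_lt(abs(mean(m$inbag_unique) - expected), 2)
  # in-bag and OOB partition the training set for every tree
  expect_true(all(m$inbag_unique >= 1))
  expect_equal(m$inbag_unique + m$oob_counts, rep(343, 300),
               ignore_attr = TRUE)
})

test_that("degenerate training inputs are handled as specified", {
  fp <- reference_table()[1:60, ]
  const <- fp
  const$body_mass_kg <- 50
  m <- suppressWarnings(fit_mass_model(const, n_trees = 20, seed = 1))
  expect_equal(m$rmse_oob, 0)
  expect_equal(predict_mass(m, fp[1:3, ]), rep(50, 3))

  allconst <- fp
  for (col in measurement_columns()) allconst[[col]] <- 1
  expect_error(fit_mass_model(allconst), "uninformative")
})

test_that("predictions stay within the training response range", {
  fp <- reference_table()
  m <- fit_mass_model(split_train_test(fp, seed = 2)$train,
                      n_trees = 100, seed = 3)
  extreme <- data.frame(heel_to_hallux_length_cm = c(0.1, 500),
                        heel_to_t2_length_cm = c(0.1, 500),
                        forefoot_breadth_cm = c(0.01, 200),
                        heel_breadth_cm = c(0.01, 200),
                        mean_depth_cm = c(0, 50))
  p <- predict_mass(m, extreme)
  expect_true(all(p >= m$training_response_range[1]))
  expect_true(all(p <= m$training_response_range[2]))
})

test_that("a single fully grown tree memorises an unambiguous training point", {
  tr <- reference_table()[1:30, ]
  target <- tr[1, ]
  target$body_mass_kg <- 99
  target$heel_to_hallux_length_cm <- 60   # far outside the rest
  tr2 <- rbind(tr[-1, ], target[rep(1, 12), ])  # in every bootstrap w.h.p.
  m1 <- suppressWarnings(fit_mass_model(tr2, n_trees = 1, nodesize = 1,
                                        seed = 5))
  expect_equal(predict_mass(m1, target), 99, tolerance = 1e-8)
})

test_that("rank order of length is preserved on noiseless monotone data", {
  n <- 120
  L <- seq(18, 28, length.out = n)
  fp <- data.frame(footprint_id = paste0("f", 1:n), subject_id = paste0("s", 1:n),
                   heel_to_hallux_length_cm = L, heel_to_t2_length_cm = L,
                   forefoot_breadth_cm = 0.38 * L, heel_breadth_cm = 0.25 * L,
                   mean_depth_cm = 1, body_mass_kg = (L / 6.8)^3)
  m <- fit_mass_model(fp, n_trees = 200, seed = 6)
  test_L <- seq(19, 27, by = 0.5)
  p <- predict_mass(m, data.frame(heel_to_hallux_length_cm = test_L,
                                  heel_to_t2_length_cm = test_L,
                                  forefoot_breadth_cm = 0.38 * test_L,
                                  heel_breadth_cm = 0.25 * test_L,
                                  mean_depth_cm = 1))
  expect_true(all(diff(p) >= 0))
})

test_that("test error shrinks with sample size on noiseless data", {
  rmse_at <- function(n) {
    L <- stats::runif(n, 17, 29)
    fp <- data.frame(footprint_id = paste0("f", 1:n),
                     subject_id = paste0("s", 1:n),
                     heel_to_hallux_length_cm = L, heel_to_t2_length_cm = L,
                     forefoot_breadth_cm = 0.38 * L, heel_breadth_cm = 0.25 * L,
                     mean_depth_cm = 1, body_mass_kg = (L / 6.8)^3)
    parts <- split_train_test(fp, seed = 1, by = "print")
    m <- fit_mass_model(parts$train, n_trees = 100, seed = 2)
    evaluate_mass_models(m, fit_length_regression(parts$train),
                         parts$test)$rmse_test
  }
  set.seed(77)
  e100 <- rmse_at(100)
  e1000 <- rmse_at(1000)
  expect_lt(e1000, e100)
  expect_lt(e1000, 2)
})

test_that("OOB error does not grow with ensemble size", {
  fp <- reference_table()
  d <- vapply(1:8, function(s) {
    tr <- split_train_test(fp, seed = s)$train
    c(fit_mass_model(tr, n_trees = 1, seed = s)$rmse_oob,
      fit_mass_model(tr, n_trees = 200, seed = s)$rmse_oob)
  }, numeric(2))
  expect_lt(mean(d[2, ]), mean(d[1, ]))
})

test_that("length regression recovers exact linear structure", {
  L <- seq(18, 28, length.out = 20)
  fp <- data.frame(heel_to_hallux_length_cm = L, body_mass_kg = 2 * L + 1)
  lmfit <- fit_length_regression(fp)
  expect_equal(unname(lmfit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(sqrt(mean((predict(lmfit, fp) - fp$body_mass_kg)^2)), 0,
               tolerance = 1e-10)

  expect_warning(fit_length_regression(fp[1:2, ]), "2 points")
  const <- data.frame(heel_to_hallux_length_cm = rep(20, 5),
                      body_mass_kg = 1:5)
  expect_error(fit_length_regression(const), "zero variance")
})

test_that("evaluation computes RMSE identities on shared test rows", {
  fp <- reference_table()[1:60, ]
  const <- fp
  const$body_mass_kg <- 50
  m <- suppressWarnings(fit_mass_model(const[1:40, ], n_trees = 20, seed = 1))
  lin <- fit_length_regression(const[1:40, ])
  ev <- evaluate_mass_models(m, lin, const[41:60, ])
  expect_equal(ev$rmse_test, 0, tolerance = 1e-8)
  expect_equal(ev$rmse_linear_test, 0, tolerance = 1e-8)
  # single test point: RMSE equals the absolute error
  one <- const[41, ]
  one$body_mass_kg <- 53
  ev1 <- evaluate_mass_models(m, lin, one)
  expect_equal(ev1$rmse_test, 3, tolerance = 1e-6)
  expect_error(evaluate_mass_models(m, lin, const[0, ]), "empty test")
})

test_that("trackway prediction averages dimensions before predicting", {
  fp <- reference_table()
  m <- fit_mass_model(split_train_test(fp, seed = 2)$train,
                      n_trees = 100, seed = 3)
  one <- fp[5, ]
  expect_equal(predict_trackway_mass(m, one), predict_mass(m, one))
  several <- one[rep(1, 4), ]
  expect_equal(predict_trackway_mass(m, several), predict_mass(m, one))
  empty <- one
  empty$mean_depth_cm <- NA_real_
  expect_error(predict_trackway_mass(m, empty), "complete measurements")
})

test_that("trackway predictions recover the generating population mean", {
  cfg <- population_config(seed = 501)
  fp <- generate_footprints(generate_population(cfg), cfg)
  m <- fit_mass_model(split_train_test(fp, seed = 2)$train, seed = 3)
  sc <- generate_fossil_scenario(n_trackways = 30, prints_per_trackway = 5,
                                 config = cfg, seed = 504)
  pred <- vapply(sc$truth$trackway_id, function(id) {
    predict_trackway_mass(m, sc$trackways[sc$trackways$subject_id == id, ])
  }, numeric(1))
  expect_lt(abs(mean(pred) - mean(sc$truth$body_mass_kg)), 2)
})
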