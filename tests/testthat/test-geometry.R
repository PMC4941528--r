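test_that("reference plane fits flat and tilted surfaces exactly", {
  flat <- generate_surface(zero_profile(), base_elevation = 2)
  p <- fit_reference_plane(flat)
  expect_equal(unname(p$coefficients), c(0, 0, 2), tolerance = 1e-10)
  expect_lt(p$rms, 1e-10)

  tilted <- generate_surface(zero_profile(), tilt = c(0.05, -0.03),
                             base_elevation = 1)
  p2 <- fit_reference_plane(tilted)
  expect_equal(unname(p2$coefficients), c(0.05, -0.03, 1), tolerance = 1e-10)
})

test_that("plane coefficients are recovered under measurement noise", {
  errs <- vapply(1:30, function(s) {
    srf <- generate_surface(zero_profile(), tilt = c(0.05, -0.03),
                            base_elevation = 1, noise_sd = 0.01, seed = s)
    max(abs(fit_reference_plane(srf)$coefficients - c(0.05, -0.03, 1)))
  }, numeric(1))
  expect_lt(max(errs), 1e-3)   # thousands of margin cells: SE ~ 1e-4
})

test_that("degenerate margin masks are rejected", {
  s <- generate_surface(zero_profile())
  s$margin_mask[] <- FALSE
  expect_error(fit_reference_plane(s), "fewer than 3")
  s$margin_mask[1, 1:10] <- TRUE   # one row: collinear
  expect_error(fit_reference_plane(s), "collinear")
})

test_that("orientation flattens the plane and is idempotent", {
  prof <- walk_template()$mean * 1.2
  s <- generate_surface(prof, tilt = c(0.04, 0.02), base_elevation = 3)
  o1 <- orient_surface(s)
  p1 <- fit_reference_plane(o1)
  expect_lt(max(abs(p1$coefficients)), 1e-8)
  o2 <- orient_surface(o1)
  expect_equal(o2$elevations, o1$elevations, tolerance = 1e-10)
  # margin residual RMS after orientation equals the fitted plane's residual
  expect_equal(fit_reference_plane(o1)$rms, fit_reference_plane(s)$rms,
               tolerance = 1e-8)
})

test_that("landmark depths round-trip through tilted noiseless surfaces", {
  set.seed(31)
  for (k in 1:3) {
    prof <- as.numeric(MASS::mvrnorm(1, walk_template()$mean * 1.5,
                                     walk_template()$cov))
    names(prof) <- depth_regions()
    prof <- pmax(prof, 0.05)
    tilt <- stats::runif(2, -0.06, 0.06)
    s <- generate_surface(prof, tilt = tilt, base_elevation = 1)
    d <- measure_depths(orient_surface(s))
    expect_equal(d, prof, tolerance = 1e-6)
  }
})

test_that("depth measurement is invariant to adding any plane", {
  prof <- walk_template()$mean
  s <- generate_surface(prof)
  d0 <- measure_depths(orient_surface(s))
  ax_x <- s$origin[1] + (seq_len(ncol(s$elevations)) - 1) * s$spacing
  ax_y <- s$origin[2] + (seq_len(nrow(s$elevations)) - 1) * s$spacing
  s$elevations <- s$elevations +
    outer(ax_y, ax_x, function(y, x) 0.07 * x - 0.02 * y + 5)
  d1 <- measure_depths(orient_surface(s))
  expect_equal(d1, d0, tolerance = 1e-8)
})

test_that("an isolated pit is measured at its own landmark only", {
  prof <- zero_profile()
  prof["mt1"] <- 1.2
  # far-field depths are zero to rounding; tiny negative float noise is expected
  d <- suppressWarnings(measure_depths(orient_surface(generate_surface(prof))))
  expect_equal(unname(d["mt1"]), 1.2, tolerance = 1e-6)
  expect_lt(max(abs(d[names(d) != "mt1"])), 1e-6)

  # all-zero profile on a flat surface: all depths zero
  d0 <- suppressWarnings(measure_depths(generate_surface(zero_profile())))
  expect_lt(max(abs(d0)), 1e-12)
})

test_that("raised relief and off-grid landmarks are handled explicitly", {
  prof <- zero_profile()
  prof["toe3"] <- -0.2          # displacement rim at a landmark
  s <- orient_surface(generate_surface(prof))
  expect_warning(measure_depths(s), "negative depth.*toe3")
  s$landmarks$x[1] <- 1e4
  expect_error(measure_depths(s), "outside grid")
})

test_that("replicate measurements with landmark jitter are repeatable", {
  # smooth, well-separated pits (the repeatability protocol's conditions)
  prof <- zero_profile()
  prof[c("heel_medial", "midfoot_lateral", "mt3", "toe1")] <- c(1.2, 0.8, 1.0, 0.9)
  s <- orient_surface(generate_surface(prof, bump_sd = 1.0))
  set.seed(99)
  diffs <- replicate(20, {
    jitter_once <- function(srf) {
      srf$landmarks$x <- srf$landmarks$x + stats::rnorm(14, 0, 0.05)
      srf$landmarks$y <- srf$landmarks$y + stats::rnorm(14, 0, 0.05)
      suppressWarnings(measure_depths(srf))
    }
    mean(abs(jitter_once(s) - jitter_once(s)))
  })
  expect_lt(mean(diffs), 0.01)
})

test_that("mean depth agrees between profile and surface forms", {
  d <- mean_depth(rep(0.8, 14))
  expect_equal(as.numeric(d), 0.8)
  expect_equal(as.numeric(mean_depth((1:14) / 10)), 0.75)
  expect_identical(attr(d, "source"), "profile")

  fp <- reference_table()
  prof <- as.matrix(fp[1:10, depth_columns()])
  colnames(prof) <- depth_regions()
  forms <- apply(prof, 1, function(p) {
    s <- orient_surface(generate_surface(p))
    c(outline = as.numeric(mean_depth(s)),
      landmarks = as.numeric(mean_depth(p)))
  })
  # outline mean integrates mostly-undeformed cells: a consistent, bounded
  # fraction of the 14-region mean for a fixed pit geometry
  ratio <- forms["outline", ] / forms["landmarks", ]
  expect_true(all(forms["outline", ] > 0))
  expect_true(all(forms["outline", ] < forms["landmarks", ]))
  expect_lt(stats::sd(ratio) / mean(ratio), 0.05)

  s <- generate_surface(zero_profile())
  s$outline_mask[] <- FALSE
  expect_error(mean_depth(s), "outline")
})

test_that("forefoot gradient slopes match exact least squares", {
  prof <- zero_profile()
  prof[paste0("mt", 1:5)] <- c(5, 4, 3, 2, 1) / 10   # mm as cm/10
  prof[paste0("toe", 1:5)] <- 0.3
  g <- forefoot_gradient(prof)
  expect_equal(unname(g["mt_slope"]), -0.1)
  expect_equal(unname(g["toe_slope"]), 0)
})

test_that("walking populations show the medial-deeper gradient; shifted templates lose it", {
  pool <- simulate_depth_profiles(1, 100, walk_template(), seed = 11)
  slopes <- apply(as.matrix(pool[, depth_columns()]), 1, function(p) {
    names(p) <- depth_regions()
    forefoot_gradient(p)["mt_slope"]
  })
  expect_lt(stats::t.test(slopes)$conf.int[2], 0)   # significantly negative
  shifted <- shift_forefoot_gradient(walk_template(), 8)
  expect_gte(unname(forefoot_gradient(shifted$mean)["mt_slope"]), 0)
})
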