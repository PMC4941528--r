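# Simulation experiments used for calibration, power and benchmarking runs.
# Each experiment drives the package's own estimators on generated data with
# known truth and returns the per-replicate results for summary by the caller.

#' Held-out-trackway resampling experiment
#'
#' Calibration and power study of the trackway comparison on an idealised
#' human pool (i.i.d. multivariate-normal 14-region profiles, exchangeable
#' across subjects; see [simulate_depth_profiles()]). With `shift = 0`, one
#' subject is held out per replicate and a random trackway-sized sample of
#' its prints is treated as the "fossil": the resulting p-values should be
#' approximately uniform, so the rejection rate at `alpha` estimates the
#' type-I error. With `shift > 0`, the fossil prints are instead drawn from a
#' template whose forefoot gradient is shifted that many pooled SDs toward
#' the non-human, lateral-deepening pattern, and the rejection rate estimates
#' power against a divergent, Laetoli-like topography.
#'
#' @param n_replicates Number of replicates.
#' @param n_iterations Resampling iterations per replicate.
#' @param n_prints Fossil trackway size (prints).
#' @param n_subjects,prints_per_subject Human pool layout.
#' @param template Pool [depth_template()].
#' @param shift Forefoot-gradient shift (pooled SDs) of the fossil template.
#' @param seed Optional integer seed.
#' @return Data frame with one row per replicate: `p_value`, `distance`.
#' @export
heldout_comparison_experiment <- function(n_replicates, n_iterations = 2000,
                                          n_prints = 5, n_subjects = 41,
                                          prints_per_subject = 12,
                                          template = default_template_library()$human_walk,
                                          shift = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fossil_tpl <- if (shift > 0) shift_forefoot_gradient(template, shift)
                else template
  p <- numeric(n_replicates)
  d <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    pool <- simulate_depth_profiles(n_subjects, prints_per_subject, template)
    if (shift > 0) {
      fossil <- MASS::mvrnorm(n_prints, fossil_tpl$mean, fossil_tpl$cov)
    } else {
      held <- sample(unique(pool$subject_id), 1)
      rows <- which(pool$subject_id == held)
      fossil <- as_profile_matrix(pool[sample(rows, n_prints), ])
      pool <- pool[-rows, , drop = FALSE]
    }
    cmp <- compare_trackway(fossil, pool, gait_match = FALSE,
                            n_iterations = n_iterations)
    p[r] <- cmp$p_value
    d[r] <- cmp$fossil_distance
  }
  data.frame(replicate = seq_len(n_replicates), p_value = p, distance = d)
}

#' Repeated mass-model benchmark on synthetic populations
#'
#' Per replicate: generate a full synthetic population and its footprints,
#' split train/test, fit the tree ensemble and the length-only regression,
#' and evaluate both on the identical test rows.
#'
#' @param n_replicates Number of replicates.
#' @param config A [population_config()] (its `seed` is ignored; replicate
#'   seeds derive from `seed`).
#' @param fraction,by Passed to [split_train_test()].
#' @param n_trees Ensemble size.
#' @param seed Optional integer seed.
#' @return Data frame per replicate: `rmse_test`, `rmse_linear_test`,
#'   `rmse_oob`, `n_train`, `n_test`.
#' @export
mass_model_experiment <- function(n_replicates = 50,
                                  config = population_config(),
                                  fraction = 0.7, by = "subject",
                                  n_trees = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    subjects <- generate_population(config)
    prints <- generate_footprints(subjects, config)
    parts <- split_train_test(prints, fraction = fraction, by = by)
    model <- fit_mass_model(parts$train, n_trees = n_trees)
    linear <- fit_length_regression(parts$train)
    ev <- evaluate_mass_models(model, linear, parts$test)
    out[[r]] <- data.frame(replicate = r, rmse_test = ev$rmse_test,
                           rmse_linear_test = ev$rmse_linear_test,
                           rmse_oob = ev$rmse_oob,
                           n_train = ev$n_train, n_test = ev$n_test)
  }
  do.call(rbind, out)
}

#' Mean-method recovery experiment on dimorphic assemblages
#'
#' Simulates assemblages of trackway masses with a known sex composition and
#' a configurable dimorphism (difference of male and female means in units of
#' the common within-sex SD), applies the mean method, and scores accuracy
#' against truth. Masses are drawn from the same truncated normals the fossil
#' scenario generator uses.
#'
#' @param n_assemblages Number of simulated assemblages.
#' @param n_trackways Trackways per assemblage.
#' @param male_fraction Fraction of male trackway makers.
#' @param dimorphism Male-female mean difference in pooled-SD units.
#' @param mass_sd Within-sex SD (kg).
#' @param mass_center Midpoint of the male and female means (kg).
#' @param mass_min Truncation bound (kg).
#' @param seed Optional integer seed.
#' @return Data frame per assemblage: `accuracy`, `males_pred`, `males_true`,
#'   `conserved` (males + females + excluded == trackways).
#' @export
sex_attribution_experiment <- function(n_assemblages = 1000, n_trackways = 16,
                                       male_fraction = 0.5, dimorphism = 1.5,
                                       mass_sd = 5.5, mass_center = 52,
                                       mass_min = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_male <- round(male_fraction * n_trackways)
  truth <- c(rep("male", n_male), rep("female", n_trackways - n_male))
  mu <- ifelse(truth == "male", mass_center + dimorphism * mass_sd / 2,
               mass_center - dimorphism * mass_sd / 2)
  out <- vector("list", n_assemblages)
  for (r in seq_len(n_assemblages)) {
    masses <- rnorm_trunc(n_trackways, mu, mass_sd, mass_min)
    att <- attribute_sex(masses)
    comp <- site_composition(att)
    out[[r]] <- data.frame(
      assemblage = r,
      accuracy = mean(att$predicted_sex == truth, na.rm = TRUE),
      males_pred = comp$males, males_true = n_male,
      conserved = comp$males + comp$females + comp$excluded == comp$trackways)
  }
  do.call(rbind, out)
}
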