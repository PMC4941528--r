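#' Run the full footprint analysis pipeline
#'
#' Chains the analysis stages in order on a reference (modern human) table
#' and a fossil table: body-mass estimation (train/test split, tree ensemble
#' + length-only benchmark, per-trackway predictions), gait classification,
#' trackway resampling comparison, and mean-method sex attribution. All
#' report tables plus a JSON run manifest are written to `out_dir`. Stages
#' that cannot run on the given inputs (e.g. the comparison when the fossil
#' table has no depth columns) are skipped with a logged reason; identical
#' inputs and seeds yield byte-identical report tables.
#'
#' @param reference Reference footprint table (data frame or CSV path) with
#'   known `body_mass_kg` and, for the gait/comparison stages, `gait` labels
#'   and depth columns.
#' @param fossil Fossil footprint table (data frame or CSV path); trackways
#'   are identified by `subject_id`.
#' @param out_dir Output directory (created if needed).
#' @param seeds Named list of integer seeds: `split`, `boot`, `gait`,
#'   `compare`.
#' @param fraction,split_by Passed to [split_train_test()].
#' @param n_trees Ensemble size for both models.
#' @param n_iterations Resampling iterations per trackway comparison.
#' @param gait_match Gait-match the comparison pool (default TRUE).
#' @param outlier_rule,outlier_flags Passed to [detect_outliers()].
#' @return Invisible list with the fitted models, per-stage tables and the
#'   manifest.
#' @export
run_pipeline <- function(reference, fossil, out_dir,
                         seeds = list(split = 1L, boot = 2L, gait = 3L,
                                      compare = 4L),
                         fraction = 0.7, split_by = "subject",
                         n_trees = 500, n_iterations = 1000,
                         gait_match = TRUE,
                         outlier_rule = "none", outlier_flags = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digests <- list()
  load_table <- function(x, label) {
    if (is.character(x)) {
      digests[[label]] <<- unname(tools::md5sum(x))
      read_footprint_table(x)
    } else validate_footprint_table(x, context = label)
  }
  reference <- load_table(reference, "reference")
  fossil <- load_table(fossil, "fossil")
  stages <- character(0)
  skipped <- list()
  note <- function(stage) stages <<- c(stages, stage)
  out_csv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  note("ingest")

  # --- mass estimation -------------------------------------------------
  parts <- split_train_test(reference, fraction = fraction,
                            seed = seeds$split, by = split_by)
  model <- fit_mass_model(parts$train, n_trees = n_trees, seed = seeds$boot)
  linear <- fit_length_regression(parts$train)
  evaluation <- evaluate_mass_models(model, linear, parts$test)
  trackway_ids <- unique(fossil$subject_id)
  masses <- vapply(trackway_ids, function(id) {
    predict_trackway_mass(model, fossil[fossil$subject_id == id, , drop = FALSE])
  }, numeric(1))
  mass_table <- data.frame(
    trackway_id = trackway_ids,
    site_id = vapply(trackway_ids, function(id) {
      fossil$site_id[fossil$subject_id == id][1]
    }, character(1)),
    n_prints = vapply(trackway_ids, function(id) {
      sum(fossil$subject_id == id)
    }, integer(1)),
    predicted_mass_kg = round(unname(masses), 6),
    stringsAsFactors = FALSE)
  out_csv(mass_table, "trackway_masses.csv")
  out_csv(data.frame(rmse_oob_kg = round(evaluation$rmse_oob, 6),
                     rmse_test_kg = round(evaluation$rmse_test, 6),
                     rmse_linear_test_kg = round(evaluation$rmse_linear_test, 6),
                     n_train = evaluation$n_train,
                     n_test = evaluation$n_test),
          "model_evaluation.csv")
  note("mass_estimation")

  # --- gait classification --------------------------------------------
  classifier <- NULL
  gait_table <- NULL
  fossil_depths <- !is.null(depth_matrix(fossil))
  ref_ok <- !is.null(depth_matrix(reference)) &&
    length(intersect(c("walking", "running"), unique(reference$gait))) == 2
  if (ref_ok && fossil_depths) {
    classifier <- fit_gait_classifier(reference, n_trees = n_trees,
                                      seed = seeds$gait)
    gaits <- lapply(trackway_ids, function(id) {
      predict_gait(classifier, fossil[fossil$subject_id == id, , drop = FALSE])
    })
    gait_table <- data.frame(
      trackway_id = trackway_ids,
      gait = vapply(gaits, `[[`, character(1), "value"),
      vote_fraction = round(vapply(gaits, `[[`, numeric(1), "probability"), 6),
      stringsAsFactors = FALSE)
    out_csv(gait_table, "trackway_gait.csv")
    note("gait")
  } else {
    skipped$gait <- if (!ref_ok) {
      "reference table lacks depth columns or both gait classes"
    } else "fossil table lacks depth columns"
    message("gait stage skipped: ", skipped$gait)
  }

  # --- morphological comparison ---------------------------------------
  compare_table <- NULL
  if (fossil_depths && !is.null(depth_matrix(reference))) {
    rows <- vector("list", length(trackway_ids))
    nulls <- vector("list", length(trackway_ids))
    for (k in seq_along(trackway_ids)) {
      id <- trackway_ids[k]
      gait_k <- if (!is.null(gait_table)) {
        gait_table$gait[gait_table$trackway_id == id]
      } else NULL
      cmp <- compare_trackway(fossil[fossil$subject_id == id, , drop = FALSE],
                              reference, gait = gait_k,
                              gait_match = gait_match && !is.null(gait_k),
                              n_iterations = n_iterations,
                              seed = seeds$compare + k)
      rows[[k]] <- data.frame(
        trackway_id = id, n_prints = cmp$n_prints,
        gait_used = ifelse(is.na(cmp$gait_used), "all", cmp$gait_used),
        mahalanobis_distance = round(cmp$fossil_distance, 6),
        p_value = round(cmp$p_value, 6),
        n_iterations = cmp$n_iterations,
        stringsAsFactors = FALSE)
      nulls[[k]] <- data.frame(trackway_id = id,
                               iteration = seq_along(cmp$null_distances),
                               distance = round(cmp$null_distances, 6),
                               stringsAsFactors = FALSE)
    }
    compare_table <- do.call(rbind, rows)
    out_csv(compare_table, "trackway_comparison.csv")
    out_csv(do.call(rbind, nulls), "null_distances.csv")
    note("morpho_compare")
  } else {
    skipped$morpho_compare <- "fossil or reference table lacks depth columns"
    message("comparison stage skipped: ", skipped$morpho_compare)
  }

  # --- sex attribution -------------------------------------------------
  excl <- detect_outliers(stats::setNames(masses, trackway_ids),
                          rule = outlier_rule, flags = outlier_flags)
  attributions <- attribute_sex(unname(masses), trackway_id = trackway_ids,
                                site_id = mass_table$site_id, exclude = excl)
  attributions$predicted_mass_kg <- round(attributions$predicted_mass_kg, 6)
  attributions$threshold_mean_kg <- round(attributions$threshold_mean_kg, 6)
  out_csv(attributions, "sex_attribution.csv")
  composition <- site_composition(attributions)
  out_csv(composition, "site_composition.csv")
  note("sex_attribution")

  manifest <- list(
    package = "footprintr",
    version = as.character(utils::packageVersion("footprintr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = seeds,
    config = list(fraction = fraction, split_by = split_by,
                  n_trees = n_trees, n_iterations = n_iterations,
                  gait_match = gait_match, outlier_rule = outlier_rule),
    input_digests = digests,
    n_reference_prints = nrow(reference),
    n_fossil_prints = nrow(fossil),
    stages = stages,
    skipped = skipped)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = model, linear = linear, evaluation = evaluation,
                 classifier = classifier, masses = mass_table,
                 gait = gait_table, comparison = compare_table,
                 attributions = attributions, composition = composition,
                 manifest = manifest))
}
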