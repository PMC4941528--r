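#' Depth-profile templates
#'
#' A template describes the expected 14-region depth topography of one gait
#' type as a mean vector (normalised to average 1, so that a print's profile
#' is the template scaled by its mean depth) plus a 14x14 covariance of
#' print-to-print shape variation. The walking template encodes the human
#' medial-to-lateral gradient of decreasing depth across the forefoot
#' (mt1 > mt2 > ... > mt5, toe1 > ... > toe5) together with a shallow medial
#' midfoot (the longitudinal arch); the running template deepens the whole
#' forefoot relative to the heel and flattens the gradient.
#'
#' @param mean Named non-negative numeric vector over [depth_regions()]
#'   (relative depths; rescaled internally to average 1).
#' @param gait `"walking"` or `"running"`.
#' @param rel_sd Per-region standard deviation as a fraction of the region
#'   mean (default 0.12).
#' @param correlation Common inter-region correlation of the shape noise
#'   (default 0.3; compound-symmetric, hence positive definite).
#' @return An object of class `depth_template`: list with `mean`, `cov`, `gait`.
#' @export
depth_template <- function(mean, gait = c("walking", "running"),
                           rel_sd = 0.12, correlation = 0.3) {
  gait <- match.arg(gait)
  regions <- depth_regions()
  if (is.null(names(mean)) || !identical(sort(names(mean)), sort(regions))) {
    stop("template mean must be named with the 14 canonical regions",
         call. = FALSE)
  }
  mean <- mean[regions]
  mean <- mean / base::mean(mean)
  sds <- rel_sd * mean
  R <- matrix(correlation, 14, 14)
  diag(R) <- 1
  cov <- outer(sds, sds) * R
  dimnames(cov) <- list(regions, regions)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) stop("template covariance is not positive semi-definite",
                             call. = FALSE)
  structure(list(mean = mean, cov = cov, gait = gait),
            class = "depth_template")
}

#' @rdname depth_template
#' @export
default_template_library <- function() {
  regions <- depth_regions()
  walk <- c(1.20, 1.15, 0.45, 0.75,          # heel m/l, midfoot m/l
            1.30, 1.20, 1.00, 0.85, 0.70,    # mt1..mt5: medial deeper
            1.10, 0.95, 0.70, 0.55, 0.45)    # toe1..toe5: medial deeper
  run <- c(0.90, 0.90, 0.50, 0.70,
           1.40, 1.35, 1.30, 1.25, 1.20,     # uniformly deep forefoot
           1.25, 1.20, 1.15, 1.10, 1.05)
  names(walk) <- names(run) <- regions
  list(human_walk = depth_template(walk, "walking"),
       human_run  = depth_template(run, "running"))
}

#' Shift a template's forefoot gradient
#'
#' Moves the forefoot portion (mt1..mt5, toe1..toe5) of a template's mean
#' vector along the unit-norm lateral-deepening direction, i.e. against the
#' human medial-to-lateral gradient, by `shift` pooled standard deviations
#' (square root of the mean forefoot variance of the template covariance).
#' `shift = 0` returns the template unchanged. Used to construct divergent
#' "Laetoli-like" topographies whose forefoot gradient is flat or reversed.
#'
#' @param template A [depth_template()].
#' @param shift Magnitude of the shift in pooled SD units (>= 0).
#' @return A `depth_template` with shifted mean and unchanged covariance.
#' @export
shift_forefoot_gradient <- function(template, shift) {
  stopifnot(inherits(template, "depth_template"), shift >= 0)
  idx <- match(c(paste0("mt", 1:5), paste0("toe", 1:5)), depth_regions())
  v <- c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2)
  u <- v / sqrt(sum(v^2))
  pooled_sd <- sqrt(base::mean(diag(template$cov)[idx]))
  template$mean[idx] <- template$mean[idx] + shift * pooled_sd * u
  template
}

#' Configuration of the synthetic footprint population
#'
#' Defaults emulate the habitually barefoot experimental reference sample:
#' 41 subjects (15 adult males, 14 adult females, 10 juvenile males and 2
#' juvenile females) each leaving roughly a dozen prints under varied
#' substrate hydration/compaction, with sex-dimorphic adult masses and an
#' allometric (isometric by default) print-length/mass relation.
#'
#' @param n_male,n_female Adult subject counts.
#' @param n_juv_male,n_juv_female Juvenile subject counts.
#' @param mass_mean_male,mass_mean_female Adult mass means (kg).
#' @param mass_sd Adult within-sex mass SD (kg).
#' @param mass_mean_juvenile,mass_sd_juvenile Juvenile mass mean/SD (kg).
#' @param mass_min Lower truncation of all mass draws (kg; draws are redrawn
#'   until above this bound).
#' @param prints_per_subject Length-2 integer range; per-subject print counts
#'   are drawn uniformly from it.
#' @param allometry_exponent Exponent of the length-mass power law (default
#'   1/3, isometry).
#' @param length_coef Coefficient c of heel-to-hallux length = c * mass^exponent
#'   (cm; default 6.8 gives ~25 cm at 50 kg).
#' @param dimension_noise_cv Print-level multiplicative noise CV on each of
#'   the four linear dimensions.
#' @param subject_size_cv Subject-level CV of foot size around the allometric
#'   expectation: people of equal mass differ in foot length, so length alone
#'   predicts mass imperfectly (a CV of 0.05 puts the length-only regression
#'   error near 3 x 0.05 x 50 = 7.5 kg for adults).
#' @param ratio_t2,ratio_forefoot,ratio_heel Mean ratios of heel-to-2nd-toe
#'   length, forefoot breadth and heel breadth to heel-to-hallux length.
#' @param breadth_mass_exponent Response of relative print breadth to the
#'   subject's mass-for-length residual: subjects heavier than their foot
#'   length implies leave relatively broader prints. This makes the breadths
#'   informative about mass beyond length (0 disables the effect).
#' @param depth_scale_cm Mean print depth (cm) of a 50 kg subject on the
#'   neutral substrate; base depth scales linearly with mass.
#' @param depth_noise_cv Print-level CV of mean depth around the
#'   substrate/mass expectation.
#' @param substrate_levels Data frame with columns `substrate` (tag) and
#'   `multiplier` (depth multiplier), sampled uniformly per print.
#' @param gait_mix Fraction of prints made walking (remainder running).
#' @param template_library Named list of [depth_template()] objects keyed by
#'   template name; must contain one per gait used.
#' @param seed Optional integer seed; all generator randomness flows from it.
#' @return An object of class `population_config` (a validated list).
#' @export
population_config <- function(n_male = 15, n_female = 14,
                              n_juv_male = 10, n_juv_female = 2,
                              mass_mean_male = 56, mass_mean_female = 49,
                              mass_sd = 5.5,
                              mass_mean_juvenile = 30, mass_sd_juvenile = 7,
                              mass_min = 15,
                              prints_per_subject = c(10, 14),
                              allometry_exponent = 1 / 3,
                              length_coef = 6.8,
                              dimension_noise_cv = 0.02,
                              subject_size_cv = 0.05,
                              ratio_t2 = 0.99, ratio_forefoot = 0.38,
                              ratio_heel = 0.25,
                              breadth_mass_exponent = 0.5,
                              depth_scale_cm = 2.0, depth_noise_cv = 0.10,
                              substrate_levels = data.frame(
                                substrate = c("dry_compact", "moist_firm", "wet_soft"),
                                multiplier = c(0.6, 1.0, 1.5)),
                              gait_mix = 0.5,
                              template_library = default_template_library(),
                              seed = NULL) {
  cfg <- as.list(environment())
  counts <- c(n_male, n_female, n_juv_male, n_juv_female)
  if (any(counts < 0)) stop("subject counts must be non-negative", call. = FALSE)
  if (mass_mean_male <= 0 || mass_mean_female <= 0 || mass_sd <= 0 ||
      mass_mean_juvenile <= 0 || mass_sd_juvenile <= 0) {
    stop("mass means and SDs must be positive", call. = FALSE)
  }
  if (gait_mix < 0 || gait_mix > 1) stop("gait_mix must lie in [0, 1]", call. = FALSE)
  if (length(prints_per_subject) != 2 || any(prints_per_subject < 1)) {
    stop("prints_per_subject must be a range of counts >= 1", call. = FALSE)
  }
  for (tpl in template_library) {
    if (!inherits(tpl, "depth_template")) {
      stop("template_library entries must be depth_template objects", call. = FALSE)
    }
  }
  structure(cfg, class = "population_config")
}

# Truncated-normal draw: redraw until above `lower`.
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic subject population
#'
#' Draws subjects with sex, age class, body mass (sex-specific truncated
#' normals) and a per-subject print count, deterministically for a given
#' `config$seed`.
#'
#' @param config A [population_config()].
#' @return Data frame with columns `subject_id`, `sex`, `age_class`,
#'   `body_mass_kg`, `n_prints`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n_total <- config$n_male + config$n_female +
    config$n_juv_male + config$n_juv_female
  if (n_total == 0) stop("empty population: all subject counts are zero",
                         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  sex <- c(rep("male", config$n_male), rep("female", config$n_female),
           rep("male", config$n_juv_male), rep("female", config$n_juv_female))
  age <- c(rep("adult", config$n_male + config$n_female),
           rep("juvenile", config$n_juv_male + config$n_juv_female))
  mass <- numeric(n_total)
  for (i in seq_len(n_total)) {
    mu <- if (age[i] == "juvenile") config$mass_mean_juvenile
          else if (sex[i] == "male") config$mass_mean_male
          else config$mass_mean_female
    sd <- if (age[i] == "juvenile") config$mass_sd_juvenile else config$mass_sd
    mass[i] <- rnorm_trunc(1, mu, sd, config$mass_min)
  }
  rng <- config$prints_per_subject
  vals <- seq(rng[1], rng[2])
  n_prints <- if (length(vals) == 1) rep(vals, n_total)
              else sample(vals, n_total, replace = TRUE)
  data.frame(subject_id = sprintf("S%02d", seq_len(n_total)),
             sex = sex, age_class = age,
             body_mass_kg = mass, n_prints = n_prints,
             stringsAsFactors = FALSE)
}

# Template lookup for a gait label.
template_for_gait <- function(gait, library) {
  for (nm in names(library)) {
    if (identical(library[[nm]]$gait, gait)) return(library[[nm]])
  }
  stop("no template for gait '", gait, "' in template_library", call. = FALSE)
}

# Generate the prints of one individual (subject or fossil trackway).
# Returns a list(table = canonical rows, truth = generating parameters).
generate_prints_one <- function(id, mass, sex, n, config, gaits,
                                template_override = NULL,
                                role = "reference", site_id = "experimental") {
  size_factor <- 1 + stats::rnorm(1, 0, config$subject_size_cv)
  sub_idx <- sample(nrow(config$substrate_levels), n, replace = TRUE)
  substrate <- config$substrate_levels$substrate[sub_idx]
  multiplier <- config$substrate_levels$multiplier[sub_idx]
  cv <- config$dimension_noise_cv
  eps <- function() if (cv > 0) stats::rnorm(n, 0, cv) else numeric(n)
  L <- config$length_coef * mass^config$allometry_exponent * size_factor *
    (1 + eps())
  t2 <- L * config$ratio_t2 * (1 + eps())
  # mass-for-length residual: subjects heavier than their foot length implies
  # (size_factor < 1) leave relatively broader prints, and vice versa
  rel_mass <- size_factor^(-3 * config$breadth_mass_exponent)
  fb <- L * config$ratio_forefoot * rel_mass * (1 + eps())
  hb <- L * config$ratio_heel * rel_mass * (1 + eps())
  base_depth <- config$depth_scale_cm * mass / 50
  d <- base_depth * multiplier *
    (1 + if (config$depth_noise_cv > 0) stats::rnorm(n, 0, config$depth_noise_cv)
         else numeric(n))
  profiles <- matrix(NA_real_, n, 14, dimnames = list(NULL, depth_regions()))
  tpl_names <- character(n)
  for (i in seq_len(n)) {
    tpl <- if (is.null(template_override)) {
      template_for_gait(gaits[i], config$template_library)
    } else template_override
    shape <- MASS::mvrnorm(1, tpl$mean, tpl$cov)
    profiles[i, ] <- d[i] * shape
    tpl_names[i] <- tpl$gait
  }
  tab <- data.frame(footprint_id = sprintf("%s_p%02d", id, seq_len(n)),
                    subject_id = id, site_id = site_id, role = role,
                    gait = gaits, sex = sex,
                    body_mass_kg = mass,
                    heel_to_hallux_length_cm = L,
                    heel_to_t2_length_cm = t2,
                    forefoot_breadth_cm = fb,
                    heel_breadth_cm = hb,
                    mean_depth_cm = d,
                    substrate = substrate,
                    stringsAsFactors = FALSE)
  prof_df <- as.data.frame(profiles)
  names(prof_df) <- depth_columns()
  tab <- cbind(tab, prof_df)
  truth <- data.frame(footprint_id = tab$footprint_id,
                      subject_id = id, body_mass_kg = mass,
                      size_factor = size_factor,
                      substrate_multiplier = multiplier,
                      base_depth_cm = base_depth,
                      mean_depth_cm = d,
                      gait = gaits,
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Generate synthetic footprint records
#'
#' For each subject draws per-print gait, substrate level, external dimensions
#' (allometric power law with subject- and print-level multiplicative noise),
#' mean depth (substrate multiplier x mass-dependent base + noise) and a
#' 14-region depth profile (gait-template multivariate normal scaled by mean
#' depth). Every generating parameter is recorded in the `"truth"` attribute,
#' joinable to the output by `footprint_id`.
#'
#' @param subjects Data frame from [generate_population()].
#' @param config The [population_config()] used to generate them.
#' @return A footprint table (canonical schema) with attribute `truth`.
#' @export
generate_footprints <- function(subjects, config) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(subjects) || nrow(subjects) == 0) {
    stop("subjects must be non-empty", call. = FALSE)
  }
  out <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    gaits <- ifelse(stats::runif(s$n_prints) < config$gait_mix,
                    "walking", "running")
    out[[i]] <- generate_prints_one(s$subject_id, s$body_mass_kg, s$sex,
                                    s$n_prints, config, gaits)
  }
  tab <- do.call(rbind, lapply(out, `[[`, "table"))
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  rownames(tab) <- rownames(truth) <- NULL
  attr(tab, "truth") <- truth
  tab
}

#' Simulate an i.i.d. multivariate-normal depth-profile pool
#'
#' Draws `n_subjects * prints_per_subject` profiles directly from a template's
#' multivariate normal (no mass/substrate scaling), labelled by subject.
#' This is the idealised pool used for calibration and power experiments on
#' the resampling comparison: exchangeable across subjects by construction.
#'
#' @param n_subjects,prints_per_subject Pool layout.
#' @param template A [depth_template()] (default: walking template).
#' @param seed Optional integer seed.
#' @param subject_prefix Prefix for subject labels.
#' @return Footprint-profile table: `subject_id`, `footprint_id` and the 14
#'   depth columns.
#' @export
simulate_depth_profiles <- function(n_subjects, prints_per_subject,
                                    template = default_template_library()$human_walk,
                                    seed = NULL, subject_prefix = "H") {
  stopifnot(inherits(template, "depth_template"),
            n_subjects >= 1, prints_per_subject >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_subjects * prints_per_subject
  X <- MASS::mvrnorm(n, template$mean, template$cov)
  subj <- rep(sprintf("%s%03d", subject_prefix, seq_len(n_subjects)),
              each = prints_per_subject)
  out <- data.frame(subject_id = subj,
                    footprint_id = sprintf("%s_p%02d", subj,
                                           rep(seq_len(prints_per_subject),
                                               n_subjects)),
                    stringsAsFactors = FALSE)
  X <- as.data.frame(X)
  names(X) <- depth_columns()
  cbind(out, X)
}

#' Generate a synthetic fossil footprint-site scenario
#'
#' Emits a multi-trackway fossil site with known composition: each trackway is
#' one individual with known sex and mass, leaving `prints_per_trackway`
#' prints. Optionally the last `n_divergent` trackways use a template whose
#' forefoot gradient is shifted `divergent_shift` pooled SDs toward the
#' lateral-deepening, non-human pattern (see [shift_forefoot_gradient()]);
#' `divergent_shift = 0` leaves the template identical to the human one.
#'
#' @param n_trackways Number of trackways (> 0).
#' @param prints_per_trackway Prints per trackway.
#' @param male_fraction Fraction of trackway makers that are male (rounded).
#' @param gait Gait of all trackways (default walking).
#' @param n_divergent Number of trackways given the divergent template.
#' @param divergent_shift Forefoot-gradient shift in pooled SDs.
#' @param config A [population_config()] supplying masses, dimensions and
#'   templates.
#' @param site_id Site label stamped on the table.
#' @param seed Optional integer seed.
#' @return List with `trackways` (canonical footprint table, role `"fossil"`)
#'   and `truth` (per-trackway sex, mass, template, shift), plus `config`.
#' @export
generate_fossil_scenario <- function(n_trackways = 4, prints_per_trackway = 5,
                                     male_fraction = 0.5, gait = "walking",
                                     n_divergent = 0, divergent_shift = 0,
                                     config = population_config(),
                                     site_id = "synthetic_site", seed = NULL) {
  if (n_trackways < 1) stop("n_trackways must be >= 1", call. = FALSE)
  stopifnot(n_divergent >= 0, n_divergent <= n_trackways)
  if (!is.null(seed)) set.seed(seed)
  n_male <- round(male_fraction * n_trackways)
  sex <- c(rep("male", n_male), rep("female", n_trackways - n_male))
  base_tpl <- template_for_gait(gait, config$template_library)
  div_tpl <- shift_forefoot_gradient(base_tpl, divergent_shift)
  out <- vector("list", n_trackways)
  truth <- data.frame(trackway_id = sprintf("T%02d", seq_len(n_trackways)),
                      sex = sex, body_mass_kg = NA_real_,
                      template = "human", divergent_shift = 0,
                      n_prints = prints_per_trackway,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_trackways)) {
    mu <- if (sex[i] == "male") config$mass_mean_male else config$mass_mean_female
    mass <- rnorm_trunc(1, mu, config$mass_sd, config$mass_min)
    divergent <- i > n_trackways - n_divergent
    tpl <- if (divergent) div_tpl else base_tpl
    res <- generate_prints_one(truth$trackway_id[i], mass, sex[i],
                               prints_per_trackway, config,
                               rep(gait, prints_per_trackway),
                               template_override = tpl,
                               role = "fossil", site_id = site_id)
    res$table$sex <- "unknown"   # sexes are hidden in the emitted fossil table
    out[[i]] <- res$table
    truth$body_mass_kg[i] <- mass
    if (divergent) {
      truth$template[i] <- "divergent"
      truth$divergent_shift[i] <- divergent_shift
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  list(trackways = tab, truth = truth, config = config)
}
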