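#' Flag outlying trackway masses for exclusion
#'
#' Supports a manual flag list (e.g. an extreme low outlier that likely
#' represents a child) and an optional automatic rule: modified z-score
#' (0.6745 * (x - median) / MAD) below `-threshold` on the low side.
#'
#' @param masses Numeric vector of predicted trackway masses (kg).
#' @param rule `"none"` (default) or `"modified_z"`.
#' @param flags Manual exclusions: indices into `masses` or names matching
#'   `names(masses)`.
#' @param threshold Modified z-score cutoff (default 3.5).
#' @return Logical exclusion vector with attribute `reasons` (character).
#' @export
detect_outliers <- function(masses, rule = c("none", "modified_z"),
                            flags = NULL, threshold = 3.5) {
  rule <- match.arg(rule)
  n <- length(masses)
  excluded <- rep(FALSE, n)
  reasons <- rep("", n)
  if (!is.null(flags)) {
    idx <- if (is.character(flags)) match(flags, names(masses)) else flags
    if (any(is.na(idx)) || any(idx < 1 | idx > n)) {
      stop("manual flag does not match any trackway", call. = FALSE)
    }
    excluded[idx] <- TRUE
    reasons[idx] <- "manual flag"
  }
  if (rule == "modified_z") {
    if (n < 3) stop("automatic outlier rule needs at least 3 masses",
                    call. = FALSE)
    med <- stats::median(masses)
    mad <- stats::median(abs(masses - med))
    if (mad > 0) {
      mz <- 0.6745 * (masses - med) / mad
      low <- mz < -threshold
      reasons[low & !excluded] <- sprintf("modified z-score %.2f", mz[low & !excluded])
      excluded <- excluded | low
    }
  }
  if (all(excluded)) stop("all masses excluded", call. = FALSE)
  structure(excluded, reasons = reasons)
}

#' Attribute sex to trackways by the mean method
#'
#' The threshold is the mean of the non-excluded predicted masses (assemblage-
#' wide by default, as excluded trackways carry no sex). Masses strictly above
#' the mean are predicted male, below female; a mass exactly at the mean is
#' assigned female with a tie note (conservative toward fewer males).
#'
#' @param masses Numeric vector of predicted trackway masses (kg).
#' @param trackway_id Trackway labels (default: names of `masses` or T01...).
#' @param site_id Optional site labels (recycled).
#' @param exclude Logical exclusion vector, e.g. from [detect_outliers()].
#' @return Data frame of class `sex_attribution`: `trackway_id`, `site_id`,
#'   `predicted_mass_kg`, `threshold_mean_kg`, `excluded`, `exclusion_reason`,
#'   `predicted_sex` (NA when excluded), `tie`.
#' @export
attribute_sex <- function(masses, trackway_id = NULL, site_id = NULL,
                          exclude = NULL) {
  n <- length(masses)
  if (is.null(trackway_id)) {
    trackway_id <- if (!is.null(names(masses))) names(masses)
                   else sprintf("T%02d", seq_len(n))
  }
  if (is.null(site_id)) site_id <- rep("site", n)
  site_id <- rep_len(site_id, n)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  reasons <- attr(exclude, "reasons")
  if (is.null(reasons)) reasons <- ifelse(exclude, "excluded", "")
  usable <- masses[!exclude]
  if (length(usable) < 2) {
    stop("need at least 2 non-excluded masses for the mean method",
         call. = FALSE)
  }
  threshold <- mean(usable)
  sex <- rep(NA_character_, n)
  tie <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (exclude[i]) next
    if (masses[i] > threshold) sex[i] <- "male"
    else if (masses[i] < threshold) sex[i] <- "female"
    else { sex[i] <- "female"; tie[i] <- TRUE }
  }
  if (any(tie)) {
    warning("mass exactly at the assemblage mean for trackway(s) ",
            paste(trackway_id[tie], collapse = ", "),
            "; assigned female (tie rule)", call. = FALSE)
  }
  out <- data.frame(trackway_id = trackway_id, site_id = site_id,
                    predicted_mass_kg = masses,
                    threshold_mean_kg = threshold,
                    excluded = as.logical(exclude),
                    exclusion_reason = reasons,
                    predicted_sex = sex, tie = tie,
                    stringsAsFactors = FALSE)
  class(out) <- c("sex_attribution", "data.frame")
  out
}

#' Per-site composition of sex attributions
#'
#' Counts predicted males, females and excluded trackways per site; the three
#' counts always sum to the site's trackway count.
#'
#' @param attributions A [attribute_sex()] result.
#' @return Data frame with columns `site_id`, `males`, `females`, `excluded`,
#'   `trackways`.
#' @export
site_composition <- function(attributions) {
  stopifnot(inherits(attributions, "sex_attribution") ||
              all(c("site_id", "predicted_sex", "excluded") %in%
                    names(attributions)))
  sites <- unique(attributions$site_id)
  if (length(sites) == 0) {
    return(data.frame(site_id = character(0), males = integer(0),
                      females = integer(0), excluded = integer(0),
                      trackways = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(sites, function(s) {
    a <- attributions[attributions$site_id == s, ]
    data.frame(site_id = s,
               males = sum(!a$excluded & a$predicted_sex == "male", na.rm = TRUE),
               females = sum(!a$excluded & a$predicted_sex == "female", na.rm = TRUE),
               excluded = sum(a$excluded),
               trackways = nrow(a),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
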