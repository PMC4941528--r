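#' Canonical depth-profile regions
#'
#' The 14 functionally relevant footprint regions at which impression depths
#' are measured: the depressions beneath the medial and lateral heel, the
#' medial and lateral midfoot, the five metatarsal heads and the five toes.
#' The order is fixed and canonical; every depth profile in the package is a
#' numeric vector named in this order.
#'
#' @return Character vector of length 14.
#' @export
#' @examples
#' depth_regions()
depth_regions <- function() {
  c("heel_medial", "heel_lateral", "midfoot_medial", "midfoot_lateral",
    "mt1", "mt2", "mt3", "mt4", "mt5",
    "toe1", "toe2", "toe3", "toe4", "toe5")
}

#' Canonical footprint-table column names
#'
#' `depth_columns()` gives the 14 per-region depth columns; `measurement_columns()`
#' the five external print dimensions used as body-mass predictors. Units are
#' embedded in the column names (all centimetres) to prevent unit drift.
#'
#' @return Character vector of column names.
#' @export
depth_columns <- function() {
  paste0("depth_", depth_regions(), "_cm")
}

#' @rdname depth_columns
#' @export
measurement_columns <- function() {
  c("heel_to_hallux_length_cm", "heel_to_t2_length_cm",
    "forefoot_breadth_cm", "heel_breadth_cm", "mean_depth_cm")
}

# Columns that must be present in any footprint table.
required_columns <- function() {
  c("footprint_id", "subject_id", measurement_columns())
}

#' Read a footprint measurement table
#'
#' Reads the canonical delimited-text footprint table: one row per print, with
#' identifier columns (`footprint_id`, `subject_id`, optionally `site_id`,
#' `role`, `gait`, `sex`, `substrate`, `body_mass_kg`), the five external
#' measurement columns and, when available, the 14 regional depth columns.
#' Unknown columns are preserved but ignored by downstream analyses.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` with one row per footprint. Missing optional label
#'   columns are filled with `"unknown"`; `body_mass_kg` with `NA`.
#' @export
read_footprint_table <- function(path) {
  if (!file.exists(path)) {
    stop("footprint table not found: ", path, call. = FALSE)
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_footprint_table(x, context = path)
}

#' @rdname read_footprint_table
#' @param x A footprint `data.frame` to write or validate.
#' @export
write_footprint_table <- function(x, path) {
  x <- validate_footprint_table(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_footprint_table
#' @param context Label used in error messages (e.g. the source file).
#' @export
validate_footprint_table <- function(x, context = "footprint table") {
  missing_cols <- setdiff(required_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop(context, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(c(measurement_columns(), depth_columns(),
                              "body_mass_kg"), names(x))
  for (col in numeric_cols) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(coerced))
      if (length(bad) > 0) {
        stop(context, ": non-numeric value in column '", col, "', row ",
             bad[1], " ('", v[bad[1]], "')", call. = FALSE)
      }
      x[[col]] <- coerced
    }
  }
  for (col in c("site_id", "role", "gait", "sex", "substrate")) {
    if (is.null(x[[col]])) x[[col]] <- "unknown"
  }
  if (is.null(x[["body_mass_kg"]])) x[["body_mass_kg"]] <- NA_real_
  x
}

# Extract the 14-region depth matrix (rows = prints) from a footprint table,
# or NULL if the depth columns are absent.
depth_matrix <- function(x) {
  cols <- depth_columns()
  if (!all(cols %in% names(x))) return(NULL)
  m <- as.matrix(x[, cols, drop = FALSE])
  colnames(m) <- depth_regions()
  m
}
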