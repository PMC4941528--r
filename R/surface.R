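# Relative landmark layout of a left foot: rx across breadth (1 = medial),
# ry along length (0 = heel). Positions are anatomically arranged and spaced
# so neighbouring Gaussian impressions do not overlap at default bump_sd.
landmark_layout <- function() {
  data.frame(
    region = depth_regions(),
    rx = c(0.58, 0.42, 0.62, 0.34,
           0.80, 0.63, 0.46, 0.29, 0.12,
           0.78, 0.60, 0.44, 0.28, 0.13),
    ry = c(0.08, 0.08, 0.40, 0.40,
           0.72, 0.74, 0.73, 0.71, 0.68,
           0.95, 0.96, 0.94, 0.92, 0.89),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic footprint surface
#'
#' Builds a gridded heightmap as a global tilted plane plus 14 negative
#' Gaussian impressions centred at anatomically arranged landmark positions,
#' with depths equal to the supplied profile, plus optional white noise.
#' Landmark coordinates are snapped to grid nodes so that point sampling of a
#' noiseless surface reproduces the profile exactly. The undisturbed-margin
#' mask marks an annulus outside the foot outline; the outline mask marks an
#' ellipse enclosing the foot.
#'
#' @param profile Named numeric vector of 14 depths (cm) over
#'   [depth_regions()].
#' @param length_cm Heel-to-hallux foot length (cm) controlling the layout.
#' @param breadth_cm Foot breadth (cm; default 0.38 * length).
#' @param spacing Grid spacing (cm, > 0).
#' @param tilt Plane slopes `c(dz/dx, dz/dy)` of the undisturbed surface.
#' @param base_elevation Plane intercept (cm).
#' @param bump_sd Gaussian impression radius (cm). The default 0.25 keeps
#'   neighbouring landmarks' impressions independent to below 1e-6 cm.
#' @param noise_sd SD of white measurement noise added to every node (cm).
#' @param seed Optional integer seed (used only when `noise_sd > 0`).
#' @return A [footprint_surface()].
#' @export
generate_surface <- function(profile, length_cm = 26,
                             breadth_cm = 0.38 * length_cm,
                             spacing = 0.25, tilt = c(0, 0),
                             base_elevation = 0, bump_sd = 0.25,
                             noise_sd = 0, seed = NULL) {
  if (spacing <= 0) stop("grid spacing must be positive", call. = FALSE)
  regions <- depth_regions()
  if (is.null(names(profile)) || !all(regions %in% names(profile))) {
    stop("profile must be named with the 14 canonical regions", call. = FALSE)
  }
  profile <- as.numeric(profile[regions])
  if (!is.null(seed)) set.seed(seed)
  pad <- 6
  W <- breadth_cm + 2 * pad
  H <- length_cm + 2 * pad
  xs <- seq(0, W, by = spacing)
  ys <- seq(0, H, by = spacing)
  lay <- landmark_layout()
  lx <- pad + lay$rx * breadth_cm
  ly <- pad + lay$ry * length_cm
  # snap landmarks to grid nodes: exact point sampling on noiseless surfaces
  lx <- xs[pmax(1, pmin(length(xs), round(lx / spacing) + 1))]
  ly <- ys[pmax(1, pmin(length(ys), round(ly / spacing) + 1))]
  Z <- outer(ys, xs, function(y, x) base_elevation + tilt[1] * x + tilt[2] * y)
  for (k in seq_along(regions)) {
    if (profile[k] == 0) next
    gx <- exp(-(xs - lx[k])^2 / (2 * bump_sd^2))
    gy <- exp(-(ys - ly[k])^2 / (2 * bump_sd^2))
    Z <- Z - profile[k] * outer(gy, gx)
  }
  if (noise_sd > 0) {
    Z <- Z + matrix(stats::rnorm(length(Z), 0, noise_sd), nrow(Z), ncol(Z))
  }
  cx <- W / 2; cy <- H / 2
  a <- breadth_cm / 2 + 1.5
  b <- length_cm / 2 + 1.5
  r <- outer(ys, xs, function(y, x) sqrt(((x - cx) / a)^2 + ((y - cy) / b)^2))
  footprint_surface(elevations = Z, spacing = spacing,
                    landmarks = data.frame(region = regions, x = lx, y = ly,
                                           stringsAsFactors = FALSE),
                    margin_mask = r >= 1.35,
                    outline_mask = r <= 1)
}

#' Read and write footprint surfaces as ASCII XYZ grids
#'
#' The surface file is a CSV of grid nodes with columns `x`, `y`, `z`,
#' `margin`, `outline`; the landmark sidecar a CSV with columns `region`,
#' `x`, `y`. Both are plain text and round-trip exactly at the printed
#' precision.
#'
#' @param surface A [footprint_surface()].
#' @param path Surface grid file path.
#' @param landmarks_path Landmark sidecar path.
#' @return `read_surface_xyz` returns a `footprint_surface`;
#'   `write_surface_xyz` returns `path` invisibly.
#' @export
write_surface_xyz <- function(surface, path, landmarks_path) {
  stopifnot(inherits(surface, "footprint_surface"))
  ax <- grid_axes(surface)
  grid <- expand.grid(y = ax$y, x = ax$x)
  df <- data.frame(x = grid$x, y = grid$y,
                   z = as.vector(surface$elevations),
                   margin = as.integer(as.vector(surface$margin_mask)),
                   outline = as.integer(if (is.null(surface$outline_mask)) {
                     rep(0L, length(surface$elevations))
                   } else as.vector(surface$outline_mask)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(surface$landmarks, landmarks_path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_xyz
#' @export
read_surface_xyz <- function(path, landmarks_path) {
  df <- utils::read.csv(path)
  lms <- utils::read.csv(landmarks_path, stringsAsFactors = FALSE)
  xs <- sort(unique(df$x))
  ys <- sort(unique(df$y))
  if (nrow(df) != length(xs) * length(ys)) {
    stop("surface file is not a complete rectangular grid", call. = FALSE)
  }
  spacing <- if (length(xs) > 1) xs[2] - xs[1] else
    if (length(ys) > 1) ys[2] - ys[1] else
      stop("degenerate 1x1 surface grid", call. = FALSE)
  ord <- order(df$x, df$y)
  df <- df[ord, ]
  shape <- function(v) matrix(v, nrow = length(ys), ncol = length(xs))
  footprint_surface(elevations = shape(df$z), spacing = spacing,
                    landmarks = lms,
                    margin_mask = shape(df$margin > 0),
                    outline_mask = shape(df$outline > 0),
                    origin = c(xs[1], ys[1]))
}
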