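#' Footprint surface object
#'
#' A gridded elevation field (cm) with an undisturbed-margin mask, an optional
#' print-outline mask, and the 14 canonical landmark coordinates. Grid node
#' `elevations[i, j]` sits at `x = origin[1] + (j-1)*spacing`,
#' `y = origin[2] + (i-1)*spacing`.
#'
#' @param elevations Numeric matrix of elevations (cm).
#' @param spacing Grid spacing (cm, > 0).
#' @param landmarks Data frame with columns `region` (exactly the canonical
#'   14, see [depth_regions()]), `x`, `y` (cm).
#' @param margin_mask Logical matrix congruent with `elevations`; `TRUE` marks
#'   undisturbed surround used for the reference-plane fit.
#' @param outline_mask Optional logical matrix marking the print outline
#'   (used by the surface form of [mean_depth()]).
#' @param origin Coordinates of grid node `[1, 1]`.
#' @return Object of class `footprint_surface`.
#' @export
footprint_surface <- function(elevations, spacing, landmarks, margin_mask,
                              outline_mask = NULL, origin = c(0, 0)) {
  if (!is.matrix(elevations) || !is.numeric(elevations)) {
    stop("elevations must be a numeric matrix", call. = FALSE)
  }
  if (spacing <= 0) stop("grid spacing must be positive", call. = FALSE)
  if (!is.logical(margin_mask) || !identical(dim(margin_mask), dim(elevations))) {
    stop("margin_mask must be a logical matrix congruent with elevations",
         call. = FALSE)
  }
  if (!is.null(outline_mask) &&
      (!is.logical(outline_mask) || !identical(dim(outline_mask), dim(elevations)))) {
    stop("outline_mask must be a logical matrix congruent with elevations",
         call. = FALSE)
  }
  if (!all(c("region", "x", "y") %in% names(landmarks)) ||
      !identical(sort(landmarks$region), sort(depth_regions()))) {
    stop("landmarks must carry exactly the 14 canonical regions", call. = FALSE)
  }
  landmarks <- landmarks[match(depth_regions(), landmarks$region), ]
  rownames(landmarks) <- NULL
  structure(list(elevations = elevations, spacing = spacing,
                 origin = origin, landmarks = landmarks,
                 margin_mask = margin_mask, outline_mask = outline_mask),
            class = "footprint_surface")
}

#' @export
print.footprint_surface <- function(x, ...) {
  cat("footprint_surface:", nrow(x$elevations), "x", ncol(x$elevations),
      "grid at", x$spacing, "cm spacing\n")
  cat("  margin cells:", sum(x$margin_mask),
      " outline cells:", if (is.null(x$outline_mask)) 0 else sum(x$outline_mask),
      "\n")
  invisible(x)
}

# Grid node coordinate vectors.
grid_axes <- function(surface) {
  list(x = surface$origin[1] + (seq_len(ncol(surface$elevations)) - 1) * surface$spacing,
       y = surface$origin[2] + (seq_len(nrow(surface$elevations)) - 1) * surface$spacing)
}

#' Fit the undisturbed-surface reference plane
#'
#' Least-squares plane `z = a*x + b*y + c` through the grid cells marked
#' undisturbed by the margin mask. The fitted plane defines the X-Y reference
#' from which impression depths are measured.
#'
#' @param surface A [footprint_surface()].
#' @return Object of class `reference_plane`: `coefficients` (a, b, c) and
#'   `rms` (residual root-mean-square, cm).
#' @export
fit_reference_plane <- function(surface) {
  stopifnot(inherits(surface, "footprint_surface"))
  idx <- which(surface$margin_mask, arr.ind = TRUE)
  if (nrow(idx) < 3) {
    stop("degenerate plane fit: fewer than 3 undisturbed margin cells",
         call. = FALSE)
  }
  ax <- grid_axes(surface)
  X <- cbind(ax$x[idx[, 2]], ax$y[idx[, 1]], 1)
  z <- surface$elevations[idx]
  qr_fit <- qr(X)
  if (qr_fit$rank < 3) {
    stop("degenerate plane fit: margin cells are collinear", call. = FALSE)
  }
  beta <- qr.coef(qr_fit, z)
  res <- z - X %*% beta
  structure(list(coefficients = c(a = beta[1], b = beta[2], c = beta[3]),
                 rms = sqrt(mean(res^2))),
            class = "reference_plane")
}

#' @export
print.reference_plane <- function(x, ...) {
  cat(sprintf("reference_plane: z = %.6g*x + %.6g*y + %.6g (residual RMS %.3g cm)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3], x$rms))
  invisible(x)
}

#' Orient a surface to its reference plane
#'
#' Replaces elevations by residuals from the (fitted or supplied) reference
#' plane, so that the undisturbed surround lies at z = 0 and impression depths
#' are read directly below it. Orientation is idempotent: re-fitting after
#' orientation yields the zero plane.
#'
#' @param surface A [footprint_surface()].
#' @param plane Optional [fit_reference_plane()] result; fitted if omitted.
#' @return The oriented `footprint_surface`.
#' @export
orient_surface <- function(surface, plane = NULL) {
  stopifnot(inherits(surface, "footprint_surface"))
  if (is.null(plane)) plane <- fit_reference_plane(surface)
  ax <- grid_axes(surface)
  cf <- plane$coefficients
  plane_z <- outer(ax$y, ax$x, function(y, x) cf[1] * x + cf[2] * y + cf[3])
  surface$elevations <- surface$elevations - plane_z
  surface
}

#' Measure landmark depths on an oriented surface
#'
#' Samples the oriented elevation field at each of the 14 landmark positions
#' (bilinear interpolation) and reports depths positive downward from the
#' reference plane. Negative depths (a raised displacement rim at a landmark)
#' are allowed and flagged with a warning. The `"local_min"` method instead
#' takes the deepest grid node within `radius` of the landmark.
#'
#' @param surface An oriented [footprint_surface()].
#' @param method `"point"` (interpolated point sample, default) or
#'   `"local_min"`.
#' @param radius Neighbourhood radius (cm) for `"local_min"`.
#' @return Named numeric vector of 14 depths (cm, positive downward).
#' @export
measure_depths <- function(surface, method = c("point", "local_min"),
                           radius = 0.5) {
  stopifnot(inherits(surface, "footprint_surface"))
  method <- match.arg(method)
  ax <- grid_axes(surface)
  lm <- surface$landmarks
  if (any(lm$x < min(ax$x) | lm$x > max(ax$x) |
          lm$y < min(ax$y) | lm$y > max(ax$y))) {
    bad <- lm$region[lm$x < min(ax$x) | lm$x > max(ax$x) |
                     lm$y < min(ax$y) | lm$y > max(ax$y)]
    stop("landmark(s) outside grid extent: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (method == "point") {
    z <- pracma::interp2(ax$x, ax$y, surface$elevations, lm$x, lm$y,
                         method = "linear")
    depths <- -z
  } else {
    depths <- vapply(seq_len(nrow(lm)), function(k) {
      dx <- outer(rep(1, length(ax$y)), ax$x) - lm$x[k]
      dy <- outer(ax$y, rep(1, length(ax$x))) - lm$y[k]
      near <- dx^2 + dy^2 <= radius^2
      if (!any(near)) return(-pracma::interp2(ax$x, ax$y, surface$elevations,
                                              lm$x[k], lm$y[k]))
      max(-surface$elevations[near])
    }, numeric(1))
  }
  names(depths) <- lm$region
  if (any(depths < 0)) {
    warning("negative depth (raised surface) at: ",
            paste(names(depths)[depths < 0], collapse = ", "), call. = FALSE)
  }
  depths
}

#' Average footprint depth
#'
#' The mean-depth predictor of the body-mass model. For an oriented surface,
#' the default is the mean depth over the print-outline cells; for a depth
#' profile (named 14-vector or table row), the mean of the 14 regional depths.
#' The form used is recorded in the `"source"` attribute.
#'
#' @param x A `footprint_surface` or a numeric depth profile.
#' @param ... Passed to methods.
#' @return Mean depth in cm, with attribute `source`.
#' @export
mean_depth <- function(x, ...) UseMethod("mean_depth")

#' @rdname mean_depth
#' @param source `"outline"` (mean over outline cells) or `"landmarks"`
#'   (mean of the 14 regional depths).
#' @export
mean_depth.footprint_surface <- function(x, source = c("outline", "landmarks"),
                                         ...) {
  source <- match.arg(source)
  if (source == "outline") {
    if (is.null(x$outline_mask) || !any(x$outline_mask)) {
      stop("surface has no outline mask cells", call. = FALSE)
    }
    d <- mean(-x$elevations[x$outline_mask])
  } else {
    d <- mean(suppressWarnings(measure_depths(x)))
  }
  structure(d, source = source)
}

#' @rdname mean_depth
#' @export
mean_depth.default <- function(x, ...) {
  x <- as.numeric(x)
  if (length(x) == 0 || any(!is.finite(x))) {
    stop("depth profile must be non-empty and finite", call. = FALSE)
  }
  structure(mean(x), source = "profile")
}

#' Forefoot depth gradient
#'
#' Least-squares slope of depth against medial-to-lateral position (1..5)
#' across the metatarsal heads (mt1..mt5) and across the toes (toe1..toe5).
#' Human walking prints show negative slopes (medial deeper), reflecting
#' medial weight transfer and toe-off through the first two digits.
#'
#' @param profile Named numeric depth profile over [depth_regions()].
#' @return Named vector `c(mt_slope, toe_slope)` in cm per position.
#' @export
forefoot_gradient <- function(profile) {
  stopifnot(all(c(paste0("mt", 1:5), paste0("toe", 1:5)) %in% names(profile)))
  pos <- 1:5
  slope <- function(d) sum((pos - 3) * d) / sum((pos - 3)^2)
  c(mt_slope = slope(as.numeric(profile[paste0("mt", 1:5)])),
    toe_slope = slope(as.numeric(profile[paste0("toe", 1:5)])))
}
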