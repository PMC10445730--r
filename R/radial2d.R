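#' A closed cubic-spline nucleus contour
#'
#' The manual 2D segmentation path: five or more control points define a
#' closed periodic cubic spline around one nucleus on the maximum projection.
#'
#' @param nucleus nucleus id.
#' @param control_points numeric matrix (n x 2) of (y, x) pixel coordinates,
#'   n >= 5, in drawing order.
#' @return A `spline_roi` object.
#' @export
spline_roi <- function(nucleus, control_points) {
  control_points <- as.matrix(control_points)
  if (nrow(control_points) < 5 || ncol(control_points) != 2 ||
      anyNA(control_points))
    abort("a spline ROI needs >= 5 finite (y, x) control points")
  structure(list(nucleus = nucleus, control_points = control_points),
            class = "spline_roi")
}

# sample the closed periodic cubic spline as a dense polygon (m x 2, (y, x));
# uniform parameterization over control points, >= samples_per_px points per
# pixel of estimated arc length
sample_spline <- function(roi, samples_per_px = 8) {
  cp <- roi$control_points
  n <- nrow(cp)
  perim <- sum(sqrt(rowSums((cp - cp[c(2:n, 1), ])^2)))
  m <- max(64L, ceiling(samples_per_px * perim))
  t_in <- 0:n
  t_out <- seq(0, n, length.out = m + 1L)[-(m + 1L)]
  ys <- spline(t_in, c(cp[, 1], cp[1, 1]), method = "periodic",
               xout = t_out)$y
  xs <- spline(t_in, c(cp[, 2], cp[1, 2]), method = "periodic",
               xout = t_out)$y
  cbind(y = ys, x = xs)
}

# TRUE if the closed polygon given as an m x 2 matrix self-intersects
polygon_self_intersects <- function(poly) {
  m <- nrow(poly)
  a <- poly
  b <- poly[c(2:m, 1), ]
  # orientation of point r relative to segment p->q
  cross <- function(py, px, qy, qx, ry, rx) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  for (i in seq_len(m - 2L)) {
    j <- (i + 2L):m
    j <- j[!(i == 1L & j == m)]            # skip shared-endpoint neighbours
    if (length(j) == 0) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], rep(a[i, 1], length(j)), rep(a[i, 2], length(j)))
    d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], rep(b[i, 1], length(j)), rep(b[i, 2], length(j)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Rasterize a spline ROI to a binary mask
#'
#' Densely samples the closed spline, validates that it does not
#' self-intersect, and fills pixels whose centres lie inside the curve
#' (even-odd rule, scanline fill).
#'
#' @param roi a [spline_roi()].
#' @param image_shape (H, W) of the target image in pixels.
#' @param samples_per_px spline densification, samples per pixel of arc.
#' @return Logical H x W matrix.
#' @export
rasterize_spline <- function(roi, image_shape, samples_per_px = 8) {
  stopifnot(inherits(roi, "spline_roi"))
  if (length(image_shape) != 2 || any(image_shape < 1))
    abort("`image_shape` must be (H, W)")
  poly <- sample_spline(roi, samples_per_px)
  # validate on a coarser sampling: intersection is a curve property, and the
  # quadratic pair check gets slow beyond ~1e3 segments
  check_poly <- if (nrow(poly) > 600) {
    poly[seq(1, nrow(poly), length.out = 600), ]
  } else poly
  if (polygon_self_intersects(check_poly))
    abort(paste0("spline ROI for nucleus ", roi$nucleus, " self-intersects"))
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  mask <- matrix(FALSE, H, W)
  m <- nrow(poly)
  y1 <- poly[, 1]; x1 <- poly[, 2]
  y2 <- poly[c(2:m, 1), 1]; x2 <- poly[c(2:m, 1), 2]
  for (row in seq_len(H)) {
    crosses <- (y1 <= row & y2 > row) | (y2 <= row & y1 > row)
    if (!any(crosses)) next
    xc <- x1[crosses] + (row - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xc <- sort(xc)
    for (p in seq(1, length(xc) - 1, by = 2)) {
      j0 <- ceiling(xc[p] + 1e-9); j1 <- floor(xc[p + 1] - 1e-9)
      if (j1 >= j0) {
        j0 <- max(1L, j0); j1 <- min(W, j1)
        if (j1 >= j0) mask[row, j0:j1] <- TRUE
      }
    }
  }
  mask
}

#' Normalized contour distance map of a nucleus mask
#'
#' Euclidean distance transform of the mask — the distance of each interior
#' pixel to the nearest background pixel, i.e. to the segmentation contour —
#' divided by its per-nucleus maximum. Values run from ~0 at the contour to
#' exactly 1 at the deepest interior point (the nucleus centre for a disk).
#'
#' @param mask logical 2D matrix (nonempty).
#' @param nucleus nucleus id carried along for reporting.
#' @return A `normalized_distance_map`: list with `nucleus`, `map` (matrix in
#'   \[0, 1\]), `max_raw` (maximum raw distance, pixels) and `argmax`
#'   (1-based (y, x) of the maximum).
#' @export
normalized_distance_map <- function(mask, nucleus = NA_integer_) {
  if (!is.matrix(mask)) abort("`mask` must be a 2D matrix")
  mask <- mask > 0
  if (!any(mask)) abort("empty mask: no interior to map")
  dt <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
  dt <- as.matrix(EBImage::imageData(dt))
  mx <- max(dt)
  am <- which(dt == mx, arr.ind = TRUE)[1, ]
  structure(list(nucleus = nucleus, map = dt / mx, max_raw = mx,
                 argmax = as.integer(am)),
            class = "normalized_distance_map")
}

#' Normalized radial position of a 2D spot
#'
#' Bilinear interpolation of the normalized distance map at the spot's
#' (y, x) coordinate; falls back to the nearest pixel at the mask edge where
#' one of the four surrounding pixels is background.
#'
#' @param spot_yx numeric (y, x) pixel coordinate (1-based, sub-pixel allowed).
#' @param ndmap a [normalized_distance_map()].
#' @return Value in \[0, 1\]: 0 at the periphery, 1 at the centre.
#' @export
normalized_position <- function(spot_yx, ndmap) {
  stopifnot(inherits(ndmap, "normalized_distance_map"))
  m <- ndmap$map
  yi <- round(spot_yx[1]); xi <- round(spot_yx[2])
  if (yi < 1 || yi > nrow(m) || xi < 1 || xi > ncol(m) || m[yi, xi] <= 0)
    abort(paste0("spot (", signif(spot_yx[1], 5), ", ", signif(spot_yx[2], 5),
                 ") lies outside the ROI mask of nucleus ", ndmap$nucleus))
  y0 <- floor(spot_yx[1]); x0 <- floor(spot_yx[2])
  y1 <- min(y0 + 1, nrow(m)); x1 <- min(x0 + 1, ncol(m))
  fy <- spot_yx[1] - y0; fx <- spot_yx[2] - x0
  corners <- c(m[y0, x0], m[y0, x1], m[y1, x0], m[y1, x1])
  if (any(corners <= 0)) return(m[yi, xi])   # nearest-pixel fallback at edge
  (1 - fy) * ((1 - fx) * m[y0, x0] + fx * m[y0, x1]) +
    fy * ((1 - fx) * m[y1, x0] + fx * m[y1, x1])
}

#' Normalized radial positions for a table of 2D spots
#'
#' Rasterizes each ROI, builds its normalized distance map, and looks up every
#' spot of that nucleus. Spots outside their ROI raise an error naming the
#' nucleus.
#'
#' @param spots2d tibble with columns `nucleus`, `y`, `x` (pixel coordinates
#'   on the maximum projection; sub-pixel allowed).
#' @param rois list of [spline_roi()] objects.
#' @param image_shape (H, W) of the projection.
#' @param condition optional condition label.
#' @return Tibble of distance records: `nucleus`, `y`, `x`,
#'   `normalized_position`, and `condition` if given.
#' @export
radial_positions <- function(spots2d, rois, image_shape, condition = NULL) {
  roi_ids <- vapply(rois, function(r) r$nucleus, numeric(1))
  out <- purrr::map_dfr(unique(spots2d$nucleus), function(k) {
    i <- which(roi_ids == k)
    if (length(i) == 0)
      abort(paste0("no spline ROI provided for nucleus ", k))
    mask <- rasterize_spline(rois[[i[1]]], image_shape)
    ndmap <- normalized_distance_map(mask, nucleus = k)
    sp <- spots2d[spots2d$nucleus == k, , drop = FALSE]
    tibble(nucleus = k, y = sp$y, x = sp$x,
           normalized_position = vapply(seq_len(nrow(sp)), function(j) {
             normalized_position(c(sp$y[j], sp$x[j]), ndmap)
           }, numeric(1)))
  })
  if (!is.null(condition) && nrow(out) > 0) out$condition <- condition
  out
}
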