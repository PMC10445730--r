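#' Parameters for Difference-of-Gaussians spot detection
#'
#' Dots are detected as local maxima of the band-pass response
#' `G(sigma_small) * v - G(sigma_large) * v` (26-neighbourhood), then refined
#' to sub-voxel precision by a local 3D centre of mass. Sigmas are in voxels,
#' per axis (z, y, x), so the anisotropic z step is handled naturally.
#'
#' @param sigma_small_zyx small Gaussian sigma per axis (voxels); a good
#'   default is the PSF sigma expressed in voxels.
#' @param sigma_large_zyx large Gaussian sigma per axis; defaults to
#'   `1.6 * sigma_small_zyx`, the classic blob-detection ratio.
#' @param response_threshold minimum DoG response for a candidate. `NULL`
#'   (default) estimates it per volume as
#'   `median(response) + threshold_k * mad(response)`.
#' @param threshold_k robustness multiplier for the automatic threshold.
#' @param com_window_zyx odd refinement-window size per axis; defaults to
#'   `2 * ceiling(2 * sigma_small) + 1`.
#' @param strict_maxima if `TRUE` a candidate must exceed all 26 neighbours;
#'   if `FALSE`, plateau voxels (equal to their neighbours) also qualify.
#' @param candidate_mode `"maxima"` (default) keeps local maxima only — the
#'   right notion for isolated diffraction-limited dots. `"dense"` keeps every
#'   voxel at or above the threshold, which samples an extended ridge-like
#'   structure such as the lamin shell densely instead of at its (few) strict
#'   maxima.
#' @param refine whether to refine candidates by centre of mass in
#'   [localize_spots()].
#' @return A `dog_params` object.
#' @export
dog_params <- function(sigma_small_zyx = c(1.2, 1.3, 1.3),
                       sigma_large_zyx = NULL,
                       response_threshold = NULL,
                       threshold_k = 6,
                       com_window_zyx = NULL,
                       strict_maxima = TRUE,
                       candidate_mode = c("maxima", "dense"),
                       refine = TRUE) {
  candidate_mode <- match.arg(candidate_mode)
  sigma_small_zyx <- check_len3(sigma_small_zyx, "sigma_small_zyx")
  if (is.null(sigma_large_zyx)) sigma_large_zyx <- 1.6 * sigma_small_zyx
  sigma_large_zyx <- check_len3(sigma_large_zyx, "sigma_large_zyx")
  if (any(sigma_large_zyx <= sigma_small_zyx))
    abort("`sigma_large_zyx` must exceed `sigma_small_zyx` on every axis")
  if (is.null(com_window_zyx))
    com_window_zyx <- 2L * as.integer(ceiling(2 * sigma_small_zyx)) + 1L
  com_window_zyx <- check_odd3(com_window_zyx, "com_window_zyx")
  if (!is.null(response_threshold) &&
      (!is.numeric(response_threshold) || length(response_threshold) != 1L))
    abort("`response_threshold` must be a single number or NULL")
  if (threshold_k <= 0) abort("`threshold_k` must be positive")
  structure(list(sigma_small_zyx = sigma_small_zyx,
                 sigma_large_zyx = sigma_large_zyx,
                 response_threshold = response_threshold,
                 threshold_k = threshold_k,
                 com_window_zyx = com_window_zyx,
                 strict_maxima = isTRUE(strict_maxima),
                 candidate_mode = candidate_mode,
                 refine = isTRUE(refine)),
            class = "dog_params")
}

#' Separable 3D Gaussian blur
#'
#' @param volume 3D numeric array (z, y, x).
#' @param sigma_zyx per-axis sigma in voxels; a zero sigma skips that axis.
#' @return Blurred array (reflected borders).
#' @export
gaussian_blur_3d <- function(volume, sigma_zyx) {
  check_volume(volume)
  sigma_zyx <- check_len3(sigma_zyx, "sigma_zyx", positive = FALSE)
  if (any(sigma_zyx < 0)) abort("sigmas must be >= 0")
  gauss_blur3d_cpp(volume, dim(volume), sigma_zyx[1], sigma_zyx[2], sigma_zyx[3])
}

#' Difference-of-Gaussians response
#'
#' @param volume 3D numeric array.
#' @param params a [dog_params()] object.
#' @return The band-pass response, same shape as `volume`.
#' @export
dog_filter <- function(volume, params = dog_params()) {
  stopifnot(inherits(params, "dog_params"))
  gaussian_blur_3d(volume, params$sigma_small_zyx) -
    gaussian_blur_3d(volume, params$sigma_large_zyx)
}

dog_auto_threshold <- function(response, k, dense_floor = 0) {
  med <- median(response)
  thr <- med + k * stats::mad(response, center = med)
  if (dense_floor > 0) {
    # dense sampling keeps every voxel above threshold, so the robust noise
    # estimate alone is too permissive on low-noise data: it would admit the
    # faint inner DoG side-lobe of the shell. Floor the threshold at a
    # fraction of the response range above the median.
    thr <- max(thr, med + dense_floor * (max(response) - med))
  }
  thr
}

#' Detect spot candidates by Difference of Gaussians
#'
#' Candidates are 26-neighbourhood local maxima of the DoG response with
#' response at or above the threshold, sorted by descending response.
#' Deterministic: identical inputs give identical candidate lists.
#'
#' @param volume 3D numeric array (z, y, x).
#' @param params a [dog_params()] object.
#' @return Tibble with integer voxel coordinates `z`, `y`, `x` (1-based) and
#'   the DoG `response`.
#' @export
dog_detect <- function(volume, params = dog_params()) {
  check_volume(volume)
  stopifnot(inherits(params, "dog_params"))
  resp <- dog_filter(volume, params)
  thr <- params$response_threshold
  if (is.null(thr))
    thr <- dog_auto_threshold(resp, params$threshold_k,
                              dense_floor =
                                if (params$candidate_mode == "dense") 0.1 else 0)
  if (params$candidate_mode == "dense") {
    cand <- which(resp >= thr, arr.ind = TRUE)
    colnames(cand) <- c("z", "y", "x")
    out <- tibble(z = as.integer(cand[, "z"]), y = as.integer(cand[, "y"]),
                  x = as.integer(cand[, "x"]))
  } else {
    cand <- local_maxima3d_cpp(resp, dim(resp), thr, params$strict_maxima)
    out <- tibble(z = cand[, "z"] + 1L, y = cand[, "y"] + 1L,
                  x = cand[, "x"] + 1L)
  }
  out$response <- resp[cbind(out$z, out$y, out$x)]
  dplyr::arrange(out, dplyr::desc(.data$response), .data$z, .data$y, .data$x)
}

#' Sub-voxel refinement by local 3D centre of mass
#'
#' Replaces an integer voxel coordinate by the intensity-weighted mean
#' coordinate over an odd window centred on it (clipped at borders). The
#' window minimum is subtracted before weighting so that a uniform background
#' does not pull the estimate toward the window centre. If the window carries
#' zero total mass after subtraction, the input coordinate is returned and
#' flagged.
#'
#' @param volume 3D numeric array (z, y, x).
#' @param voxel_zyx integer coordinate (1-based) inside the volume.
#' @param window odd window size per axis (z, y, x).
#' @return Numeric (z, y, x) coordinate with attribute `degenerate` set to
#'   `TRUE` when refinement was impossible.
#' @export
refine_com <- function(volume, voxel_zyx, window = c(5L, 7L, 7L)) {
  check_volume(volume)
  window <- check_odd3(window, "window")
  d <- dim(volume)
  if (any(voxel_zyx < 1) || any(voxel_zyx > d))
    abort("`voxel_zyx` must lie inside the volume")
  r <- (window - 1L) %/% 2L
  idx <- lapply(1:3, function(i) {
    max(1L, voxel_zyx[i] - r[i]):min(d[i], voxel_zyx[i] + r[i])
  })
  w <- volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  w <- w - min(w)
  total <- sum(w)
  if (total <= 0) {
    out <- as.numeric(voxel_zyx)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  com <- vapply(1:3, function(i) {
    ax <- slice.index(w, i)
    sum(w * idx[[i]][ax]) / total
  }, numeric(1))
  attr(com, "degenerate") <- FALSE
  com
}

#' Detect, refine and assign spots in one channel
#'
#' Runs [dog_detect()] on the requested channel, refines every candidate by
#' [refine_com()], converts to physical coordinates (0-based voxel index times
#' per-axis voxel size, voxel-centre convention) and assigns each spot the
#' nucleus label at its integer detection voxel (label 0 becomes `NA`:
#' detected outside every nucleus and excluded from distance analysis).
#'
#' @param stack an [image_stack()].
#' @param channel channel role: `"probe"` or `"lamin"` (or `"dna"`).
#' @param labels a `labeled_nuclei` object from [segment_nuclei()], or `NULL`
#'   to skip assignment.
#' @param params a [dog_params()] object.
#' @return Tibble with one row per spot: `channel`, integer voxel coordinates
#'   `z`, `y`, `x`, refined coordinates `zr`, `yr`, `xr`, physical coordinates
#'   `z_um`, `y_um`, `x_um`, `nucleus` (NA if unassigned), `response` and
#'   `degenerate` (centre-of-mass fallback flag).
#' @export
localize_spots <- function(stack, channel = "probe", labels = NULL,
                           params = dog_params()) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels))
    abort(paste0("channel `", channel, "` not present in stack"))
  vol <- stack$channels[[channel]]
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "labeled_nuclei"))
    if (!identical(dim(labels$label_volume), dim(vol)))
      abort("label volume shape does not match the stack")
  }
  cand <- dog_detect(vol, params)
  n <- nrow(cand)
  ref <- cbind(as.numeric(cand$z), as.numeric(cand$y), as.numeric(cand$x))
  degenerate <- logical(n)
  if (params$refine) {
    for (i in seq_len(n)) {
      rc <- refine_com(vol, c(cand$z[i], cand$y[i], cand$x[i]),
                       params$com_window_zyx)
      ref[i, ] <- rc
      degenerate[i] <- attr(rc, "degenerate")
    }
  }
  vs <- stack$voxel_size_zyx
  lab <- if (is.null(labels)) rep(NA_integer_, n) else {
    l <- labels$label_volume[cbind(cand$z, cand$y, cand$x)]
    ifelse(l == 0L, NA_integer_, l)
  }
  tibble(channel = rep(channel, n),
         z = cand$z, y = cand$y, x = cand$x,
         zr = ref[, 1], yr = ref[, 2], xr = ref[, 3],
         z_um = (ref[, 1] - 1) * vs[1],
         y_um = (ref[, 2] - 1) * vs[2],
         x_um = (ref[, 3] - 1) * vs[3],
         nucleus = lab, response = cand$response, degenerate = degenerate)
}

#' Densely sample the lamin staining as a per-nucleus point cloud
#'
#' Applies the same detector to the lamin channel with a permissive threshold
#' and plateau-tolerant maxima, so the shell is sampled densely, and groups
#' the resulting physical points by nucleus label. Nuclei without any lamin
#' point are excluded from 3D distance analysis and reported in the
#' `excluded_nuclei` attribute.
#'
#' @param stack an [image_stack()].
#' @param labels a `labeled_nuclei` object.
#' @param params a [dog_params()] object; the default keeps every voxel whose
#'   DoG response clears the robust background threshold
#'   (`candidate_mode = "dense"`), refined by centre of mass over a tight
#'   3x5x5 window — a larger window would average over the curved shell and
#'   bias points toward the nucleus interior.
#' @return Tibble of lamin points (`nucleus`, `z_um`, `y_um`, `x_um`) with
#'   attribute `excluded_nuclei` (labels with zero points).
#' @export
lamin_point_cloud <- function(stack, labels,
                              params = dog_params(candidate_mode = "dense",
                                                  com_window_zyx = c(3L, 5L, 5L))) {
  pts <- localize_spots(stack, "lamin", labels, params)
  pts <- dplyr::filter(pts, !is.na(.data$nucleus))
  cloud <- dplyr::select(pts, "nucleus", "z_um", "y_um", "x_um")
  all_labels <- labels$nuclei$nucleus
  excluded <- setdiff(all_labels, unique(cloud$nucleus))
  if (length(excluded) > 0)
    warn(paste0("no lamin points for nucleus(ei) ",
                paste(excluded, collapse = ", "),
                "; excluded from 3D distances"))
  attr(cloud, "excluded_nuclei") <- excluded
  cloud
}
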