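#' Parameters for a synthetic FISH scene
#'
#' Describes a 3-channel 3D stack of densely packed near-ellipsoidal nuclei
#' (DNA counterstain), a thin bright lamin shell at each nucleus boundary, and
#' diffraction-limited probe spots placed at requested normalized radial
#' positions. The normalized radial position r runs from 0 at the nuclear
#' periphery to 1 at the nucleus centre.
#'
#' @param shape_zyx integer voxel counts per axis, (z, y, x).
#' @param voxel_size_zyx physical voxel size in micrometres per axis, (z, y, x).
#'   Defaults emulate a 100x oil objective with an anisotropic z step.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_semiaxes_um length-2 range (min, max) from which each
#'   ellipsoid semi-axis is drawn, in micrometres.
#' @param shell_thickness_um full thickness of the lamin shell, centred on the
#'   ellipsoid surface.
#' @param spots_spec data frame with columns `nucleus` (1-based index), `r`
#'   (normalized radial position in \[0, 1\], 1 = centre) and `amplitude`
#'   (peak counts). One probe spot is rendered per row.
#' @param psf_sigma_um per-axis Gaussian PSF sigma (z, y, x), micrometres.
#' @param background mean background level added before Poisson noise (counts).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param dna_amplitude,lamin_amplitude peak counts of the counterstain
#'   interior and of the lamin shell.
#' @param min_gap_um minimum surface-to-surface gap enforced between nuclei
#'   (conservatively, between bounding spheres).
#' @param max_placement_tries re-draws allowed before giving up on a
#'   non-overlapping placement.
#' @param seed integer seed making the scene reproducible.
#'
#' @return A validated `scene_params` object (a list).
#' @seealso [generate_scene()]
#' @export
scene_params <- function(shape_zyx = c(32L, 256L, 256L),
                         voxel_size_zyx = c(0.3, 0.1, 0.1),
                         n_nuclei = 10L,
                         nucleus_semiaxes_um = c(1.6, 2.2),
                         shell_thickness_um = 0.2,
                         spots_spec = NULL,
                         psf_sigma_um = c(0.35, 0.13, 0.13),
                         background = 20,
                         read_noise_sd = 3,
                         dna_amplitude = 300,
                         lamin_amplitude = 500,
                         min_gap_um = 0.8,
                         max_placement_tries = 5000L,
                         seed = 1L) {
  shape_zyx <- check_len3(shape_zyx, "shape_zyx")
  if (any(shape_zyx != round(shape_zyx))) abort("`shape_zyx` must be integer")
  voxel_size_zyx <- check_len3(voxel_size_zyx, "voxel_size_zyx")
  psf_sigma_um <- check_len3(psf_sigma_um, "psf_sigma_um")
  if (!is.numeric(n_nuclei) || n_nuclei < 1) abort("`n_nuclei` must be >= 1")
  if (length(nucleus_semiaxes_um) != 2L || any(nucleus_semiaxes_um <= 0) ||
      nucleus_semiaxes_um[1] > nucleus_semiaxes_um[2])
    abort("`nucleus_semiaxes_um` must be a positive (min, max) range")
  if (shell_thickness_um <= 0) abort("`shell_thickness_um` must be positive")
  if (background < 0) abort("`background` must be >= 0")
  if (read_noise_sd < 0) abort("`read_noise_sd` must be >= 0")
  if (is.null(spots_spec)) {
    spots_spec <- tibble(nucleus = integer(), r = numeric(), amplitude = numeric())
  }
  spots_spec <- as_tibble(spots_spec)
  if (!all(c("nucleus", "r", "amplitude") %in% names(spots_spec)))
    abort("`spots_spec` needs columns nucleus, r, amplitude")
  if (nrow(spots_spec) > 0) {
    if (any(spots_spec$r < 0 | spots_spec$r > 1))
      abort("every requested `r` must lie in [0, 1]")
    if (any(spots_spec$nucleus < 1 | spots_spec$nucleus > n_nuclei) ||
        any(spots_spec$nucleus != round(spots_spec$nucleus)))
      abort("`spots_spec$nucleus` must index an existing nucleus")
    if (any(spots_spec$amplitude <= 0)) abort("spot amplitudes must be positive")
  }
  structure(list(
    shape_zyx = as.integer(shape_zyx), voxel_size_zyx = voxel_size_zyx,
    n_nuclei = as.integer(n_nuclei), nucleus_semiaxes_um = nucleus_semiaxes_um,
    shell_thickness_um = shell_thickness_um, spots_spec = spots_spec,
    psf_sigma_um = psf_sigma_um, background = background,
    read_noise_sd = read_noise_sd, dna_amplitude = dna_amplitude,
    lamin_amplitude = lamin_amplitude, min_gap_um = min_gap_um,
    max_placement_tries = as.integer(max_placement_tries),
    seed = as.integer(seed)
  ), class = "scene_params")
}

#' Construct a 3-channel image stack
#'
#' @param dna,probe,lamin 3D numeric arrays indexed (z, y, x), identical shape.
#' @param voxel_size_zyx micrometres per voxel, (z, y, x).
#' @return An `image_stack` object.
#' @export
image_stack <- function(dna, probe, lamin, voxel_size_zyx) {
  check_volume(dna, "dna"); check_volume(probe, "probe")
  check_volume(lamin, "lamin")
  if (!identical(dim(dna), dim(probe)) || !identical(dim(dna), dim(lamin)))
    abort("all three channels must share the same shape")
  voxel_size_zyx <- check_len3(voxel_size_zyx, "voxel_size_zyx")
  if (min(dna, probe, lamin) < 0) abort("channel counts must be >= 0")
  structure(list(channels = list(dna = dna, probe = probe, lamin = lamin),
                 voxel_size_zyx = voxel_size_zyx),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels$dna)
  cat(sprintf("<image_stack> %d x %d x %d voxels (z,y,x), voxel %s um, channels: %s\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size_zyx, 3), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# radius of an axis-aligned ellipsoid along unit direction u (rows of n x 3)
ellipsoid_ray_radius <- function(u, semiaxes) {
  1 / sqrt(rowSums(sweep(u, 2, semiaxes, `/`)^2))
}

#' Exact distance from an interior point to an ellipsoid surface
#'
#' Solves the point-to-ellipsoid projection via its Lagrange condition with a
#' bracketed root search; exact (closed form) for spheres.
#'
#' @param point_um point coordinate (z, y, x) in micrometres.
#' @param center_um ellipsoid centre (z, y, x) in micrometres.
#' @param semiaxes_um per-axis semi-axes (z, y, x) in micrometres.
#' @return Euclidean distance to the surface in micrometres.
#' @export
ellipsoid_surface_distance <- function(point_um, center_um, semiaxes_um) {
  p <- point_um - center_um
  a <- semiaxes_um
  if (max(abs(a - a[1])) < 1e-12) {           # sphere: closed form
    return(abs(a[1] - sqrt(sum(p^2))))
  }
  if (all(abs(p) < 1e-12)) return(min(a))      # centre: nearest pole
  # closest surface point q_i = a_i^2 p_i / (a_i^2 + t); interior root
  # t in (-min(a)^2, 0]
  g <- function(t) sum((a^2 * p / (a^2 + t))^2 / a^2) - 1
  lo <- -min(a)^2 * (1 - 1e-9)
  root <- stats::uniroot(g, c(lo, max(a)^2), tol = 1e-12)$root
  q <- a^2 * p / (a^2 + root)
  sqrt(sum((q - p)^2))
}

place_nuclei <- function(params) {
  ext <- params$shape_zyx * params$voxel_size_zyx
  rng <- params$nucleus_semiaxes_um
  centers <- matrix(NA_real_, 0, 3)
  axes <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(centers) < params$n_nuclei) {
    tries <- tries + 1L
    if (tries > params$max_placement_tries)
      abort(paste0("could not place ", params$n_nuclei,
                   " non-overlapping nuclei in ", params$max_placement_tries,
                   " tries; shrink nuclei or enlarge the volume"))
    a <- runif(3, rng[1], rng[2])
    amax <- max(a)
    lo <- a + 0.5 * params$shell_thickness_um
    hi <- ext - lo
    if (any(hi <= lo)) abort("nuclei do not fit inside the volume")
    c_new <- runif(3, lo, hi)
    ok <- TRUE
    if (nrow(centers) > 0) {
      d <- sqrt(rowSums(sweep(centers, 2, c_new, `-`)^2))
      ok <- all(d > apply(axes, 1, max) + amax + params$min_gap_um)
    }
    if (ok) {
      centers <- rbind(centers, c_new)
      axes <- rbind(axes, a)
    }
  }
  dimnames(centers) <- NULL
  dimnames(axes) <- NULL
  list(centers_um = centers, semiaxes_um = axes)
}

# physical voxel-centre coordinate grids for a (z,y,x) bounding-box window
window_grid <- function(idx, voxel_size) lapply(1:3, function(i) (idx[[i]] - 1) * voxel_size[i])

#' Generate a synthetic FISH scene with ground truth
#'
#' Renders the three channels on a voxel-centre grid: the DNA channel fills
#' each ellipsoid interior, the lamin channel is a thin shell centred on each
#' ellipsoid surface (rendered at its apparent width), and the probe channel
#' holds one PSF-shaped spot per `spots_spec` row at the exact sub-voxel
#' position whose normalized radial coordinate equals the requested `r` along
#' a random direction. Poisson shot noise plus Gaussian read noise are applied
#' unless `background` and `read_noise_sd` are both zero, in which case the
#' clean continuous rendering is returned. Deterministic for a fixed seed.
#'
#' @param params a [scene_params()] object.
#' @return A list with elements `stack` (an [image_stack()]), `truth` (a
#'   tibble of spots: `spot`, `nucleus`, true `z_um`, `y_um`, `x_um`,
#'   `r` and `shell_distance_um`), and `nuclei` (a tibble of centres and
#'   semi-axes in micrometres).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    geom <- place_nuclei(params)
    nz <- params$shape_zyx[1]; ny <- params$shape_zyx[2]; nx <- params$shape_zyx[3]
    vs <- params$voxel_size_zyx
    dna <- array(0, c(nz, ny, nx))
    lamin <- array(0, c(nz, ny, nx))
    probe <- array(0, c(nz, ny, nx))

    for (k in seq_len(params$n_nuclei)) {
      ctr <- geom$centers_um[k, ]; a <- geom$semiaxes_um[k, ]
      half <- a + params$shell_thickness_um
      idx <- lapply(1:3, function(i) {
        r <- max(1, floor((ctr[i] - half[i]) / vs[i])):
             min(params$shape_zyx[i], ceiling((ctr[i] + half[i]) / vs[i]) + 1)
        r
      })
      g <- window_grid(idx, vs)
      dz <- g[[1]] - ctr[1]; dy <- g[[2]] - ctr[2]; dx <- g[[3]] - ctr[3]
      # ellipsoidal coordinate rho (1 on the surface) and ray radius R(u)
      rho2 <- outer(outer((dz / a[1])^2, (dy / a[2])^2, `+`), (dx / a[3])^2, `+`)
      rho <- sqrt(rho2)
      d2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
      ray_r <- sqrt(d2) / pmax(rho, 1e-12)   # distance centre -> surface along ray
      dna[idx[[1]], idx[[2]], idx[[3]]] <-
        dna[idx[[1]], idx[[2]], idx[[3]]] + params$dna_amplitude * (rho <= 1)
      shell <- abs(1 - rho) * ray_r <= params$shell_thickness_um / 2
      lamin[idx[[1]], idx[[2]], idx[[3]]] <-
        lamin[idx[[1]], idx[[2]], idx[[3]]] + params$lamin_amplitude * shell
    }

    # Extended structures (interior, shell) are rendered at their apparent
    # size: the shell thickness models the observed lamin width, so the PSF
    # is applied only to point sources below.

    # spots: exact sub-voxel positions; rendered directly as the PSF response
    spec <- params$spots_spec
    truth <- tibble(spot = integer(), nucleus = integer(), z_um = numeric(),
                    y_um = numeric(), x_um = numeric(), r = numeric(),
                    shell_distance_um = numeric())
    if (nrow(spec) > 0) {
      for (s in seq_len(nrow(spec))) {
        k <- spec$nucleus[s]
        ctr <- geom$centers_um[k, ]; a <- geom$semiaxes_um[k, ]
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p <- ctr + (1 - spec$r[s]) * (a * u)
        sd_um <- ellipsoid_surface_distance(p, ctr, a)
        truth <- dplyr::bind_rows(truth, tibble(
          spot = s, nucleus = k, z_um = p[1], y_um = p[2], x_um = p[3],
          r = spec$r[s], shell_distance_um = sd_um))
        # render A * exp(-sum(d_i^2 / 2 sigma_i^2)) on a +/- 4 sigma window
        half <- 4 * params$psf_sigma_um
        idx <- lapply(1:3, function(i) {
          max(1, floor((p[i] - half[i]) / vs[i])):
          min(params$shape_zyx[i], ceiling((p[i] + half[i]) / vs[i]) + 1)
        })
        g <- window_grid(idx, vs)
        qz <- exp(-(g[[1]] - p[1])^2 / (2 * params$psf_sigma_um[1]^2))
        qy <- exp(-(g[[2]] - p[2])^2 / (2 * params$psf_sigma_um[2]^2))
        qx <- exp(-(g[[3]] - p[3])^2 / (2 * params$psf_sigma_um[3]^2))
        probe[idx[[1]], idx[[2]], idx[[3]]] <-
          probe[idx[[1]], idx[[2]], idx[[3]]] +
          spec$amplitude[s] * outer(outer(qz, qy), qx)
      }
    }

    stack <- image_stack(dna, probe, lamin, vs)
    if (params$background > 0 || params$read_noise_sd > 0) {
      stack <- apply_noise(stack, params$background, params$read_noise_sd,
                           seed = NULL)  # already inside the seeded block
    }
    nuclei <- tibble(
      nucleus = seq_len(params$n_nuclei),
      z_um = geom$centers_um[, 1], y_um = geom$centers_um[, 2],
      x_um = geom$centers_um[, 3],
      az_um = geom$semiaxes_um[, 1], ay_um = geom$semiaxes_um[, 2],
      ax_um = geom$semiaxes_um[, 3])
    list(stack = stack, truth = truth, nuclei = nuclei)
  })
}

#' Apply a shot-noise plus read-noise camera model
#'
#' Each channel becomes `Poisson(clean + background) + N(0, read_noise_sd)`,
#' clipped at zero and quantized to 16-bit unsigned integers.
#'
#' @param clean an [image_stack()] with finite counts.
#' @param background mean background counts added before the Poisson draw.
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return A noisy [image_stack()] with integer counts.
#' @export
apply_noise <- function(clean, background, read_noise_sd, seed = NULL) {
  stopifnot(inherits(clean, "image_stack"))
  if (background < 0) abort("`background` must be >= 0")
  if (read_noise_sd < 0) abort("`read_noise_sd` must be >= 0")
  if (!all(vapply(clean$channels, function(ch) all(is.finite(ch)), logical(1))))
    abort("clean counts must be finite")
  with_seed(seed, {
    noisy <- lapply(clean$channels, function(ch) {
      d <- dim(ch)
      v <- rpois(length(ch), lambda = as.vector(ch) + background)
      v <- v + rnorm(length(ch), 0, read_noise_sd)
      v <- pmin(pmax(round(v), 0), 65535)
      array(v, d)
    })
    image_stack(noisy$dna, noisy$probe, noisy$lamin, clean$voxel_size_zyx)
  })
}
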