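# shared scene builders: small, fast, deterministic

# two well-separated spherical nuclei in a 16 x 96 x 96 stack, noiseless;
# 1.8 um radius, the scale of a blastoderm nucleus
small_sphere_scene <- function(spots = data.frame(nucleus = c(1, 2),
                                                  r = c(0.5, 0.2),
                                                  amplitude = 400),
                               seed = 7, noise = FALSE) {
  scene_params(shape_zyx = c(16L, 96L, 96L),
               voxel_size_zyx = c(0.3, 0.1, 0.1),
               n_nuclei = 2L,
               nucleus_semiaxes_um = c(1.8, 1.8),
               spots_spec = spots,
               background = if (noise) 20 else 0,
               read_noise_sd = if (noise) 3 else 0,
               seed = seed)
}

probe_dog_params <- function(params) {
  dog_params(sigma_small_zyx = params$psf_sigma_um / params$voxel_size_zyx)
}

# truth index of the nearest ground-truth spot for each estimated position
match_truth <- function(est_um, truth) {
  tru <- as.matrix(truth[, c("z_um", "y_um", "x_um")])
  apply(as.matrix(est_um), 1, function(e) which.min(colSums((t(tru) - e)^2)))
}

# brute-force reflect-padding 3D median filter (independent oracle)
oracle_median_3d <- function(v, rz, ry, rx) {
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n - i + 1, i)
    }
    i
  }
  d <- dim(v)
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    w <- v[refl((z - rz):(z + rz), d[1]),
           refl((y - ry):(y + ry), d[2]),
           refl((x - rx):(x + rx), d[3])]
    out[z, y, x] <- median(w)
  }
  out
}

# exhaustive-scan Otsu oracle over the same equal-width histogram
oracle_otsu <- function(v, n_bins = 256L) {
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  best_k <- NA; best_v <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    bcv <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (bcv > best_v + 1e-12) { best_v <- bcv; best_k <- k }
  }
  edges[best_k + 1L]
}

# exhaustive all-pairs minimum distance oracle
oracle_min_distance <- function(spot, cloud) {
  best <- Inf
  for (i in seq_len(nrow(cloud))) {
    d <- sqrt(sum((spot - cloud[i, ])^2))
    if (d < best) best <- d
  }
  best
}

# 4-connected flood fill component count of a logical matrix
count_components_4conn <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    n <- n + 1L
    queue <- s
    lab[s] <- n
    H <- nrow(mask)
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      y <- (cur - 1L) %% H + 1L; x <- (cur - 1L) %/% H + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        yy <- y + d[1]; xx <- x + d[2]
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= ncol(mask)) {
          j <- (xx - 1L) * H + yy
          if (mask[j] && lab[j] == 0L) { lab[j] <- n; queue <- c(queue, j) }
        }
      }
    }
  }
  n
}
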