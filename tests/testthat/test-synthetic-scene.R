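test_that("scene generation is bit-identical for a fixed seed", {
  p <- small_sphere_scene(noise = TRUE)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth, b$truth)
})

test_that("a spot requested at r = 1 sits at the nucleus centre", {
  p <- small_sphere_scene(spots = data.frame(nucleus = 1, r = 1, amplitude = 300))
  sc <- generate_scene(p)
  expect_equal(unlist(sc$truth[1, c("z_um", "y_um", "x_um")], use.names = FALSE),
               unlist(sc$nuclei[1, c("z_um", "y_um", "x_um")], use.names = FALSE),
               tolerance = 1e-12)
  # for a sphere, the centre is one radius away from the surface
  expect_equal(sc$truth$shell_distance_um[1], sc$nuclei$az_um[1],
               tolerance = 1e-12)
})

test_that("noiseless rendering puts the brightest probe voxel at the spot", {
  p <- small_sphere_scene(spots = data.frame(nucleus = 2, r = 0.4, amplitude = 400))
  sc <- generate_scene(p)
  probe <- sc$stack$channels$probe
  am <- which(probe == max(probe), arr.ind = TRUE)[1, ]
  tru_vox <- unlist(sc$truth[1, c("z_um", "y_um", "x_um")]) /
    p$voxel_size_zyx + 1
  expect_true(all(abs(am - tru_vox) <= 1))
})

test_that("ground truth respects the radial-position and shell-distance invariants", {
  set.seed(11)
  for (seed in 1:5) {
    spots <- data.frame(nucleus = c(1, 1, 2), r = runif(3), amplitude = 300)
    sc <- generate_scene(small_sphere_scene(spots = spots, seed = seed))
    expect_true(all(sc$truth$r >= 0 & sc$truth$r <= 1))
    expect_true(all(sc$truth$shell_distance_um >= 0))
    # spherical nuclei: shell distance is exactly radius * r
    expect_equal(sc$truth$shell_distance_um,
                 sc$nuclei$az_um[sc$truth$nucleus] * sc$truth$r,
                 tolerance = 1e-9)
  }
})

test_that("noiseless lamin support lies within the shell thickness of a surface", {
  p <- small_sphere_scene()
  sc <- generate_scene(p)
  lam <- sc$stack$channels$lamin
  idx <- which(lam > 0, arr.ind = TRUE)
  pos <- sweep(idx - 1, 2, p$voxel_size_zyx, `*`)
  ctr <- as.matrix(sc$nuclei[, c("z_um", "y_um", "x_um")])
  dist_to_surface <- vapply(seq_len(nrow(pos)), function(i) {
    min(abs(sqrt(rowSums(sweep(ctr, 2, pos[i, ], `-`)^2)) - sc$nuclei$az_um))
  }, numeric(1))
  expect_true(all(dist_to_surface <= p$shell_thickness_um + 1e-9))
})

test_that("exact ellipsoid surface distance agrees with dense surface sampling", {
  set.seed(42)
  a <- c(1.1, 1.7, 2.3)
  th <- runif(40000, 0, pi); ph <- runif(40000, 0, 2 * pi)
  surf <- cbind(a[1] * cos(th), a[2] * sin(th) * cos(ph), a[3] * sin(th) * sin(ph))
  for (i in 1:10) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- (runif(1, 0, 0.95) * a) * u
    exact <- ellipsoid_surface_distance(p, c(0, 0, 0), a)
    sampled <- min(sqrt(rowSums(sweep(surf, 2, p, `-`)^2)))
    expect_lt(abs(exact - sampled), 0.05)
    expect_lte(exact, sampled + 1e-12)  # exact distance is the infimum
  }
})

test_that("spot specs referencing missing nuclei and bad radii are rejected", {
  expect_error(small_sphere_scene(spots = data.frame(nucleus = 3, r = 0.5,
                                                     amplitude = 1)),
               "existing nucleus")
  expect_error(small_sphere_scene(spots = data.frame(nucleus = 1, r = 1.2,
                                                     amplitude = 1)),
               "\\[0, 1\\]")
})

test_that("unplaceable nucleus configurations fail after bounded re-draws", {
  expect_error(
    generate_scene(scene_params(shape_zyx = c(12L, 40L, 40L),
                                n_nuclei = 30L,
                                nucleus_semiaxes_um = c(1.0, 1.2),
                                max_placement_tries = 200L,
                                background = 0, read_noise_sd = 0)),
    "non-overlapping|fit inside")
})

test_that("camera noise model is seeded, unbiased and degenerate-safe", {
  zeros <- array(0, c(4, 5, 6))
  clean0 <- image_stack(zeros, zeros, zeros, c(0.3, 0.1, 0.1))
  out0 <- apply_noise(clean0, background = 0, read_noise_sd = 0, seed = 1)
  expect_true(all(unlist(out0$channels) == 0))

  v <- 400
  const <- array(v, c(20, 20, 20))
  clean <- image_stack(const, const, const, c(0.3, 0.1, 0.1))
  noisy <- apply_noise(clean, background = 50, read_noise_sd = 3, seed = 2)
  n <- length(const)
  expect_lt(abs(mean(noisy$channels$dna) - (v + 50)), 3 * sqrt(v / n) + 1)
  expect_true(all(unlist(noisy$channels) == round(unlist(noisy$channels))))
  expect_true(min(unlist(noisy$channels)) >= 0)

  again <- apply_noise(clean, background = 50, read_noise_sd = 3, seed = 2)
  expect_identical(noisy$channels, again$channels)

  expect_error(apply_noise(clean, background = -1, read_noise_sd = 0), ">= 0")
  expect_error(apply_noise(clean, background = 0, read_noise_sd = -2), ">= 0")
})

test_that("stacks round-trip through TIFF plus sidecar", {
  p <- small_sphere_scene(noise = TRUE)
  sc <- generate_scene(p)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(sc$stack, path)
  back <- read_stack(path)
  expect_equal(back$channels$dna, sc$stack$channels$dna, tolerance = 1e-8)
  expect_equal(back$channels$probe, sc$stack$channels$probe, tolerance = 1e-8)
  expect_equal(back$voxel_size_zyx, sc$stack$voxel_size_zyx)
})
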