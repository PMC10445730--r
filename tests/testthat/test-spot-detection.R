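render_blob <- function(shape, center, sigma, amplitude = 100) {
  g <- lapply(1:3, function(i) {
    exp(-((seq_len(shape[i]) - center[i])^2) / (2 * sigma[i]^2))
  })
  amplitude * outer(outer(g[[1]], g[[2]]), g[[3]])
}

test_that("DoG detection finds isolated blobs and nothing in blank volumes", {
  dp <- dog_params(sigma_small_zyx = c(1.5, 1.5, 1.5), response_threshold = 1)
  blank <- array(0, c(12, 24, 24))
  expect_equal(nrow(dog_detect(blank, dp)), 0)

  one <- render_blob(c(12, 24, 24), c(6.3, 11.6, 15.2), c(2, 2, 2))
  cand <- dog_detect(one, dp)
  expect_equal(nrow(cand), 1)
  expect_true(all(abs(unlist(cand[1, c("z", "y", "x")]) - c(6.3, 11.6, 15.2)) <= 1))

  two <- render_blob(c(12, 40, 24), c(6, 10, 12), c(2, 2, 2)) +
    render_blob(c(12, 40, 24), c(6, 30, 12), c(2, 2, 2))   # 20 px = 10 sigma apart
  expect_equal(nrow(dog_detect(two, dp)), 2)
})

test_that("detection is deterministic and monotone in the threshold", {
  set.seed(8)
  v <- array(rpois(10 * 20 * 20, 10), c(10, 20, 20)) +
    render_blob(c(10, 20, 20), c(5, 10, 10), c(1.5, 1.5, 1.5), 200)
  dp <- dog_params(sigma_small_zyx = c(1.2, 1.2, 1.2))
  expect_identical(dog_detect(v, dp), dog_detect(v, dp))
  resp_thresholds <- c(0.5, 2, 10, 50)
  ns <- vapply(resp_thresholds, function(t) {
    nrow(dog_detect(v, dog_params(sigma_small_zyx = c(1.2, 1.2, 1.2),
                                  response_threshold = t)))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("centre-of-mass refinement matches hand-computed weighted means", {
  # symmetric blob centred on a voxel
  v <- render_blob(c(9, 9, 9), c(5, 5, 5), c(1.5, 1.5, 1.5))
  expect_equal(as.numeric(refine_com(v, c(5, 5, 5), c(3, 3, 3))), c(5, 5, 5),
               tolerance = 1e-12)

  # 1D-asymmetric toy volume: background 1 everywhere, one bright pair
  v <- array(1, c(1, 1, 5))
  v[1, 1, 2] <- 5; v[1, 1, 3] <- 9
  # window min (=1) is subtracted: weights (0, 4, 8, 0, 0) at x = 1..5
  rc <- refine_com(v, c(1, 1, 3), c(1, 1, 5))
  expect_equal(rc[3], (4 * 2 + 8 * 3) / 12, tolerance = 1e-12)

  # zero-mass window returns the input, flagged
  z <- array(0, c(5, 5, 5))
  rc <- refine_com(z, c(3, 3, 3), c(3, 3, 3))
  expect_equal(as.numeric(rc), c(3, 3, 3))
  expect_true(attr(rc, "degenerate"))

  expect_error(refine_com(z, c(9, 3, 3), c(3, 3, 3)), "inside")
})

test_that("physical coordinates are the 0-based refined voxel times the voxel size", {
  v <- array(0, c(16, 32, 40))
  v[11, 21, 31] <- 100   # 1-based voxel (11, 21, 31) = 0-based (10, 20, 30)
  st <- image_stack(v, v, v, c(0.3, 0.1, 0.1))
  sp <- localize_spots(st, "probe",
                       params = dog_params(sigma_small_zyx = c(1, 1, 1),
                                           response_threshold = 0.01))
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$z_um, sp$y_um, sp$x_um), c(3.0, 2.0, 3.0), tolerance = 1e-9)
})

test_that("spots are assigned to nuclei by detection voxel; outsiders are NA", {
  p <- small_sphere_scene(noise = TRUE)
  sc <- generate_scene(p)
  seg <- segment_nuclei(sc$stack)
  # add a bright artificial spot at the voxel farthest from both nuclei
  d <- dim(seg$label_volume)
  grid <- expand.grid(z = seq(2, d[1] - 1, by = 2), y = seq(2, d[2] - 1, by = 4),
                      x = seq(2, d[3] - 1, by = 4))
  pos_um <- sweep(as.matrix(grid) - 1, 2, p$voxel_size_zyx[c(1, 2, 3)], `*`)
  ctr <- as.matrix(sc$nuclei[, c("z_um", "y_um", "x_um")])
  mind <- apply(pos_um, 1, function(q) min(sqrt(rowSums(sweep(ctr, 2, q, `-`)^2))))
  far <- as.integer(grid[which.max(mind), ])
  sc$stack$channels$probe[far[1], far[2], far[3]] <- 800
  spots <- localize_spots(sc$stack, "probe", seg, probe_dog_params(p))
  inside <- spots[!is.na(spots$nucleus), ]
  outside <- spots[is.na(spots$nucleus), ]
  expect_equal(nrow(inside), 2)
  expect_gte(nrow(outside), 1)
  # assigned nuclei match the ground truth (labels matched by position)
  m <- match_truth(inside[, c("z_um", "y_um", "x_um")], sc$truth)
  expect_equal(length(unique(m)), 2)
})

test_that("noiseless localization is sub-voxel accurate", {
  spots_spec <- data.frame(nucleus = c(1, 2), r = c(0.6, 0.35), amplitude = 400)
  p <- small_sphere_scene(spots = spots_spec)
  sc <- generate_scene(p)
  seg <- segment_nuclei(sc$stack)
  spots <- localize_spots(sc$stack, "probe", seg, probe_dog_params(p))
  expect_equal(nrow(spots), 2)
  m <- match_truth(spots[, c("z_um", "y_um", "x_um")], sc$truth)
  err_vox <- sweep(as.matrix(spots[, c("z_um", "y_um", "x_um")]) -
                     as.matrix(sc$truth[m, c("z_um", "y_um", "x_um")]),
                   2, p$voxel_size_zyx, `/`)
  rms <- sqrt(mean(rowSums(err_vox^2)))
  expect_lt(rms, 0.5)
})

test_that("the lamin point cloud densely samples the shell surface", {
  p <- small_sphere_scene()
  sc <- generate_scene(p)
  seg <- segment_nuclei(sc$stack)
  cloud <- lamin_point_cloud(sc$stack, seg)
  expect_gt(nrow(cloud), 500)
  ctr <- as.matrix(sc$nuclei[, c("z_um", "y_um", "x_um")])
  off <- vapply(seq_len(nrow(cloud)), function(i) {
    pt <- as.numeric(cloud[i, c("z_um", "y_um", "x_um")])
    min(abs(sqrt(rowSums(sweep(ctr, 2, pt, `-`)^2)) - sc$nuclei$az_um))
  }, numeric(1))
  expect_gte(mean(off <= p$shell_thickness_um), 0.95)

  # lowering the response threshold never shrinks the cloud
  n_strict <- nrow(lamin_point_cloud(sc$stack, seg,
    dog_params(candidate_mode = "dense", response_threshold = 50)))
  n_perm <- nrow(lamin_point_cloud(sc$stack, seg,
    dog_params(candidate_mode = "dense", response_threshold = 5)))
  expect_gte(n_perm, n_strict)
})

test_that("a blank lamin channel excludes every nucleus with a warning", {
  p <- small_sphere_scene()
  sc <- generate_scene(p)
  seg <- segment_nuclei(sc$stack)
  sc$stack$channels$lamin[] <- 0
  expect_warning(cloud <- lamin_point_cloud(sc$stack, seg,
    dog_params(candidate_mode = "dense", response_threshold = 1)),
    "excluded")
  expect_equal(nrow(cloud), 0)
  expect_setequal(attr(cloud, "excluded_nuclei"), 1:2)
})
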