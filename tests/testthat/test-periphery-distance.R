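test_that("min_distance_3d handles analytic geometries", {
  set.seed(10)
  th <- runif(200, 0, pi); ph <- runif(200, 0, 2 * pi)
  sphere <- 2 * cbind(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  expect_equal(min_distance_3d(c(0, 0, 0), sphere), 2, tolerance = 1e-12)
  expect_equal(min_distance_3d(sphere[5, ], sphere), 0, tolerance = 1e-12)
  expect_error(min_distance_3d(c(0, 0, 0), sphere[0, , drop = FALSE]), "empty")
})

test_that("min_distance_3d equals the exhaustive all-pairs oracle", {
  set.seed(11)
  for (i in 1:10) {
    cloud <- matrix(rnorm(100 * 3, sd = 3), ncol = 3)
    spots <- matrix(rnorm(10 * 3, sd = 3), ncol = 3)
    for (j in 1:10) {
      expect_equal(min_distance_3d(spots[j, ], cloud),
                   oracle_min_distance(spots[j, ], cloud), tolerance = 1e-12)
    }
  }
})

test_that("min_distance_3d is translation invariant and monotone in the cloud", {
  set.seed(12)
  cloud <- matrix(rnorm(50 * 3), ncol = 3)
  spot <- rnorm(3)
  shift <- c(5, -3, 11)
  expect_equal(min_distance_3d(spot, cloud),
               min_distance_3d(spot + shift, sweep(cloud, 2, shift, `+`)),
               tolerance = 1e-9)
  d0 <- min_distance_3d(spot, cloud)
  expect_lte(min_distance_3d(spot, rbind(cloud, rnorm(3))), d0)
})

test_that("maximum projection reduces z correctly and ignores z order", {
  p <- small_sphere_scene(noise = TRUE)
  sc <- generate_scene(p)
  proj <- max_project_composite(sc$stack)
  expect_equal(dim(proj$channels$dna), c(96, 96))
  expect_equal(dim(proj$composite), c(96, 96, 3))
  perm <- sc$stack
  perm$channels$dna <- perm$channels$dna[sample(16), , ]
  expect_equal(max_project_composite(perm)$channels$dna, proj$channels$dna)

  one <- image_stack(array(1:12, c(1, 3, 4)), array(0, c(1, 3, 4)),
                     array(0, c(1, 3, 4)), c(0.3, 0.1, 0.1))
  expect_equal(max_project_composite(one)$channels$dna, matrix(1:12, 3, 4))
})

test_that("spline ROIs rasterize to the expected disk", {
  roi <- roi_from_ellipse(1, c(40, 40), c(20, 20), n_points = 8)
  mask <- rasterize_spline(roi, c(80, 80))
  expect_lt(abs(sum(mask) - pi * 20^2) / (pi * 20^2), 0.05)
  expect_equal(count_components_4conn(mask), 1)
  expect_true(mask[40, 40])

  # a small square around one pixel keeps that pixel foreground
  sq <- spline_roi(2, rbind(c(9, 10), c(10, 11), c(11, 10), c(10, 9),
                            c(9.3, 9.3)))
  m2 <- rasterize_spline(sq, c(20, 20))
  expect_true(m2[10, 10])

  # figure-eight control points self-intersect
  fig8 <- spline_roi(3, rbind(c(10, 10), c(20, 20), c(10, 30), c(20, 40),
                              c(10, 50), c(22, 30)))
  expect_error(rasterize_spline(fig8, c(40, 60)), "self-intersect")

  expect_error(spline_roi(4, rbind(c(1, 1), c(2, 2), c(3, 3))), ">= 5")
})

test_that("the normalized distance map peaks at exactly 1 in the disk centre", {
  roi <- roi_from_ellipse(1, c(35, 35), c(20, 20), n_points = 10)
  mask <- rasterize_spline(roi, c(70, 70))
  nd <- normalized_distance_map(mask, 1)
  expect_equal(max(nd$map), 1)
  expect_true(all(nd$map >= 0 & nd$map <= 1))
  expect_equal(nd$map[35, 35], 1)
  # boundary pixels are within one pixel-equivalent of zero
  boundary <- mask &
    !(EBImage::erode(EBImage::Image(mask * 1),
                     EBImage::makeBrush(3, "box")) > 0)
  expect_lte(max(nd$map[boundary]), 1.5 / nd$max_raw)

  # translation invariance
  roi2 <- roi_from_ellipse(1, c(30, 32), c(20, 20), n_points = 10)
  nd2 <- normalized_distance_map(rasterize_spline(roi2, c(70, 70)), 1)
  expect_equal(sort(nd$map[nd$map > 0]), sort(nd2$map[nd2$map > 0]),
               tolerance = 1e-9)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  nd1 <- normalized_distance_map(single)
  expect_equal(as.numeric(nd1$map[3, 3]), 1)
  expect_error(normalized_distance_map(matrix(FALSE, 4, 4)), "empty")
})

test_that("normalized positions recover known radial placements on a disk", {
  roi <- roi_from_ellipse(1, c(60, 60), c(20, 20), n_points = 10)
  nd <- normalized_distance_map(rasterize_spline(roi, c(120, 120)), 1)
  expect_equal(normalized_position(nd$argmax, nd), 1)
  # points on a ring of true normalized position r
  angles <- seq(0, 2 * pi, length.out = 13)[-13]
  for (r in c(0.2, 0.5, 0.8)) {
    vals <- vapply(angles, function(th) {
      normalized_position(c(60 + (1 - r) * 20 * sin(th),
                            60 + (1 - r) * 20 * cos(th)), nd)
    }, numeric(1))
    expect_lt(mean(abs(vals - r)), 0.05)
  }
  # near-contour points are within one pixel-equivalent of zero
  edge <- normalized_position(c(60, 60 + 19.4), nd)
  expect_lte(edge, 1.5 / nd$max_raw)
  expect_error(normalized_position(c(2, 2), nd), "nucleus 1")
})

test_that("pdf histogram heights always sum to one", {
  set.seed(13)
  for (n in c(1, 7, 500)) {
    h <- pdf_histogram(runif(n), bins = 20)
    expect_lt(abs(sum(h$height) - 1), 1e-12)
    expect_true(all(h$height >= 0))
    expect_equal(attr(h, "n"), n)
  }
  one_bin <- pdf_histogram(rep(0.35, 50), bin_edges = c(0, 0.3, 0.4, 1))
  expect_equal(one_bin$height, c(0, 1, 0))
  expect_error(pdf_histogram(numeric(0)), "nonempty")
  expect_error(pdf_histogram(c(0.5, 1.7), bins = 20), "cover")
})

test_that("uniform samples fill pdf bins evenly within the binomial bound", {
  set.seed(14)
  h <- pdf_histogram(runif(500), bins = 20)
  bound <- 5 * sqrt(0.05 * 0.95 / 500)
  expect_true(all(abs(h$height - 0.05) <= bound))
})

test_that("condition comparison reports medians and their difference", {
  a <- tibble::tibble(normalized_position = c(0.2, 0.3, 0.4))
  expect_equal(compare_conditions(a, a)$diff_of_medians, 0)

  x <- tibble::tibble(normalized_position = 1.0)
  y <- tibble::tibble(normalized_position = 2.0)
  cmp <- compare_conditions(x, y, bin_edges = c(0, 1, 2, 3))
  expect_equal(cmp$diff_of_medians, -1.0)

  set.seed(15)
  tethered <- tibble::tibble(distance_3d_um = abs(rnorm(100, 0.2, 0.05)))
  released <- tibble::tibble(distance_3d_um = abs(rnorm(100, 0.8, 0.2)))
  cmp <- compare_conditions(tethered, released, value_col = "distance_3d_um",
                            labels = c("tethered", "released"))
  expect_lt(cmp$summary$median[1], cmp$summary$median[2])
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$n, c(100, 100))
  gl <- glance(cmp)
  expect_equal(gl$diff_of_medians, cmp$diff_of_medians)
  expect_error(compare_conditions(x, tibble::tibble(other = 1)), "readout")

  plt <- ggplot2::autoplot(cmp)
  expect_s3_class(plt, "ggplot")
})
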