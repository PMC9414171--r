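test_that("exact circles are fitted exactly", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  fit <- fit_circle(cbind(10 + 5 * cos(th), 10 + 5 * sin(th)))
  expect_equal(fit$center_px, c(10, 10), tolerance = 1e-9)
  expect_equal(fit$radius_px, 5, tolerance = 1e-9)
  expect_lt(fit$fit_residual, 1e-9)
})

test_that("three points yield their circumcircle", {
  set.seed(42)
  for (i in 1:10) {
    pts <- matrix(runif(6, 0, 20), 3, 2)
    oracle <- circumcircle(pts[1, ], pts[2, ], pts[3, ])
    # skip near-degenerate triangles the oracle itself can't resolve
    if (!all(is.finite(oracle$center)) || oracle$radius > 1e3) next
    fit <- fit_circle(pts)
    expect_equal(fit$center_px, oracle$center, tolerance = 1e-6)
    expect_equal(fit$radius_px, oracle$radius, tolerance = 1e-6)
  }
})

test_that("collinear or insufficient points are rejected", {
  expect_error(fit_circle(cbind(1:5, 2 * (1:5) + 1)), "collinear")
  expect_error(fit_circle(cbind(1:2, 1:2)), "3 points")
})

test_that("the algebraic fit agrees with a geometric grid search", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    cx <- runif(1, 20, 40); cy <- runif(1, 20, 40); r <- runif(1, 5, 15)
    # jittered full-circle coverage (partial arcs bias any algebraic fit)
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + runif(n, -0.3, 0.3)
    pts <- cbind(cx + r * cos(th), cy + r * sin(th)) +
      matrix(rnorm(2 * n, 0, 0.1), n, 2)
    fit <- fit_circle(pts)
    oracle <- grid_circle_fit(pts)
    expect_lt(sqrt(sum((fit$center_px - oracle$center)^2)), 0.1)
    expect_lt(abs(fit$radius_px - oracle$radius), 0.1)
  }
})

test_that("a blank image segments to an empty table", {
  img <- gray_image(matrix(60, 100, 100))
  expect_equal(nrow(segment_cells(img)), 0)
})

test_that("hole filling collapses a holey oocyte to one contour", {
  sc <- render_scene(one_oocyte_spec(n_holes = 5, noise_sd = 0, seed = 11))
  filled <- segment_cells(sc$image, fill_holes = TRUE)
  unfilled <- segment_cells(sc$image, fill_holes = FALSE,
                            min_area_px2 = 20)
  expect_equal(nrow(filled), 1)
  expect_gt(nrow(unfilled), 1)
  expect_true(any(unfilled$is_hole))
})

test_that("segmentation recovers oocyte geometry within tight tolerance", {
  for (seed in 1:8) {
    sc <- render_scene(random_scene_spec(n_oocytes = 3, seed = seed))
    det <- classify_cells(segment_cells(sc$image))
    tr <- sc$truth$oocytes
    expect_length(det$oocytes, nrow(tr))
    cent <- t(vapply(det$oocytes, function(o) {
      c(o$contour$cx_px, o$contour$cy_px, o$contour$r_px)
    }, numeric(3)))
    for (i in seq_len(nrow(tr))) {
      d <- sqrt((cent[, 1] - tr$cx_px[i])^2 + (cent[, 2] - tr$cy_px[i])^2)
      j <- which.min(d)
      expect_lt(d[j], 2)
      expect_lt(abs(cent[j, 3] - tr$r_px[i]) / tr$r_px[i], 0.03)
    }
  }
})

test_that("the attachment rule follows d <= R + r + s", {
  mk <- function(d) {
    data.frame(cx_px = c(100, 100 + d), cy_px = 100, r_px = c(40, 10),
               area_px2 = c(5027, 314), fit_residual = 0,
               is_hole = FALSE)
  }
  # R=40, r=10, s=8: boundary at 58 (tol absorbs the equality)
  near <- classify_cells(mk(57), pixel_size_um = 1, s_um = 8, tol_um = 0)
  expect_true(near$oocytes[[1]]$cumulus$attached[1])
  far <- classify_cells(mk(100), pixel_size_um = 1, s_um = 8, tol_um = 0)
  expect_equal(nrow(far$oocytes[[1]]$cumulus), 0)
  expect_equal(nrow(far$dispersed), 1)
})

test_that("classification is permutation-invariant and matches a pairwise oracle", {
  for (seed in 1:5) {
    sc <- render_scene(random_scene_spec(n_oocytes = 3, n_dispersed = 3,
                                         seed = seed))
    det <- segment_cells(sc$image)
    cl1 <- classify_cells(det)
    cl2 <- classify_cells(det[sample(nrow(det)), ])
    n_att <- function(cl) sum(vapply(cl$oocytes,
                                     function(o) nrow(o$cumulus), 1L))
    expect_equal(n_att(cl1), n_att(cl2))
    expect_equal(nrow(cl1$dispersed), nrow(cl2$dispersed))
    # exhaustive pairwise oracle on the same contours
    oo <- det[det$r_px >= 25, ]; cu <- det[det$r_px < 25, ]
    oracle_attached <- sum(vapply(seq_len(nrow(cu)), function(j) {
      any(sqrt((cu$cx_px[j] - oo$cx_px)^2 + (cu$cy_px[j] - oo$cy_px)^2) <=
            oo$r_px + cu$r_px[j] + 8 + 1)
    }, logical(1)))
    expect_equal(n_att(cl1), oracle_attached)
  }
})

test_that("cumulus-sized blobs are never promoted to oocytes", {
  for (seed in 1:10) {
    sc <- render_scene(cumulus_only_spec(seed = seed))
    det <- classify_cells(segment_cells(sc$image))
    expect_length(det$oocytes, 0)
  }
})

test_that("combined mass follows the sphere-volume formula", {
  expect_equal(combined_mass(0, numeric(), 1000)$combined_mass_kg, 0)
  m <- combined_mass(40, numeric(), 1000)$combined_mass_kg
  expect_equal(m, (4 / 3) * pi * (40e-6)^3 * 1000, tolerance = 1e-12)
  expect_equal(m, 2.68e-10, tolerance = 0.002)
  # cubic scaling under radius doubling
  m1 <- combined_mass(30, c(5, 8), 1050)$combined_mass_kg
  m2 <- combined_mass(60, c(10, 16), 1050)$combined_mass_kg
  expect_equal(m2 / m1, 8, tolerance = 1e-12)
  # one cumulus cell recovers the single-radius form
  expect_equal(combined_mass(40, 10, 1050)$combined_mass_kg,
               (4 / 3) * pi * 1050 * ((40e-6)^3 + (10e-6)^3),
               tolerance = 1e-12)
  expect_error(combined_mass(-1, numeric(), 1000), "non-negative")
})
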