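test_that("an empty noiseless scene is uniform background with empty truth", {
  sp <- scene_spec(80, 60, background_level = 60, noise_sd = 0)
  sc <- render_scene(sp)
  expect_true(all(sc$image == 60))
  expect_equal(nrow(sc$truth$oocytes), 0)
  expect_equal(nrow(sc$truth$cumulus), 0)
  expect_null(sc$truth$pipette)
})

test_that("rendering is bit-deterministic given the seed", {
  sp <- random_scene_spec(n_oocytes = 2, n_dispersed = 3, seed = 5)
  a <- render_scene(sp)$image
  b <- render_scene(sp)$image
  expect_identical(as.numeric(a), as.numeric(b))
  sp2 <- sp; sp2$noise_seed <- sp$noise_seed + 1L
  expect_false(identical(as.numeric(a),
                         as.numeric(render_scene(sp2)$image)))
})

test_that("ground truth px coordinates are um divided by the pixel size", {
  ps <- 0.5
  oo <- lapply(c(60, 100, 140), function(x) {
    oocyte_spec(center_um = c(x, 70), radius_um = 20)
  })
  sp <- scene_spec(400, 280, pixel_size_um = ps, oocytes = oo)
  tr <- render_scene(sp)$truth
  expect_equal(nrow(tr$oocytes), 3)
  expect_equal(tr$oocytes$cx_px, tr$oocytes$cx_um / ps)
  expect_equal(tr$oocytes$cy_px, tr$oocytes$cy_um / ps)
  expect_equal(tr$oocytes$r_px, tr$oocytes$r_um / ps)
})

test_that("objects outside the frame raise an error naming the object", {
  sp <- scene_spec(100, 100, oocytes = list(
    oocyte_spec(center_um = c(95, 50), radius_um = 20)))
  expect_error(render_scene(sp), "oocyte 1")
  sp2 <- scene_spec(100, 100,
                    pipette = pipette_spec(tip_um = c(150, 50)))
  expect_error(render_scene(sp2), "pipette")
})

test_that("rasterized circles centroid back to their spec centres within 0.5 px", {
  for (seed in 1:5) {
    set.seed(seed)
    cx <- runif(1, 40, 80); cy <- runif(1, 40, 80); r <- runif(1, 10, 25)
    sp <- scene_spec(120, 120, noise_sd = 0, oocytes = list(
      oocyte_spec(center_um = c(cx, cy), radius_um = r,
                  zona_thickness_um = 0)))
    img <- render_scene(sp)$image
    mask <- img > 110
    idx <- which(mask, arr.ind = TRUE)
    cent <- c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))
    expect_lt(max(abs(cent - c(cx, cy))), 0.5)
  }
})

test_that("oocyte interior stays separable from background at default noise", {
  sp <- one_oocyte_spec(noise_sd = 5, seed = 3)
  sc <- render_scene(sp)
  img <- as.matrix(sc$image)
  h <- nrow(img); w <- ncol(img)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  d <- sqrt((xs - 80)^2 + (ys - 80)^2)
  inner <- mean(img[d < 30])
  bg <- mean(img[d > 70])
  expect_gt(inner, bg + 3 * 5)
})

test_that("a zero-shift pair renders identical noiseless frames", {
  sp <- random_scene_spec(n_oocytes = 2, noise_sd = 0, seed = 9)
  pr <- render_shifted_pair(sp, c(0, 0), 0)
  expect_identical(as.numeric(pr$frame_a), as.numeric(pr$frame_b))
})

test_that("a pure translation shifts content exactly over the overlap", {
  sp <- random_scene_spec(n_oocytes = 2, noise_sd = 0, seed = 9)
  pr <- render_shifted_pair(sp, c(100, 0), 0)
  a <- as.matrix(pr$frame_a); b <- as.matrix(pr$frame_b)
  w <- ncol(a)
  expect_equal(b[, 101:w], a[, 1:(w - 100)], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pr$truth$shift_applied_px, c(100, 0))
})

test_that("a rotated stage step obeys dy/dx = tan(angle)", {
  sp <- random_scene_spec(n_oocytes = 2, noise_sd = 0, seed = 9)
  pr <- render_shifted_pair(sp, c(100, 0), 2)
  t <- pr$truth$shift_applied_px
  expect_equal(t[2] / t[1], tan(2 * pi / 180), tolerance = 1e-12)
})

test_that("insufficient overlap is rejected", {
  sp <- random_scene_spec(n_oocytes = 2, noise_sd = 0, seed = 9)
  expect_error(render_shifted_pair(sp, c(0.9 * sp$width_px, 0.9 * sp$height_px), 0),
               "overlap")
})

test_that("ground truth survives a JSON round trip", {
  sc <- render_scene(random_scene_spec(n_oocytes = 2, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sc$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$oocytes$cx_px, sc$truth$oocytes$cx_px)
  expect_equal(back$cumulus$attached, sc$truth$cumulus$attached)
})

test_that("images round-trip through PNG at 8-bit precision", {
  sc <- render_scene(one_oocyte_spec(noise_sd = 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".png")
  write_gray_image(sc$image, path)
  back <- read_gray_image(path)
  expect_equal(dim(back), dim(sc$image))
  expect_lt(max(abs(as.numeric(back) - as.numeric(sc$image))), 0.51)
})
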