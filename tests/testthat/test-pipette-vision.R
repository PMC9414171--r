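test_that("the tip is the midpoint of the rightmost wall-edge points", {
  sc <- render_scene(pipette_scene(tip = c(160, 100), noise_sd = 0))
  fix <- detect_tip(sc$image)
  expect_equal(fix$tip_px[1], (fix$point_A[1] + fix$point_B[1]) / 2)
  expect_equal(fix$tip_px[2], (fix$point_A[2] + fix$point_B[2]) / 2)
  expect_lte(fix$point_A[2], fix$point_B[2])
  expect_lt(sqrt(sum((fix$tip_px - c(160, 100))^2)), 2)
})

test_that("blank and noise-only images raise a no-pipette error", {
  expect_error(detect_tip(gray_image(matrix(60, 200, 230))), "no pipette")
  set.seed(1)
  noisy <- gray_image(matrix(pmax(0, pmin(255, 60 + rnorm(200 * 230, 0, 8))),
                             200, 230))
  expect_error(detect_tip(noisy), "no pipette")
})

test_that("tip localization stays within 2 px over seeded scenes", {
  errs <- vapply(1:25, function(s) {
    set.seed(s)
    tx <- runif(1, 120, 200); ty <- runif(1, 75, 125)
    sc <- render_scene(pipette_scene(tip = c(tx, ty), noise_sd = 3, seed = s),
                       .clip = TRUE)
    fix <- detect_tip(sc$image)
    sqrt(sum((fix$tip_px - c(tx, ty))^2))
  }, 0)
  expect_lt(max(errs), 2)
})

test_that("detect_tip is translation-equivariant and idempotent", {
  sc <- render_scene(pipette_scene(tip = c(150, 95), noise_sd = 2, seed = 8),
                     .clip = TRUE)
  f0 <- detect_tip(sc$image)
  f0b <- detect_tip(sc$image)
  expect_identical(f0$tip_px, f0b$tip_px)
  for (dd in list(c(12, 0), c(0, 9), c(-8, 7))) {
    shifted <- translate_image(sc$image, dd[1], dd[2], fill = 60)
    f1 <- detect_tip(shifted)
    expect_lt(max(abs(f1$tip_px - (f0$tip_px + dd))), 1)
  }
})

test_that("noise does not improve tip accuracy on average", {
  err_at <- function(noise_sd) {
    mean(vapply(1:15, function(s) {
      set.seed(s + 100)
      tx <- runif(1, 130, 190); ty <- runif(1, 80, 120)
      sc <- render_scene(pipette_scene(tip = c(tx, ty),
                                       noise_sd = noise_sd, seed = s),
                         .clip = TRUE)
      sqrt(sum((detect_tip(sc$image)$tip_px - c(tx, ty))^2))
    }, 0))
  }
  expect_lte(err_at(0), err_at(10) + 1e-9)
})

test_that("contact is declared at the first frame exceeding the threshold", {
  mk_seq <- function(shift_from, dx) {
    lapply(1:8, function(k) {
      d <- if (k >= shift_from) dx else 0
      render_scene(pipette_scene(tip = c(150 + d, 100), noise_sd = 2,
                                 seed = 50 + k), .clip = TRUE)$image
    })
  }
  ev <- detect_contact(mk_seq(5, 6), threshold_px = 3)
  expect_true(ev$contact)
  expect_equal(ev$frame_index, 5)
  expect_gt(ev$displacement_px, 3)

  still <- detect_contact(mk_seq(99, 0), threshold_px = 3)
  expect_false(still$contact)
  expect_true(is.na(still$frame_index))
})

test_that("a repeated identical frame never signals contact", {
  img <- render_scene(pipette_scene(noise_sd = 0))$image
  ev <- detect_contact(rep(list(img), 10), threshold_px = 3)
  expect_false(ev$contact)
  expect_equal(ev$displacement_px, 0)
})

test_that("a lost tip names the offending frame", {
  good <- render_scene(pipette_scene(noise_sd = 0))$image
  blank <- gray_image(matrix(60, 200, 230))
  expect_error(detect_contact(list(good, good, blank), threshold_px = 3),
               "frame 3")
  expect_error(detect_contact(list(good), threshold_px = 3), "2 frames")
})
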