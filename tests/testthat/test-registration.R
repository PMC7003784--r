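tpl60 <- function(scale = 100) landmark_set(landmark_template() * scale)

test_that("mirroring is an involution on image and landmarks", {
  set.seed(21)
  img <- rgb_image(array(round(runif(40 * 50 * 3, 0, 255)), c(40, 50, 3)))
  lm <- landmark_set(cbind(runif(60, 0, 49), runif(60, 0, 39)))
  m1 <- mirror_right_side(img, lm)
  m2 <- mirror_right_side(m1$image, m1$landmarks)
  expect_identical(m2$image$pixels, img$pixels)
  expect_equal(m2$landmarks$points, lm$points, ignore_attr = TRUE)
})

test_that("mirroring flips x coordinates and relocates content", {
  p <- matrix(c(0, 5), 60, 2, byrow = TRUE)
  img <- rgb_image(array(0, c(10, 100, 3)))
  m <- mirror_right_side(img, landmark_set(p))
  expect_equal(unname(m$landmarks$points[1, 1]), 99)
  # a bright patch on the left cheek moves to the right
  px <- array(10, c(20, 30, 3)); px[8:12, 3:7, ] <- 200
  mm <- mirror_right_side(rgb_image(px), landmark_set(p[, 1:2] * 0 + 1))
  bright <- which(mm$image$pixels[, , 1] == 200, arr.ind = TRUE)
  expect_equal(sort(unique(bright[, 2])), 24:28)  # x 2..6 -> 29-1-x
})

test_that("the reference shape is the per-landmark mean, order-invariant", {
  a <- tpl60(); b <- landmark_set(a$points + 10)
  ref <- estimate_reference_shape(list(a, b), 128, 128)
  expect_equal(ref$mean_points, a$points + 5, ignore_attr = TRUE)
  ref2 <- estimate_reference_shape(list(b, a), 128, 128)
  expect_equal(ref$mean_points, ref2$mean_points)
  same <- estimate_reference_shape(list(a, a, a), 128, 128)
  expect_equal(same$mean_points, a$points, ignore_attr = TRUE)
  short <- landmark_set(a$points[1:59, ], n_required = 59)
  expect_error(estimate_reference_shape(list(a, short), 128, 128),
               "inconsistent")
})

test_that("TPS warp is the identity when source equals reference", {
  lm <- tpl60(90)
  ref <- estimate_reference_shape(list(lm, lm), 96, 96)
  wf <- build_warp(lm, ref)
  expect_lt(max(abs(wf$map_x - (col(wf$map_x) - 1))), 1e-6)
  expect_lt(max(abs(wf$map_y - (row(wf$map_y) - 1))), 1e-6)
  expect_false(wf$folded)
})

test_that("TPS reproduces a pure translation exactly everywhere", {
  lm <- tpl60(90)
  ref <- estimate_reference_shape(list(lm, lm), 96, 96)
  src <- landmark_set(sweep(lm$points, 2, c(7, -3), `+`))
  wf <- build_warp(src, ref)
  expect_lt(max(abs(wf$map_x - (col(wf$map_x) - 1) - 7)), 1e-6)
  expect_lt(max(abs(wf$map_y - (row(wf$map_y) - 1) + 3)), 1e-6)
})

test_that("every reference landmark maps exactly onto its source landmark", {
  lm <- tpl60(120)
  ref <- estimate_reference_shape(list(lm, lm), 128, 128)
  set.seed(33)
  for (rep in 1:5) {
    src <- landmark_set(lm$points + matrix(runif(120, -3, 3), 60, 2))
    mapped <- warp_points(src, ref)
    expect_lt(max(abs(mapped - src$points)), 1e-6)
  }
})

test_that("duplicate landmarks raise a singular-system error", {
  p <- landmark_template() * 100
  p[2, ] <- p[1, ]
  ref <- estimate_reference_shape(list(landmark_set(p), landmark_set(p)),
                                  100, 100)
  expect_error(build_warp(landmark_set(p), ref), "singular|duplicate")
})

test_that("a landmark swap that folds the plane is flagged", {
  p <- landmark_template() * 100
  ref <- estimate_reference_shape(list(landmark_set(p), landmark_set(p)),
                                  100, 100)
  q <- p; q[25, ] <- p[26, ]; q[26, ] <- p[25, ]   # swap two eye points
  expect_warning(wf <- build_warp(landmark_set(q), ref), "fold")
  expect_true(wf$folded)
})

test_that("warping through the identity field preserves a smooth image", {
  lm <- tpl60(60)
  ref <- estimate_reference_shape(list(lm, lm), 64, 64)
  wf <- build_warp(lm, ref)
  x <- matrix(rep(0:63, each = 64), 64, 64)
  px <- array(c(30 + x / 8, 10 + x / 16, 12 + 0 * x), c(64, 64, 3))
  img <- lab_image(px)
  out <- warp_image(img, wf)
  expect_lt(max(abs(out$pixels[out$mask] -
                    px[array(out$mask, dim(px))])), 1e-6)
  # constant image stays constant wherever valid
  cimg <- const_lab(64, 64, 47, 9, 14)
  outc <- warp_image(cimg, wf)
  expect_lt(max(abs(outc$pixels[, , 1][outc$mask] - 47)), 1e-6)
})

test_that("a translation field shifts a delta patch by the translation", {
  lm <- tpl60(60)
  ref <- estimate_reference_shape(list(lm, lm), 64, 64)
  src <- landmark_set(sweep(lm$points, 2, c(4, 6), `+`))
  wf <- build_warp(src, ref)
  px <- array(20, c(64, 64, 3))
  px[31:34 + 6, 21:24 + 4, 1] <- 80       # patch at source position
  out <- warp_image(lab_image(px), wf)
  got <- which(out$pixels[, , 1] > 70, arr.ind = TRUE)
  # centroid in reference coords = source centroid minus translation
  expect_equal(mean(got[, 2] - 1), mean(21:24 - 1), tolerance = 0.01)
  expect_equal(mean(got[, 1] - 1), mean(31:34 - 1), tolerance = 0.01)
})

test_that("bilinear warping never overshoots the local value range", {
  set.seed(44)
  lm <- tpl60(60)
  ref <- estimate_reference_shape(list(lm, lm), 64, 64)
  src <- landmark_set(lm$points + matrix(runif(120, -1, 1), 60, 2))
  wf <- build_warp(src, ref)
  px <- array(runif(64 * 64 * 3, 0, 100), c(64, 64, 3))
  out <- warp_image(lab_image(px), wf)
  expect_gte(min(out$pixels[array(out$mask, dim(px))]), min(px))
  expect_lte(max(out$pixels[array(out$mask, dim(px))]), max(px))
})

test_that("landmark JSON files round-trip", {
  lm <- landmark_set(landmark_template() * 80 + 0.123, image_id = "img7")
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(lm2$points, lm$points, ignore_attr = TRUE)
  expect_identical(lm2$image_id, "img7")
})
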