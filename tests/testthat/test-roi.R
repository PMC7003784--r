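test_that("roi_mean averages exactly the pixels whose centres fall inside", {
  img <- const_lab(12, 12, 60, 8, 9)
  sq <- roi_spec("sq", cbind(c(2.5, 6.5, 6.5, 2.5), c(3.5, 3.5, 8.5, 8.5)))
  expect_equal(roi_mean(img, sq), c(L = 60, a = 8, b = 9))
  # patch/background half-split: centres x in 3..6, y in 4..8 (0-based)
  px <- array(rep(c(50, 0, 0), each = 144), c(12, 12, 3))
  px[, 6:12, 1] <- 70                       # x >= 5 is the patch
  lab <- lab_image(px)
  want <- mean(c(50, 50, 70, 70))           # centres x = 3,4 vs 5,6 per row
  expect_equal(unname(roi_mean(lab, sq)["L"]), want)
  # brute-force enumeration oracle on an irregular polygon
  poly <- cbind(c(1.2, 9.8, 7.1, 2.4), c(1.1, 2.9, 9.6, 8.2))
  set.seed(12)
  px2 <- array(runif(144 * 3, 20, 80), c(12, 12, 3))
  lab2 <- lab_image(px2)
  acc <- c(0, 0, 0); cnt <- 0
  for (yy in 0:11) for (xx in 0:11) {
    # independent even-odd test via angle winding on a dense edge walk
    sides <- 0
    n <- nrow(poly)
    for (e in seq_len(n)) {
      p1 <- poly[e, ]; p2 <- poly[if (e == n) 1 else e + 1, ]
      if ((p1[2] > yy) != (p2[2] > yy)) {
        xint <- p1[1] + (yy - p1[2]) * (p2[1] - p1[1]) / (p2[2] - p1[2])
        if (xx < xint) sides <- sides + 1
      }
    }
    if (sides %% 2 == 1) { acc <- acc + px2[yy + 1, xx + 1, ]; cnt <- cnt + 1 }
  }
  expect_equal(unname(roi_mean(lab2, roi_spec("p", poly))),
               unname(acc / cnt))
  # empty intersection errors
  far <- roi_spec("far", cbind(c(100, 101, 101), c(100, 100, 101)))
  expect_error(roi_mean(img, far), "overlap")
})

test_that("ROI masks respect the image mask", {
  m <- matrix(TRUE, 12, 12); m[, 1:6] <- FALSE
  px <- array(rep(c(50, 0, 0), each = 144), c(12, 12, 3))
  px[, 7:12, 1] <- 70
  img <- lab_image(px, mask = m)
  sq <- roi_spec("sq", cbind(c(0, 11, 11, 0), c(0, 0, 11, 11)))
  expect_equal(unname(roi_mean(img, sq)["L"]), 70)
})

test_that("the worked five-subject probe matches t and exact Wilcoxon", {
  mk <- function(vals, tp) {
    a <- array(50, c(5, 6, 6, 3))
    if (tp == "T28") for (i in 1:5) a[i, , , 1] <- 50 + vals[i]
    registered_stack(a, paste0("s", 1:5), "active", tp, matrix(TRUE, 6, 6))
  }
  roi <- roi_spec("all", cbind(c(0, 5, 5, 0), c(0, 0, 5, 5)))
  tab <- roi_change_table(list(active = list(T0 = mk(0, "T0"),
                                             T28 = mk(1:5, "T28"))),
                          list(roi))
  L <- tab[tab$channel == "L", ]
  expect_equal(L$delta_mean, 3)
  expect_equal(round(L$p_t, 4), 0.0132)
  expect_equal(L$p_wilcoxon, 0.0625)
  expect_equal(L$p_wilcoxon, wilcoxon_exact_enum(1:5))
  expect_true(L$significant)
  # unchanged channels are flat with p_t = 1
  a <- tab[tab$channel == "a", ]
  expect_equal(a$delta_mean, 0)
  expect_equal(a$p_t, 1)
})

test_that("Wilcoxon p-values agree with sign-flip enumeration", {
  set.seed(13)
  for (n in c(5, 7, 9)) {
    d <- round(rnorm(n, 0.3, 1), 3)
    got <- suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
    expect_equal(got, wilcoxon_exact_enum(d), tolerance = 1e-12)
  }
})

test_that("an injected regional effect is recovered in the ROI table", {
  set.seed(14)
  n <- 27; H <- 40; W <- 40
  rois <- default_rois(W, H)
  uc <- rois[[2]]                  # upper cheek
  sel <- matrix(FALSE, H, W)
  px <- rep(0:(W - 1), each = H); py <- rep(0:(H - 1), times = W)
  sel[point_in_polygon(px, py, uc$polygon)] <- TRUE
  one_draw <- function() {
    subj_effect <- rnorm(n, 0.36, 1.05)
    a0 <- array(0, c(n, H, W, 3))
    a0[, , , 1] <- 55; a0[, , , 2] <- 10; a0[, , , 3] <- 14
    a1 <- a0
    for (i in 1:n) {
      sl <- a1[i, , , 1]; sl[sel] <- sl[sel] + subj_effect[i]
      a1[i, , , 1] <- sl
    }
    s0 <- registered_stack(a0, sprintf("s%02d", 1:n), "active", "T0",
                           matrix(TRUE, H, W))
    s1 <- registered_stack(a1, sprintf("s%02d", 1:n), "active", "T28",
                           matrix(TRUE, H, W))
    tab <- roi_change_table(list(active = list(T0 = s0, T28 = s1)), rois)
    list(tab = tab, subj_effect = subj_effect)
  }
  first <- one_draw()
  row <- first$tab[first$tab$roi == "upper_cheek" & first$tab$channel == "L", ]
  # the realized per-subject effects are recovered exactly ...
  expect_equal(row$delta_mean, mean(first$subj_effect), tolerance = 1e-9)
  expect_equal(row$delta_sd, sd(first$subj_effect), tolerance = 1e-9)
  # ... untouched regions stay flat ...
  fh <- first$tab[first$tab$roi == "forehead" & first$tab$channel == "L", ]
  expect_equal(fh$delta_mean, 0)
  # ... and over repeated draws the estimate is unbiased for the
  # population effect (SE of the 8-draw mean ~ 0.07)
  draws <- c(row$delta_mean, replicate(7, {
    d <- one_draw()
    d$tab[d$tab$roi == "upper_cheek" & d$tab$channel == "L", "delta_mean"]
  }))
  expect_lt(abs(mean(draws) - 0.36), 0.3)
})

test_that("null ROI simulations flag at about the nominal 5% rate", {
  set.seed(15)
  reps <- 120; hits <- 0
  roi <- roi_spec("c", cbind(c(2, 15, 15, 2), c(2, 2, 15, 15)))
  for (r in seq_len(reps)) {
    s0 <- make_stack(8, 18, 18, noise = 1, timepoint = "T0",
                     group = "vehicle")
    s1 <- make_stack(8, 18, 18, noise = 1, timepoint = "T28",
                     group = "vehicle")
    tab <- roi_change_table(list(vehicle = list(T0 = s0, T28 = s1)),
                            list(roi))
    hits <- hits + sum(tab$significant)
  }
  rate <- hits / (reps * 3)
  expect_gt(rate, 0.01); expect_lt(rate, 0.11)
})

test_that("ROI JSON files round-trip", {
  rois <- default_rois(100, 100)
  f <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, f)
  rois2 <- read_rois(f)
  expect_equal(length(rois2), 4)
  expect_identical(rois2[[1]]$name, "forehead")
  expect_equal(rois2[[3]]$polygon, rois[[3]]$polygon, ignore_attr = TRUE)
})
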