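test_that("identical stacks give zero change and p = 1 everywhere", {
  set.seed(1)
  s0 <- make_stack(6, 10, 10, noise = 2, timepoint = "T0")
  s1 <- s0; s1$timepoint <- "T28"
  cm <- change_maps(s0, s1)
  expect_true(all(cm$dL == 0) && all(cm$da == 0) && all(cm$db == 0))
  expect_true(all(cm$dE == 0))
  expect_true(all(cm$p$L == 1) && all(cm$p$a == 1) && all(cm$p$b == 1))
  expect_equal(cm$qc$constant_nonzero, 0L)
})

test_that("the per-pixel paired t-test matches the reference implementation", {
  # worked probe: differences (1,2,3,4,5)
  a0 <- array(50, c(5, 1, 1, 3)); a1 <- a0; a1[, 1, 1, 1] <- 50 + 1:5
  s0 <- registered_stack(a0, paste0("s", 1:5), "active", "T0", matrix(TRUE, 1, 1))
  s1 <- registered_stack(a1, paste0("s", 1:5), "active", "T28", matrix(TRUE, 1, 1))
  cm <- change_maps(s0, s1)
  tt <- t.test(1:5)
  expect_equal(unname(tt$statistic), 4.2426, tolerance = 1e-4)
  expect_equal(cm$p$L[1, 1], tt$p.value, tolerance = 1e-12)
  expect_equal(round(cm$p$L[1, 1], 4), 0.0132)
  expect_equal(cm$dL[1, 1], 3)
  # antisymmetric differences: t = 0, p = 1
  a2 <- array(50, c(2, 1, 1, 3)); a3 <- a2
  a3[1, 1, 1, 1] <- 49; a3[2, 1, 1, 1] <- 51
  cm2 <- change_maps(
    registered_stack(a2, c("x", "y"), "active", "T0", matrix(TRUE, 1, 1)),
    registered_stack(a3, c("x", "y"), "active", "T28", matrix(TRUE, 1, 1)))
  expect_equal(cm2$p$L[1, 1], 1)
  # random stacks: every pixel against t.test
  set.seed(2)
  r0 <- make_stack(7, 5, 5, noise = 1.5, timepoint = "T0")
  r1 <- make_stack(7, 5, 5, noise = 1.5, timepoint = "T28")
  cmr <- change_maps(r0, r1)
  for (i in 1:5) for (j in 1:5) {
    d <- r1$lab_values[, i, j, 2] - r0$lab_values[, i, j, 2]
    expect_equal(cmr$p$a[i, j], t.test(d)$p.value, tolerance = 1e-10)
    expect_equal(cmr$da[i, j], mean(d), tolerance = 1e-12)
  }
})

test_that("pairing and dimension mismatches are rejected", {
  s0 <- make_stack(4, 4, 4, timepoint = "T0")
  s1 <- make_stack(4, 4, 4, timepoint = "T28",
                   ids = sprintf("z%03d", 1:4))
  expect_error(change_maps(s0, s1), "pairing|subject")
  g1 <- make_stack(4, 4, 4, timepoint = "T28", group = "vehicle")
  expect_error(change_maps(s0, g1), "group")
  one <- make_stack(1, 4, 4, timepoint = "T28", ids = "s001")
  expect_error(change_maps(make_stack(1, 4, 4, ids = "s001"), one),
               "at least 2")
})

test_that("dE is swap-invariant while signed maps negate", {
  set.seed(3)
  s0 <- make_stack(6, 8, 8, noise = 1, timepoint = "T0")
  s1 <- make_stack(6, 8, 8, noise = 1, shift = c(1, 0.5, -0.5),
                   timepoint = "T28")
  cm <- change_maps(s0, s1)
  s0b <- s0; s0b$timepoint <- "T28"; s1b <- s1; s1b$timepoint <- "T0"
  cmb <- change_maps(s1b, s0b)
  expect_equal(cm$dE, cmb$dE)
  expect_equal(cm$dL, -cmb$dL)
  expect_equal(cm$sign$a, -cmb$sign$a)
  expect_equal(cm$p$L, cmb$p$L)
})

test_that("constant non-zero differences hit the degenerate-pixel rule", {
  a0 <- array(50, c(3, 2, 2, 3)); a1 <- a0; a1[, 1, 1, 1] <- 52
  s0 <- registered_stack(a0, paste0("s", 1:3), "active", "T0", matrix(TRUE, 2, 2))
  s1 <- registered_stack(a1, paste0("s", 1:3), "active", "T28", matrix(TRUE, 2, 2))
  cm <- change_maps(s0, s1)
  expect_gt(cm$p$L[1, 1], 0)            # never exactly zero
  expect_lt(cm$p$L[1, 1], 1e-300)       # but at the vanishing-variance limit
  expect_equal(cm$p$L[1, 2], 1)
  expect_equal(cm$qc$constant_nonzero, 1L)
})

test_that("under a true null the significant-pixel fraction is near alpha", {
  set.seed(4)
  H <- 105; W <- 105; n <- 20
  s0 <- make_stack(n, H, W, noise = 1, timepoint = "T0")
  s1 <- make_stack(n, H, W, noise = 1, timepoint = "T28")
  cm <- change_maps(s0, s1)
  expect_gte(sum(cm$mask), 10000)
  for (ch in c("L", "a", "b")) {
    f <- mean(cm$p[[ch]][cm$mask] < 0.05)
    expect_gt(f, 0.035); expect_lt(f, 0.065)
  }
})

test_that("observed power tracks the closed-form paired-t power", {
  for (ratio in c(0.5, 1.0)) {
    set.seed(40 + ratio * 10)
    n <- 24; H <- 60; W <- 60
    s0 <- make_stack(n, H, W, timepoint = "T0")
    s1 <- make_stack(n, H, W, noise = 1, shift = c(ratio, 0, 0),
                     timepoint = "T28")
    cm <- change_maps(s0, s1)
    frac <- mean(cm$p$L[cm$mask] < 0.05)
    expect_equal(frac, paired_t_power(ratio, 1, n), tolerance = 0.03)
  }
})

test_that("the relevance map applies a strict dE > threshold rule", {
  mkpair <- function(dL) {
    a0 <- array(50, c(3, 6, 6, 3)); a1 <- a0
    a1[, 2:4, 2:4, 1] <- 50 + dL
    list(registered_stack(a0, paste0("s", 1:3), "active", "T0", matrix(TRUE, 6, 6)),
         registered_stack(a1, paste0("s", 1:3), "active", "T28", matrix(TRUE, 6, 6)))
  }
  p2 <- mkpair(2)
  rel2 <- relevance_map(change_maps(p2[[1]], p2[[2]]))
  expect_true(all(rel2$visible_mask[2:4, 2:4]))
  expect_false(any(rel2$visible_mask[, 5:6]))
  p1 <- mkpair(1)
  rel1 <- relevance_map(change_maps(p1[[1]], p1[[2]]))
  expect_false(any(rel1$visible_mask))   # dE = 1 exactly is NOT over 1
  # null: rendering equals the face
  pz <- mkpair(0)
  face <- lab_to_srgb(const_lab(6, 6, 50, 10, 10))
  relz <- relevance_map(change_maps(pz[[1]], pz[[2]]), face = face)
  expect_identical(relz$rendering$pixels, face$pixels)
})

test_that("significance maps follow the blue/red direction convention", {
  set.seed(5)
  n <- 24; H <- 20; W <- 20
  patch <- function(ch, delta) {
    a0 <- array(50, c(n, H, W, 3))
    a1 <- a0 + array(rnorm(n * H * W * 3, 0, 0.2), c(n, H, W, 3))
    a1[, 6:15, 6:15, ch] <- a1[, 6:15, 6:15, ch] + delta
    list(registered_stack(a0, sprintf("s%02d", 1:n), "active", "T0",
                          matrix(TRUE, H, W)),
         registered_stack(a1, sprintf("s%02d", 1:n), "active", "T28",
                          matrix(TRUE, H, W)))
  }
  # lighter skin (dL > 0) is the desired direction -> blue
  pL <- patch(1, +1)
  smL <- significance_map(change_maps(pL[[1]], pL[[2]]), "L")
  expect_gt(mean(smL$direction[6:15, 6:15] == "blue"), 0.95)
  expect_false(any(smL$direction == "red" & !smL$significant_mask))
  # more yellow (db > 0) is the undesired direction -> red
  pb <- patch(3, +1)
  smb <- significance_map(change_maps(pb[[1]], pb[[2]]), "b")
  expect_gt(mean(smb$direction[6:15, 6:15] == "red"), 0.95)
  # less red (da < 0) is desired -> blue
  pa <- patch(2, -1)
  sma <- significance_map(change_maps(pa[[1]], pa[[2]]), "a")
  expect_gt(mean(sma$direction[6:15, 6:15] == "blue"), 0.95)
  # null stacks: nothing significant
  s0 <- make_stack(5, 8, 8, timepoint = "T0")
  s1 <- s0; s1$timepoint <- "T28"
  smn <- significance_map(change_maps(s0, s1), "L")
  expect_false(any(smn$significant_mask))
})

test_that("BH correction only ever weakens per-pixel significance", {
  set.seed(6)
  s0 <- make_stack(8, 12, 12, noise = 1, timepoint = "T0")
  s1 <- make_stack(8, 12, 12, noise = 1, shift = c(0.5, 0, 0),
                   timepoint = "T28")
  raw <- change_maps(s0, s1)
  adj <- change_maps(s0, s1, fdr = TRUE)
  expect_true(all(adj$p$L[adj$mask] >= raw$p$L[raw$mask] - 1e-12))
})
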