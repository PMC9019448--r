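test_that("weighted cross-entropy matches closed forms and validates input", {
  # single sample, true class 2, uniform prediction
  expect_equal(weighted_cross_entropy(matrix(c(0, 1), 1), matrix(c(0.5, 0.5), 1)),
               -log(0.5), tolerance = 1e-12)
  # perfect prediction -> 0 up to the log clamp
  y <- matrix(c(1, 0, 0, 1, 1, 0), 3, byrow = TRUE)
  expect_lt(weighted_cross_entropy(y, y), 1e-10)
  expect_error(weighted_cross_entropy(y, y, w = c(-1, 1)), "negative")
  expect_error(weighted_cross_entropy(y, y, w = c(0, 0)), "> 0")
  expect_error(weighted_cross_entropy(y, matrix(0.4, 3, 2)), "sum to 1")
  expect_error(weighted_cross_entropy(matrix(0.5, 3, 2), y), "one-hot")
})

test_that("doubling the foreground weight doubles its loss share on a toy grid", {
  # 3x3 toy labels/probabilities, hand-summed oracle
  set.seed(2)
  lab <- matrix(c(0, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  pfg <- matrix(runif(9, 0.1, 0.9), 3)
  y <- cbind(as.vector(1 - lab), as.vector(lab))
  yp <- cbind(1 - as.vector(pfg), as.vector(pfg))
  hand <- function(w) {
    tot <- 0
    for (i in 1:9) for (cc in 1:2) tot <- tot - w[cc] * y[i, cc] * log(yp[i, cc])
    tot / 9
  }
  w1 <- c(1, 1); w2 <- c(1, 2)
  expect_equal(weighted_cross_entropy(y, yp, w1), hand(w1), tolerance = 1e-12)
  expect_equal(weighted_cross_entropy(y, yp, w2), hand(w2), tolerance = 1e-12)
  fg_share <- function(w) {
    sum(-w[2] * y[, 2] * log(yp[, 2])) / 9
  }
  expect_equal(weighted_cross_entropy(y, yp, w2) - weighted_cross_entropy(y, yp, w1),
               fg_share(c(1, 1)), tolerance = 1e-12)
})

test_that("uniform weights reduce to plain cross-entropy on random inputs", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    p <- matrix(runif(2 * n, 0.05, 1), n)
    p <- p / rowSums(p)
    cls <- sample(1:2, n, replace = TRUE)
    y <- cbind(cls == 1, cls == 2) + 0
    expect_equal(weighted_cross_entropy(y, p, c(1, 1)), bf_cross_entropy(y, p),
                 tolerance = 1e-9)
  }
})

test_that("dsc handles identities, disjoint masks and counts", {
  m <- random_small_mask()
  expect_equal(dsc(m, m), 1)
  a <- array(0L, c(4, 4, 2)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 2)); b[3:4, 4, 2] <- 1L
  expect_equal(dsc(a, b), 0)
  # |A| = 4, |B| = 2, overlap 1 -> 1/3
  a2 <- array(0L, c(4, 4, 1)); a2[1:4, 1, 1] <- 1L
  b2 <- array(0L, c(4, 4, 1)); b2[1, 1, 1] <- 1L; b2[1, 2, 1] <- 1L
  expect_equal(dsc(a2, b2), 2 * 1 / (4 + 2))
  expect_equal(dsc(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), 1)
  expect_error(dsc(a, array(0L, c(3, 3, 3))), "shape")
  # symmetry
  expect_equal(dsc(a2, b2), dsc(b2, a2))
})

test_that("surface extraction matches the 6-connectivity definition", {
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_equal(surface_voxels(single), which(single == 1, arr.ind = TRUE),
               ignore_attr = TRUE)
  cube <- array(1L, c(3, 3, 3))
  s <- surface_voxels(cube)
  expect_equal(nrow(s), 26)  # all but the centre voxel
  expect_false(any(s[, 1] == 2 & s[, 2] == 2 & s[, 3] == 2))
  expect_equal(nrow(surface_voxels(array(0L, c(3, 3, 3)))), 0)
  # border foreground voxels are surface even without interior background
  slab <- array(1L, c(2, 2, 1))
  expect_equal(nrow(surface_voxels(slab)), 4)
})

test_that("surface distances match closed forms and scale with spacing", {
  a <- array(0L, c(8, 4, 4)); a[2, 2, 2] <- 1L
  b <- array(0L, c(8, 4, 4)); b[5, 2, 2] <- 1L
  # two single voxels 3 voxels apart along an axis with 0.5 mm spacing
  expect_equal(asd(a, b, c(0.5, 0.5, 0.5)), 1.5, tolerance = 1e-12)
  expect_equal(avd(a, b, c(0.5, 0.5, 0.5)), 1.5, tolerance = 1e-12)
  m <- random_small_mask()
  expect_equal(asd(m, m, c(1, 1, 1)), 0)
  expect_equal(avd(m, m, c(1, 1, 1)), 0)
  # linear scaling with isotropic spacing
  set.seed(3)
  x <- random_small_mask(); y <- random_small_mask()
  expect_equal(asd(x, y, c(2, 2, 2)), 2 * asd(x, y, c(1, 1, 1)), tolerance = 1e-9)
  expect_equal(avd(x, y, c(2, 2, 2)), 2 * avd(x, y, c(1, 1, 1)), tolerance = 1e-9)
  empty <- array(0L, c(8, 4, 4))
  expect_error(asd(a, empty, c(1, 1, 1)), "empty")
})

test_that("avd equals the larger directed mean and is bounded by Hausdorff", {
  a <- array(0L, c(6, 6, 2)); a[2, 2, 1] <- 1L
  b <- array(0L, c(6, 6, 2)); b[2, 2, 1] <- 1L; b[5, 5, 1] <- 1L; b[2, 5, 2] <- 1L
  sp <- c(1, 1, 1)
  d <- bf_directed_means(a, b, sp)
  expect_false(isTRUE(all.equal(mean(d$ab), mean(d$ba))))
  expect_equal(avd(a, b, sp), max(mean(d$ab), mean(d$ba)), tolerance = 1e-12)
  expect_gte(avd(a, b, sp) + 1e-12, mean(d$ab))
  expect_gte(avd(a, b, sp) + 1e-12, mean(d$ba))
  expect_lte(avd(a, b, sp), bf_hausdorff(a, b, sp) + 1e-12)
})

test_that("metrics agree with brute-force oracles on randomized mask pairs", {
  set.seed(77)
  for (i in 1:40) {
    a <- random_small_mask(c(8L, 8L, 5L))
    b <- random_small_mask(c(8L, 8L, 5L))
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- runif(3, 0.2, 1.5)
    expect_equal(dsc(a, b), bf_dsc(a, b), tolerance = 1e-12)
    expect_equal(asd(a, b, sp), bf_asd(a, b, sp), tolerance = 1e-9)
    expect_equal(avd(a, b, sp), bf_avd(a, b, sp), tolerance = 1e-9)
  }
})

test_that("metrics report aggregates cases and flags empty predictions", {
  gt <- label_mask(random_small_mask(), c(0.5, 0.5, 0.5))
  pred_ok <- gt
  pred_empty <- label_mask(array(0L, dim(gt$labels)), c(0.5, 0.5, 0.5))
  rep_ <- metrics_report(list(pred_ok, pred_empty), list(gt, gt))
  expect_equal(nrow(rep_), 3)
  expect_equal(rep_$dsc[1], 1)
  expect_true(is.na(rep_$asd_mm[2]))
  expect_equal(rep_$case_id[3], "mean")
  expect_equal(rep_$asd_mm[3], rep_$asd_mm[1])  # mean over defined cases
})

test_that("class weights are inverse-frequency based, capped and normalised", {
  m <- array(0L, c(10, 10, 10)); m[1:5, 1, 1] <- 1L  # 0.5% foreground
  w <- class_weights_from_masks(list(m))
  expect_equal(mean(w), 1)
  expect_equal(w[2] / w[1], 20)  # hits the default cap
  w5 <- class_weights_from_masks(list(m), cap_ratio = 5)
  expect_equal(w5[2] / w5[1], 5)
  m2 <- array(0L, c(4, 4, 4)); m2[1:32] <- 1L  # balanced
  expect_equal(class_weights_from_masks(list(m2)), c(1, 1))
  expect_equal(class_weights_from_masks(list(array(0L, c(2, 2, 2)))), c(1, 1))
})
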