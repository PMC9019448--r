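ns <- asNamespace("vestibuleseg")

test_that("downblocks pool as specified: max at level 1, average at 2-4", {
  cfg <- net2d_config(channels = c(4L, 8L, 8L, 8L, 8L))
  expect_equal(build_downblock(1L, 1L, cfg)$pool_type, "max")
  expect_equal(build_downblock(2L, 4L, cfg)$pool_type, "avg")
  expect_equal(build_downblock(3L, 8L, cfg)$pool_type, "avg")
  expect_equal(build_downblock(4L, 8L, cfg)$pool_type, "avg")
  expect_equal(build_downblock(5L, 8L, cfg)$pool_type, "none")
  expect_error(build_downblock(0L, 1L, cfg), "level")
  expect_error(build_downblock(6L, 1L, cfg), "level")
})

test_that("the encoder halves the spatial size at each pooled level", {
  set.seed(1)
  cfg <- net2d_config(channels = c(2L, 2L, 2L, 2L, 2L), kernels = 3L,
                      se_reduction = 4L)
  net <- net2d_new(cfg, 1L)
  h <- array(rnorm(224 * 224), c(224, 224, 1, 1, 1))
  sizes <- integer(0)
  for (l in 1:5) {
    res <- ns$downblock_forward(net$enc[[l]], h, FALSE)
    h <- ns$ag_val(res$out)
    sizes <- c(sizes, dim(h)[1])
  }
  expect_equal(sizes, c(112L, 56L, 28L, 14L, 14L))  # level-5 input is 14x14
})

test_that("multi-receptive-field fusion keeps shape and honours channel budgets", {
  set.seed(2)
  x <- array(rnorm(64 * 64 * 1 * 3 * 2), c(64, 64, 1, 3, 2))
  # degenerate single-kernel set reduces to conv + projection
  m1 <- multi_rf_fusion(3L, 5L, kernels = 3L)
  expect_length(m1$branches, 1L)
  y1 <- ns$ag_val(multi_rf_forward(m1, x))
  ref <- ns$ag_val(ns$ly_fwd(m1$proj, ns$ly_fwd(m1$branches[[1]], x)))
  expect_equal(y1, ref, tolerance = 1e-12)
  # same-padding contract over the standard kernel set
  m3 <- multi_rf_fusion(3L, 6L, kernels = c(1L, 3L, 5L))
  y3 <- ns$ag_val(multi_rf_forward(m3, x))
  expect_equal(dim(y3), c(64, 64, 1, 6, 2))
  # output channels equal the budget regardless of branch count
  for (ks in list(1L, c(3L, 5L), c(1L, 3L, 5L, 7L))) {
    cout <- sample(2:9, 1)
    mm <- multi_rf_fusion(3L, cout, kernels = ks)
    expect_equal(dim(ns$ag_val(multi_rf_forward(mm, x)))[4], cout)
  }
  expect_error(multi_rf_fusion(3L, 4L, kernels = integer(0)), "empty")
})

test_that("SE gating squeezes channel means and stays in (0, 1)", {
  set.seed(3)
  se <- se_block(6L, reduction = 2L)
  # constant-per-channel input: the squeeze vector is the channel constants
  consts <- c(0.5, -1, 2, 0, 1.5, 3)
  x <- ns$chexpand(consts, c(4, 4, 2, 6, 1))
  sq <- ns$op_gap(x)
  expect_equal(as.vector(sq), consts, tolerance = 1e-12)
  g <- ns$ag_val(ns$op_sigmoid(ns$ly_fwd(se$fc2, ns$op_relu(ns$ly_fwd(se$fc1, sq)))))
  expect_true(all(g > 0 & g < 1))
  # gated output = per-channel rescale of x
  y <- ns$ag_val(se_forward(se, x))
  expect_equal(as.vector(y[1, 1, 1, , 1]), consts * as.vector(g), tolerance = 1e-12)
})

test_that("forward_2d meets the shape contract and normalises class scores", {
  set.seed(4)
  cfg <- net2d_config(channels = c(4L, 8L, 8L, 8L, 8L), se_reduction = 4L)
  net <- net2d_new(cfg, 1L)
  out <- ns$ag_no_grad(forward_2d(net, feature_stack(array(rnorm(3 * 64 * 48),
                                                           c(3, 64, 48, 1)), "slices")))
  expect_equal(dim(out$features$data), c(3, 64, 48, 64))
  expect_equal(dim(out$logits$data), c(3, 64, 48, 2))
  p <- ns$softmax_channels(ns$t5(ns$ag_val(out$logits5)))
  sums <- p[, , , 1, ] + p[, , , 2, ]
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  expect_error(forward_2d(net, feature_stack(array(0, c(1, 50, 64, 1)), "slices")),
               "divisible by 16")
})

test_that("the centre output pixel sees distant input pixels", {
  set.seed(5)
  cfg <- net2d_config(channels = c(4L, 8L, 8L, 8L, 8L), se_reduction = 4L)
  net <- net2d_new(cfg, 1L)
  x <- array(rnorm(64 * 64), c(1, 64, 64, 1))
  base <- ns$ag_no_grad(forward_2d(net, feature_stack(x, "slices")))
  x2 <- x
  x2[1, 1, 1, 1] <- x2[1, 1, 1, 1] + 5
  pert <- ns$ag_no_grad(forward_2d(net, feature_stack(x2, "slices")))
  centre_diff <- abs(ns$ag_val(base$logits5)[32, 32, 1, 1, 1] -
                       ns$ag_val(pert$logits5)[32, 32, 1, 1, 1])
  expect_gt(centre_diff, 0)
})

test_that("a tiny 2D network overfits a handful of phantom slices", {
  set.seed(6)
  ph <- generate_phantom(phantom_spec(volume_shape = c(32L, 32L, 8L),
                                      voxel_spacing = c(0.25, 0.25, 0.5),
                                      radii_range = c(0.4, 0.8), seed = 15L))
  vol <- window_normalize(ph$volume)
  ks <- which(apply(ph$mask$labels, 3, sum) > 0)[1:2]
  ks <- c(ks, 1L, 8L)  # two foreground slices, two background slices
  xs <- array(0, c(4, 32, 32, 1))
  yb <- array(0, c(32, 32, 1, 4))
  for (i in 1:4) {
    xs[i, , , 1] <- vol$data[, , ks[i]]
    yb[, , 1, i] <- ph$mask$labels[, , ks[i]]
  }
  cfg <- net2d_config(channels = c(4L, 8L, 8L, 8L, 8L), se_reduction = 4L)
  net <- net2d_new(cfg, 1L)
  opt <- sgd_new(ns$collect_params(net), lr = 0.15)
  w <- class_weights_from_masks(list(ph$mask))
  losses <- numeric(0)
  for (step in 1:200) {
    ns$ag_tape_start()
    out <- forward_2d(net, feature_stack(xs, "slices"), training = TRUE)
    loss <- ns$op_wce_logits(out$logits5, ns$onehot5(yb), w)
    losses <- c(losses, ns$ag_val(loss))
    ns$ag_backward(loss)
    sgd_step(opt)
  }
  out <- ns$ag_no_grad(forward_2d(net, feature_stack(xs, "slices"), FALSE))
  p <- ns$softmax_channels(ns$t5(ns$ag_val(out$logits5)))
  pred <- p[, , 1, 2, ] > 0.5
  acc <- mean((pred * 1) == aperm(yb[, , 1, ], c(1, 2, 3)))
  expect_gt(acc, 0.99)
  expect_lt(mean(tail(losses, 10)), 0.5 * mean(head(losses, 10)))
})
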