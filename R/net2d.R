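# Intraslice 2D segmentation network: a five-level encoder-decoder with
# three feature-fusion strategies — multi-receptive-field convolution fusion,
# squeeze-and-excitation channel attention in the encoder, and concatenation
# skip connections between encoder and decoder. 2D slices travel as 5D
# tensors with depth 1.

#' Configuration of the intraslice 2D network
#'
#' Five encoder and five decoder blocks. Each Downblock is
#' multi-receptive-field convolution fusion, then an SE block, batch norm,
#' ReLU, and pooling (max pooling in Downblock 1, average pooling in
#' Downblocks 2-4; level 5 is the bottleneck without pooling). The decoder
#' mirrors the encoder with transposed-convolution upsampling and
#' concatenation skips, without SE blocks; upblock 5 emits the 64-channel
#' feature map consumed by the hybrid fusion head.
#'
#' @param channels channel schedule over the five levels.
#' @param kernels kernel sizes of the parallel receptive-field branches.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param n_classes number of output classes.
#' @param feature_channels channels of the upblock-5 feature map (64 is
#'   required by the hybrid fusion arithmetic).
#' @return object of class `net2d_config`.
#' @export
net2d_config <- function(channels = c(32L, 64L, 128L, 256L, 512L),
                         kernels = c(1L, 3L, 5L),
                         se_reduction = 16L,
                         n_classes = 2L,
                         feature_channels = 64L) {
  if (length(channels) != 5L) stop("net2d_config: exactly 5 levels are required")
  if (length(kernels) < 1L) stop("net2d_config: kernel set must be non-empty")
  structure(list(channels = as.integer(channels), kernels = as.integer(kernels),
                 se_reduction = as.integer(se_reduction),
                 n_classes = as.integer(n_classes),
                 feature_channels = as.integer(feature_channels)),
            class = "net2d_config")
}

#' Multi-receptive-field convolution fusion stage
#'
#' Parallel same-padding 2D convolutions with distinct kernel sizes, their
#' outputs concatenated and projected by a 1x1 convolution to `cout`.
#'
#' @param cin,cout input/output channels.
#' @param kernels integer vector of square kernel sizes.
#' @return a layer list for [multi_rf_forward()].
#' @export
multi_rf_fusion <- function(cin, cout, kernels = c(1L, 3L, 5L)) {
  if (length(kernels) < 1L) stop("multi_rf_fusion: empty kernel set")
  branches <- lapply(kernels, function(k) ly_conv(c(k, k, 1L), cin, cout))
  list(type = "multi_rf", branches = branches,
       proj = ly_conv(c(1L, 1L, 1L), cout * length(kernels), cout))
}

#' Forward pass of the multi-receptive-field fusion stage
#' @param mrf layer from [multi_rf_fusion()].
#' @param x 5D input tensor.
#' @param training logical.
#' @return fused tensor with `cout` channels, same spatial shape.
#' @export
multi_rf_forward <- function(mrf, x, training = FALSE) {
  outs <- lapply(mrf$branches, function(b) ly_fwd(b, x, training))
  ly_fwd(mrf$proj, if (length(outs) == 1L) outs[[1]] else op_concat_c(outs), training)
}

#' Build one encoder Downblock of the 2D network
#'
#' Multi-receptive-field fusion, SE block, batch norm, ReLU, then pooling:
#' max pooling at level 1, average pooling at levels 2-4. Level 5 (the
#' bottleneck) carries no pooling.
#'
#' @param level integer in 1..5.
#' @param cin input channels.
#' @param cfg a [net2d_config()].
#' @return a layer list.
#' @export
build_downblock <- function(level, cin, cfg) {
  if (level < 1L || level > 5L) stop("build_downblock: level must be in 1..5")
  cout <- cfg$channels[level]
  list(type = "downblock", level = level,
       mrf = multi_rf_fusion(cin, cout, cfg$kernels),
       se = se_block(cout, cfg$se_reduction),
       bn = ly_bn(cout),
       pool_type = if (level == 1L) "max" else if (level <= 4L) "avg" else "none")
}

downblock_forward <- function(blk, x, training = FALSE) {
  h <- multi_rf_forward(blk$mrf, x, training)
  h <- se_forward(blk$se, h, training)
  h <- op_relu(ly_fwd(blk$bn, h, training))
  pre_pool <- h
  if (blk$pool_type != "none") {
    h <- op_pool(h, c(2L, 2L, 1L), c(2L, 2L, 1L), type = blk$pool_type)
  }
  list(out = h, skip = pre_pool)
}

#' Construct the intraslice 2D network
#'
#' @param cfg a [net2d_config()].
#' @param in_channels input channels per slice (1 for windowed CT).
#' @return object of class `net2d`.
#' @export
net2d_new <- function(cfg = net2d_config(), in_channels = 1L) {
  ch <- cfg$channels
  enc <- list()
  cin <- in_channels
  for (l in 1:5) {
    enc[[l]] <- build_downblock(l, cin, cfg)
    cin <- ch[l]
  }
  dec <- list()
  for (l in 4:1) {
    dec[[paste0("up", l)]] <- list(
      up = ly_convtr(c(2L, 2L, 1L), if (l == 4L) ch[5] else ch[l + 1], ch[l]),
      conv = ly_conv(c(3L, 3L, 1L), 2L * ch[l], ch[l]),
      bn = ly_bn(ch[l]))
  }
  structure(list(cfg = cfg, in_channels = as.integer(in_channels),
                 enc = enc, dec = dec,
                 feat = list(conv = ly_conv(c(3L, 3L, 1L), ch[1], cfg$feature_channels),
                             bn = ly_bn(cfg$feature_channels)),
                 head = ly_conv(c(1L, 1L, 1L), cfg$feature_channels, cfg$n_classes)),
            class = "net2d")
}

#' Segment a volume slice by slice with the 2D network alone
#'
#' The "2D only" (ablation A) prediction path: every depth slice is passed
#' through the network and foreground probabilities above 0.5 become mask
#' voxels.
#'
#' @param vol a normalized [ct_volume()].
#' @param net a [net2d_new()] model.
#' @return a [label_mask()] aligned with `vol`.
#' @export
predict_volume_2d <- function(vol, net) {
  stopifnot(inherits(vol, "ct_volume"), inherits(net, "net2d"))
  if (!vol$normalized) stop("predict_volume_2d: volume must be window-normalized")
  label_mask(predict_slices_2d(net, vol$data), vol$spacing)
}

#' Forward pass of the 2D network over a batch of slices
#'
#' @param net a [net2d_new()] model.
#' @param slices `feature_stack` with slices axes (N, H, W, C), or a 4D
#'   array in that order; H and W must be divisible by 16.
#' @param training logical; enables batch statistics.
#' @return list with `logits` and `features` as slices-axes
#'   [feature_stack()]s of shapes (N, H, W, n_classes) and (N, H, W, 64)
#'   (plus the internal 5D tensors `logits5`, `features5`).
#' @export
forward_2d <- function(net, slices, training = FALSE) {
  if (inherits(slices, "feature_stack")) {
    if (slices$axes != "slices") stop("forward_2d: expected slices axes (N,H,W,C)")
    arr <- slices$data
  } else {
    arr <- as.array(slices)
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  }
  d <- dim(arr)  # N,H,W,C
  if (d[2] %% 16L != 0L || d[3] %% 16L != 0L) {
    stop("forward_2d: H and W must be divisible by 16 (2^4 poolings); ",
         "pad the slices to a multiple of 16")
  }
  x <- aperm(arr, c(2, 3, 4, 1))                 # H,W,C,N
  x <- array(x, c(d[2], d[3], 1L, d[4], d[1]))   # insert singleton depth: H,W,1,C,N
  skips <- list()
  h <- x
  for (l in 1:5) {
    res <- downblock_forward(net$enc[[l]], h, training)
    h <- res$out
    if (l <= 4L) skips[[l]] <- res$skip
  }
  for (l in 4:1) {
    blk <- net$dec[[paste0("up", l)]]
    h <- ly_fwd(blk$up, h, training)
    h <- op_concat_c(list(h, skips[[l]]))
    h <- op_relu(ly_fwd(blk$bn, ly_fwd(blk$conv, h, training), training))
  }
  feats <- op_relu(ly_fwd(net$feat$bn, ly_fwd(net$feat$conv, h, training), training))
  logits <- ly_fwd(net$head, feats, training)
  fv <- ag_val(feats); lv <- ag_val(logits)
  to_slices <- function(t5v) {
    dd <- dim(t5v)  # H,W,1,C,N
    feature_stack(aperm(array(t5v, dd[c(1, 2, 4, 5)]), c(4, 1, 2, 3)), "slices")
  }
  list(logits = to_slices(lv), features = to_slices(fv),
       logits5 = logits, features5 = feats)
}
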