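# Hybrid feature fusion: the 2D network's per-slice features are converted
# back to volume form (f-inverse), concatenated with the 3D DenseUNet's
# features (64 + 64 = 128 channels) and reduced to per-voxel class scores by
# the HFF head (conv, dropout, batch norm, ReLU, then a 1x1x1 classifier).

#' Configuration of the hybrid feature fusion head
#'
#' @param dropout_rate dropout probability after the fusion convolution.
#' @param fusion_channels width of the internal fusion convolution.
#' @param n_classes output classes (2: background / vestibule).
#' @param in_channels expected input channels (64 2D-derived + 64
#'   3D-derived).
#' @return object of class `hff_config`.
#' @export
hff_config <- function(dropout_rate = 0.3, fusion_channels = 64L,
                       n_classes = 2L, in_channels = 128L) {
  structure(list(dropout_rate = dropout_rate,
                 fusion_channels = as.integer(fusion_channels),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "hff_config")
}

#' Construct the HFF head
#' @param cfg a [hff_config()].
#' @return object of class `hff`.
#' @export
hff_new <- function(cfg = hff_config()) {
  structure(list(cfg = cfg,
                 conv1 = ly_conv(c(3L, 3L, 3L), cfg$in_channels, cfg$fusion_channels),
                 bn = ly_bn(cfg$fusion_channels),
                 conv2 = ly_conv(c(1L, 1L, 1L), cfg$fusion_channels, cfg$n_classes)),
            class = "hff")
}

#' Forward pass of the HFF head
#'
#' Convolution, dropout, batch norm, ReLU, then a 1x1x1 convolution to the
#' class channels. Dropout is inactive in inference mode.
#'
#' @param hff a [hff_new()] head.
#' @param fused_in 5D tensor (H, W, D, 128, N): channel concatenation of the
#'   2D-derived and 3D-derived 64-channel feature volumes.
#' @param training logical.
#' @return 5D logits (H, W, D, n_classes, N).
#' @export
hff_forward <- function(hff, fused_in, training = FALSE) {
  d <- dim(ag_val(fused_in))
  if (d[4] != hff$cfg$in_channels) {
    stop(sprintf("hff_forward: expected %d input channels, got %d",
                 hff$cfg$in_channels, d[4]))
  }
  h <- ly_fwd(hff$conv1, fused_in, training)
  h <- op_dropout(h, hff$cfg$dropout_rate, training)
  h <- op_relu(ly_fwd(hff$bn, h, training))
  ly_fwd(hff$conv2, h, training)
}

#' Assemble the full hybrid model
#'
#' @param net2d intraslice network ([net2d_new()]).
#' @param net3d interslice network ([densunet3d_new()], `in_channels = 2`).
#' @param hff fusion head ([hff_new()]).
#' @return object of class `hybrid_model`.
#' @export
hybrid_model <- function(net2d = net2d_new(), net3d = densunet3d_new(),
                         hff = hff_new()) {
  stopifnot(inherits(net2d, "net2d"), inherits(net3d, "densunet3d"),
            inherits(hff, "hff"))
  structure(list(net2d = net2d, net3d = net3d, hff = hff),
            class = "hybrid_model")
}

patch_to_array <- function(patch) {
  if (inherits(patch, "ct_volume")) {
    if (!patch$normalized) stop("hybrid_forward: patch must be window-normalized")
    patch$data
  } else {
    as.array(patch)
  }
}

#' Forward pass of the full hybrid segmentation network
#'
#' The patch is converted to slices (f), passed through the 2D network, and
#' both its foreground probability map and its 64-channel feature map are
#' converted back to volume form (f-inverse). The 3D DenseUNet receives the
#' patch concatenated with the 2D foreground probabilities (2 channels); its
#' 64-channel features are concatenated with the 2D feature volume (128
#' channels) and fused by the HFF head into per-voxel class probabilities.
#'
#' @param model a [hybrid_model()].
#' @param patch normalized [ct_volume()] or 3D array (H, W, D); H, W must be
#'   divisible by 32 and D by 4.
#' @param training logical; when TRUE the 2D network is still run frozen
#'   (no gradient) if `freeze_2d` is TRUE.
#' @param freeze_2d run the 2D network without recording gradients
#'   (the default two-stage schedule trains it separately).
#' @param mode `"A+B+C"` (full model), `"A+B"` (bypass the HFF head, use the
#'   3D network's auxiliary 2-class head) or `"A"` (2D network only).
#' @return list with `probs` (H, W, D, n_classes array of per-voxel
#'   probabilities summing to 1), `logits5` (the differentiable logits
#'   tensor) and `probs2d` (the 2D network's foreground probability volume).
#' @export
hybrid_forward <- function(model, patch, training = FALSE, freeze_2d = TRUE,
                           mode = c("A+B+C", "A+B", "A")) {
  mode <- match.arg(mode)
  arr <- patch_to_array(patch)
  d <- dim(arr)
  run2d <- function() {
    slices <- f_volume_to_slices(feature_stack(array(arr, c(d, 1L)), "volume"))
    forward_2d(model$net2d, slices, training = training && !freeze_2d)
  }
  out2d <- if (freeze_2d) ag_no_grad(run2d()) else run2d()
  probs2d_sl <- softmax_channels(t5(ag_val(out2d$logits5)))
  # foreground probability map back in volume form: (H,W,1,2,N) -> (H,W,D)
  p2 <- probs2d_sl[, , 1, 2, ]
  probs2d_vol <- array(p2, d)
  if (mode == "A") {
    logits_sl <- ag_val(out2d$logits5)          # H,W,1,C,N
    nc <- dim(logits_sl)[4]
    logits_vol <- aperm(array(logits_sl, dim(logits_sl)[c(1, 2, 4, 5)]), c(1, 2, 4, 3))
    probs <- softmax_channels(array(logits_vol, c(d, nc, 1L)))
    return(list(probs = array(probs, c(d, nc)), logits5 = out2d$logits5,
                probs2d = probs2d_vol))
  }
  vol_in <- array(0, c(d, 2L, 1L))
  vol_in[, , , 1L, 1L] <- arr
  vol_in[, , , 2L, 1L] <- probs2d_vol
  out3d <- forward_3d(model$net3d, feature_stack(array(vol_in, c(d, 2L)), "volume"),
                      training = training, use_aux_head = (mode == "A+B"))
  if (mode == "A+B") {
    logits <- out3d$aux_logits5
  } else {
    feats2d_vol <- f_inverse_slices_to_volume(out2d$features)
    f2 <- array(feats2d_vol$data, c(d, dim(feats2d_vol$data)[4], 1L))
    fused <- op_concat_c(list(ag_wrap_const(f2), out3d$features5))
    logits <- hff_forward(model$hff, fused, training = training)
  }
  lv <- ag_val(logits)
  probs <- softmax_channels(lv)
  list(probs = array(probs, dim(lv)[1:4]), logits5 = logits,
       probs2d = probs2d_vol)
}

# wrap a plain array so op_concat_c sees a uniform input list
ag_wrap_const <- function(x) x

#' Segment a whole volume with a trained hybrid model
#'
#' Tiles the volume into patches, runs [hybrid_forward()] on each,
#' overlap-averages the per-voxel foreground probabilities and thresholds by
#' argmax.
#'
#' @param vol normalized [ct_volume()].
#' @param model a [hybrid_model()].
#' @param patch_shape patch size, default c(224, 224, 8).
#' @param patch_stride stride between patches, default `patch_shape`.
#' @param mode forwarded to [hybrid_forward()].
#' @return a [label_mask()] aligned with `vol`.
#' @export
predict_volume <- function(vol, model, patch_shape = c(224L, 224L, 8L),
                           patch_stride = patch_shape, mode = "A+B+C") {
  stopifnot(inherits(vol, "ct_volume"))
  if (!vol$normalized) stop("predict_volume: volume must be window-normalized")
  patches <- extract_patches(vol, NULL, patch_shape, patch_stride)
  fields <- lapply(patches, function(p) {
    out <- ag_no_grad(hybrid_forward(model, p$patch, training = FALSE, mode = mode))
    out$probs[, , , 2L]
  })
  d <- dim(vol$data)
  padded <- pmax(d, as.integer(patch_shape))
  prob_fg <- reassemble_patches(patches, fields, padded)
  # cut away symmetric padding if the volume was smaller than the patch
  lo <- (padded - d) %/% 2L
  prob_fg <- prob_fg[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]),
                     lo[3] + seq_len(d[3]), drop = FALSE]
  label_mask(array(as.integer(prob_fg > 0.5), d), vol$spacing)
}
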