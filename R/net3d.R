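# Interslice 3D DenseUNet: DenseNet-BC encoder (half-depth blocks, growth
# rate K) with a UNet-style transposed-convolution decoder joined to the
# encoder by elementwise sums. The default configuration reproduces the
# printed layer schedule of the reference architecture row for row; a
# machine-readable transcription ships in inst/extdata for the shape-trace
# oracle.

#' Configuration of the 3D DenseUNet
#'
#' Defaults: growth rate `K = 32`; dense blocks of (3, 4, 12, 8) layers
#' (half of DenseNet-121's (6, 12, 24, 16)); 1x1x1 bottleneck width `4K`
#' (128); 7x7x7 stem with `3K` (96) channels; DenseNet-BC compression 0.5 in
#' the transition layers. With compression 0.5 the encoder channel trail is
#' 96 / 192 / 96 / 224 / 112 / 496 / 248 / 504, so dense block 4 feeds the
#' printed 504-channel upconv directly and the skips of upsampling layers
#' 2-4 match their upconv widths (224 / 192 / 96); only the first sum
#' junction needs a 1x1x1 projection (496-channel dense-block-3 skip vs 504).
#'
#' @param growth_rate channels added per dense layer (K).
#' @param block_layers integer 4-tuple of dense-layer counts per block.
#' @param bottleneck_width channels of the 1x1x1 bottleneck conv.
#' @param stem_channels channels of the 7x7x7 stem conv.
#' @param compression transition-layer compression in (0, 1].
#' @param upconv_channels 5-tuple of decoder upconv widths; `NULL` derives
#'   them from the encoder bookkeeping (db4, db2, db1, stem, 64), which for
#'   the defaults is (504, 224, 192, 96, 64) as printed.
#' @param head_channels output-head channels (3 as printed; the 2-class task
#'   logits come from the fusion head or the auxiliary head).
#' @param feature_channels channels of the decoder feature output (64).
#' @return object of class `densunet3d_config`.
#' @export
densunet3d_config <- function(growth_rate = 32L,
                              block_layers = c(3L, 4L, 12L, 8L),
                              bottleneck_width = 4L * growth_rate,
                              stem_channels = 3L * growth_rate,
                              compression = 0.5,
                              upconv_channels = NULL,
                              head_channels = 3L,
                              feature_channels = 64L) {
  if (length(block_layers) != 4L) stop("densunet3d_config: need 4 dense blocks")
  if (compression <= 0 || compression > 1) {
    stop("densunet3d_config: compression must be in (0, 1]")
  }
  structure(list(growth_rate = as.integer(growth_rate),
                 block_layers = as.integer(block_layers),
                 bottleneck_width = as.integer(bottleneck_width),
                 stem_channels = as.integer(stem_channels),
                 compression = compression,
                 upconv_channels = if (!is.null(upconv_channels)) as.integer(upconv_channels),
                 head_channels = as.integer(head_channels),
                 feature_channels = as.integer(feature_channels)),
            class = "densunet3d_config")
}

#' Build a dense block
#'
#' `n_layers` bottleneck pairs (BN-ReLU-1x1x1 conv to `bottleneck` channels,
#' BN-ReLU-3x3x3 conv to `k` channels) with dense feed-forward connectivity:
#' every layer receives the concatenation of the block input and all previous
#' layer outputs, so the block emits `in_channels + n_layers * k` channels.
#'
#' @param in_channels block input channels.
#' @param n_layers number of dense layers (0 gives an identity block).
#' @param k growth rate.
#' @param bottleneck 1x1x1 bottleneck width.
#' @return a layer list for [dense_block_forward()].
#' @export
build_dense_block <- function(in_channels, n_layers, k, bottleneck = 4L * k) {
  layers <- list()
  cin <- in_channels
  for (j in seq_len(n_layers)) {
    layers[[j]] <- list(bn1 = ly_bn(cin),
                        conv1 = ly_conv(c(1L, 1L, 1L), cin, bottleneck),
                        bn2 = ly_bn(bottleneck),
                        conv2 = ly_conv(c(3L, 3L, 3L), bottleneck, k))
    cin <- cin + k
  }
  list(type = "dense_block", layers = layers,
       out_channels = as.integer(in_channels + n_layers * k))
}

#' Forward pass of a dense block
#' @param blk layer from [build_dense_block()].
#' @param x 5D tensor.
#' @param training logical.
#' @return tensor with `in_channels + n_layers * k` channels.
#' @export
dense_block_forward <- function(blk, x, training = FALSE) {
  h <- x
  for (ly in blk$layers) {
    u <- ly_fwd(ly$conv1, op_relu(ly_fwd(ly$bn1, h, training)), training)
    u <- ly_fwd(ly$conv2, op_relu(ly_fwd(ly$bn2, u, training)), training)
    h <- op_concat_c(list(h, u))
  }
  h
}

#' Build a transition layer
#'
#' BN-ReLU, a 1x1x1 convolution to `floor(compression * in_channels)`
#' channels, then 2x2x1 average pooling: spatial H and W are halved while the
#' depth axis is preserved.
#'
#' @param in_channels input channels.
#' @param compression DenseNet-BC compression in (0, 1].
#' @return a layer list for [transition_forward()].
#' @export
build_transition <- function(in_channels, compression = 0.5) {
  if (compression <= 0 || compression > 1) stop("build_transition: bad compression")
  cout <- max(1L, as.integer(floor(compression * in_channels)))
  list(type = "transition", bn = ly_bn(in_channels),
       conv = ly_conv(c(1L, 1L, 1L), in_channels, cout),
       out_channels = cout)
}

#' Forward pass of a transition layer
#' @param tr layer from [build_transition()].
#' @param x 5D tensor.
#' @param training logical.
#' @return tensor with halved H, W and preserved depth.
#' @export
transition_forward <- function(tr, x, training = FALSE) {
  h <- ly_fwd(tr$conv, op_relu(ly_fwd(tr$bn, x, training)), training)
  op_pool(h, c(2L, 2L, 1L), c(2L, 2L, 1L), type = "avg")
}

#' Construct the 3D DenseUNet
#'
#' @param cfg a [densunet3d_config()].
#' @param in_channels input channels (2 for the hybrid model: windowed CT
#'   concatenated with the 2D network's foreground probability map).
#' @return object of class `densunet3d`.
#' @export
densunet3d_new <- function(cfg = densunet3d_config(), in_channels = 2L) {
  k <- cfg$growth_rate
  stem <- list(conv = ly_conv(c(7L, 7L, 7L), in_channels, cfg$stem_channels,
                              stride = c(2L, 2L, 2L), pad = c(3L, 3L, 3L)),
               bn = ly_bn(cfg$stem_channels))
  blocks <- list(); transitions <- list()
  ch <- cfg$stem_channels
  enc_channels <- c(stem = ch)
  for (b in 1:4) {
    blocks[[b]] <- build_dense_block(ch, cfg$block_layers[b], k, cfg$bottleneck_width)
    ch <- blocks[[b]]$out_channels
    enc_channels[paste0("db", b)] <- ch
    if (b < 4L) {
      transitions[[b]] <- build_transition(ch, cfg$compression)
      ch <- transitions[[b]]$out_channels
      enc_channels[paste0("tr", b)] <- ch
    }
  }
  upc <- cfg$upconv_channels
  if (is.null(upc)) {
    upc <- c(enc_channels[["db4"]], enc_channels[["db2"]], enc_channels[["db1"]],
             enc_channels[["stem"]], cfg$feature_channels)
  }
  skip_channels <- c(enc_channels[["db3"]], enc_channels[["db2"]],
                     enc_channels[["db1"]], enc_channels[["stem"]])
  dec <- list()
  cin <- enc_channels[["db4"]]
  for (u in 1:5) {
    kernel <- if (u <= 3L) c(2L, 2L, 1L) else c(2L, 2L, 2L)
    entry <- list(up = ly_convtr(kernel, cin, upc[u]), bn = ly_bn(upc[u]))
    if (u <= 4L && skip_channels[u] != upc[u]) {
      entry$proj <- ly_conv(c(1L, 1L, 1L), skip_channels[u], upc[u])
    }
    dec[[paste0("up", u)]] <- entry
    cin <- upc[u]
  }
  structure(list(cfg = cfg, in_channels = as.integer(in_channels),
                 stem = stem, blocks = blocks, transitions = transitions,
                 dec = dec,
                 head = ly_conv(c(1L, 1L, 1L), upc[5], cfg$head_channels),
                 aux_head = ly_conv(c(1L, 1L, 1L), upc[5], 2L)),
            class = "densunet3d")
}

as_volume5 <- function(x, what) {
  if (inherits(x, "feature_stack")) {
    if (x$axes != "volume") stop(what, ": expected volume axes (H,W,D,C)")
    arr <- x$data
  } else {
    arr <- as.array(x)
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  }
  array(arr, c(dim(arr), 1L))  # add batch axis
}

#' Forward pass of the 3D DenseUNet
#'
#' Stem (7x7x7 conv, stride 2 in all axes) and 3x3x3 max pooling (stride
#' 2,2,1-padded) take 224x224x8 to 56x56x2; four dense blocks with three
#' depth-preserving transitions reach the 7x7x2 bottleneck; five upsampling
#' layers (2x2x1 upconvs, then 2x2x2 for the last two) mirror the schedule
#' back to 224x224x8, each of the first four summed with its encoder skip
#' (1x1x1-projected when channel counts differ).
#'
#' @param net a [densunet3d_new()] model.
#' @param volume_in volume-axes [feature_stack()] (H, W, D, C) or 3D/4D
#'   array; H, W must be divisible by 32 and D by 4.
#' @param training logical.
#' @param use_aux_head also return 2-class logits from the auxiliary head.
#' @return list with `features` (H, W, D, 64) and `logits` (H, W, D, head)
#'   feature stacks, internal 5D tensors `features5` / `logits5` (and
#'   `aux_logits5` when requested), and a `trace` data.frame of per-row
#'   feature sizes following the printed table's conventions (upsampling
#'   rows 1-4 list their input size, row 5 its output size).
#' @export
forward_3d <- function(net, volume_in, training = FALSE, use_aux_head = FALSE) {
  x <- as_volume5(volume_in, "forward_3d")
  d <- dim(x)
  if (d[1] %% 32L || d[2] %% 32L) stop("forward_3d: H and W must be divisible by 32")
  if (d[3] %% 4L) stop("forward_3d: D must be divisible by 4")
  tr_rows <- list()
  note <- function(name, t) {
    dd <- dim(ag_val(t))
    tr_rows[[length(tr_rows) + 1L]] <<- data.frame(
      block = name, h = dd[1], w = dd[2], d = dd[3], channels = dd[4],
      stringsAsFactors = FALSE)
  }
  note("Input", x)
  h <- op_relu(ly_fwd(net$stem$bn, ly_fwd(net$stem$conv, x, training), training))
  stem_out <- h
  note("Convolution 1", h)
  h <- op_pool(h, c(3L, 3L, 3L), c(2L, 2L, 2L), pad = c(1L, 1L, 1L), type = "max")
  note("Pooling", h)
  skips <- list()
  for (b in 1:4) {
    h <- dense_block_forward(net$blocks[[b]], h, training)
    note(paste("Dense block", b), h)
    skips[[paste0("db", b)]] <- h
    if (b < 4L) {
      h <- transition_forward(net$transitions[[b]], h, training)
      note(paste("Transition layer", b), h)
    }
  }
  skip_for <- list("db3", "db2", "db1", "stem")
  skips$stem <- stem_out
  for (u in 1:5) {
    entry <- net$dec[[paste0("up", u)]]
    pre <- h
    h <- ly_fwd(entry$up, h, training)
    if (u <= 4L) {
      # the printed table lists the input size for upsampling layers 1-4
      note(paste("Upsampling layer", u), pre)
      s <- skips[[skip_for[[u]]]]
      if (!is.null(entry$proj)) s <- ly_fwd(entry$proj, s, training)
      dh <- dim(ag_val(h)); ds <- dim(ag_val(s))
      if (!identical(dh, ds)) {
        stop(sprintf("forward_3d: shape mismatch at sum junction %d: decoder %s vs skip %s",
                     u, paste(dh, collapse = "x"), paste(ds, collapse = "x")))
      }
      h <- op_add(h, s)
      note(paste("Sum with", c("dense block 3", "dense block 2", "dense block 1",
                               "convolution 1")[u]), h)
    } else {
      note("Upsampling layer 5", h)
    }
    h <- op_relu(ly_fwd(entry$bn, h, training))
  }
  feats <- h
  logits <- ly_fwd(net$head, feats, training)
  note("Output", logits)
  out <- list(features5 = feats, logits5 = logits,
              trace = do.call(rbind, tr_rows))
  fv <- ag_val(feats); lv <- ag_val(logits)
  out$features <- feature_stack(array(fv, dim(fv)[1:4]), "volume")
  out$logits <- feature_stack(array(lv, dim(lv)[1:4]), "volume")
  if (use_aux_head) out$aux_logits5 <- ly_fwd(net$aux_head, feats, training)
  out
}

#' Per-row feature-size trace of the 3D DenseUNet
#'
#' Builds (or reuses) the network, forwards one input of the given shape in
#' inference mode and returns the per-row feature sizes in the printed
#' table's row order and conventions.
#'
#' @param net a [densunet3d_new()] model.
#' @param input_shape (H, W, D) triple, default c(224, 224, 8).
#' @return data.frame with columns block, h, w, d, channels.
#' @export
net3d_shape_trace <- function(net, input_shape = c(224L, 224L, 8L)) {
  x <- array(0, c(input_shape, net$in_channels))
  ag_no_grad(forward_3d(net, feature_stack(x, "volume"), training = FALSE))$trace
}
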