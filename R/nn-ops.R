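# Differentiable tensor operations. All volumetric activations are 5D arrays
# (H, W, D, C, N); 2D slice batches use D = 1. Each op computes its value via
# the compiled kernels (or vectorised R) and registers a backward closure on
# the active tape through ag_record().

t5 <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (length(d) > 5L) stop("tensor has more than 5 dimensions")
  array(x, c(d, rep(1L, 5L - length(d))))
}

# per-channel sum of a 5D array -> length-C vector
chsum <- function(x) rowSums(.cpp_channel_dot(x, dim(x), NULL))

# per-channel sum of an elementwise product -> length-C vector
chdot <- function(x, y) rowSums(.cpp_channel_dot(x, dim(x), y))

as_cn <- function(v, d) if (is.matrix(v)) v else matrix(v, d[4], d[5])

# broadcast a length-C (or C x N) quantity over (H,W,D,C,N)
chexpand <- function(v, d) .cpp_channel_expand(as_cn(v, d), as.integer(d))

# x * a[c] + b[c] with per-channel (or C x N) coefficients
chaffine <- function(x, a, b) {
  d <- dim(x)
  .cpp_channel_affine(x, as.integer(d), as_cn(a, d), as_cn(b, d))
}

same_pad <- function(kernel) as.integer((kernel - 1L) %/% 2L)

op_conv <- function(x, w, b, stride = c(1L, 1L, 1L), pad = NULL) {
  xv <- ag_val(x); wv <- ag_val(w); bv <- ag_val(b)
  if (is.null(pad)) pad <- same_pad(dim(wv)[1:3])
  stride <- as.integer(stride); pad <- as.integer(pad)
  y <- .cpp_conv3d_forward(xv, dim(xv), wv, dim(wv), bv, stride, pad)
  ag_record(y, list(x, w, b), function(dy) {
    gx <- if (ag_requires(x)) {
      .cpp_conv3d_backward_input(dy, dim(xv), wv, dim(wv), stride, pad)
    }
    gwb <- .cpp_conv3d_backward_weights(xv, dim(xv), dy, dim(wv), stride, pad)
    list(gx, gwb$dw, gwb$db)
  })
}

op_convtr <- function(x, w, b) {
  xv <- ag_val(x); wv <- ag_val(w); bv <- ag_val(b)
  y <- .cpp_convtr3d_forward(xv, dim(xv), wv, dim(wv), bv)
  ag_record(y, list(x, w, b), function(dy) {
    g <- .cpp_convtr3d_backward(xv, dim(xv), dy, wv, dim(wv))
    list(if (ag_requires(x)) g$dx, g$dw, g$db)
  })
}

op_pool <- function(x, kernel, stride = kernel, pad = c(0L, 0L, 0L),
                    type = c("max", "avg")) {
  type <- match.arg(type)
  ty <- if (type == "max") 0L else 1L
  xv <- ag_val(x)
  kernel <- as.integer(kernel); stride <- as.integer(stride); pad <- as.integer(pad)
  res <- .cpp_pool3d_forward(xv, dim(xv), kernel, stride, pad, ty)
  xdim <- dim(xv)
  ag_record(res$y, list(x), function(dy) {
    list(.cpp_pool3d_backward(dy, xdim, kernel, stride, pad, ty, res$argmax))
  })
}

op_relu <- function(x) {
  xv <- ag_val(x)
  y <- xv * (xv > 0)
  ag_record(y, list(x), function(dy) list(dy * (xv > 0)))
}

op_sigmoid <- function(x) {
  xv <- ag_val(x)
  y <- 1 / (1 + exp(-xv))
  ag_record(y, list(x), function(dy) list(dy * y * (1 - y)))
}

op_add <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  stopifnot(identical(dim(av), dim(bv)))
  ag_record(av + bv, list(a, b), function(dy) list(dy, dy))
}

# concatenate along the channel axis (4th dimension)
op_concat_c <- function(xs) {
  vals <- lapply(xs, ag_val)
  d0 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[4], numeric(1L))
  d <- d0; d[4] <- sum(chans)
  y <- array(0, d)
  off <- 0L
  for (v in vals) {
    y[, , , off + seq_len(dim(v)[4]), ] <- v
    off <- off + dim(v)[4]
  }
  ag_record(y, xs, function(dy) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      ci <- chans[i]
      out[[i]] <- array(dy[, , , off + seq_len(ci), ], dim(vals[[i]]))
      off <- off + ci
    }
    out
  })
}

# global average pool over (H,W,D) -> C x N matrix
op_gap <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  hwd <- prod(d[1:3])
  y <- .cpp_channel_dot(xv, as.integer(d), NULL) / hwd
  ag_record(y, list(x), function(dy) list(chexpand(dy / hwd, d)))
}

# dense layer on (Cin x N) feature matrices: y = t(W) x + b
op_linear <- function(x, w, b) {
  xv <- ag_val(x); wv <- ag_val(w); bv <- ag_val(b)
  y <- crossprod(wv, xv) + bv
  ag_record(y, list(x, w, b), function(dy) {
    list(wv %*% dy, xv %*% t(dy), rowSums(dy))
  })
}

# per-channel, per-sample rescale: gate is C x N
op_scale_channels <- function(x, gate) {
  xv <- ag_val(x); gv <- ag_val(gate)
  d <- dim(xv)
  zero <- matrix(0, d[4], d[5])
  ag_record(chaffine(xv, gv, zero), list(x, gate), function(dy) {
    list(chaffine(dy, gv, zero), .cpp_channel_dot(dy, as.integer(d), xv))
  })
}

op_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  xv <- ag_val(x)
  keep <- array((runif(length(xv)) >= rate) / (1 - rate), dim(xv))
  ag_record(xv * keep, list(x), function(dy) list(dy * keep))
}

# Batch normalisation over (H,W,D,N) per channel. `layer` is the ly_bn list
# whose $stats environment holds running_mean / running_var (updated as a side
# effect in training mode).
op_batchnorm <- function(x, gamma, beta, layer, training) {
  xv <- ag_val(x)
  d <- dim(xv)
  cnt <- prod(d[1:3]) * d[5]
  eps <- layer$eps
  st <- layer$stats
  if (training) {
    mu <- chsum(xv) / cnt
    va <- chsum(xv * xv) / cnt - mu^2
    va[va < 0] <- 0
    st$running_mean <- (1 - layer$momentum) * st$running_mean + layer$momentum * mu
    st$running_var <- (1 - layer$momentum) * st$running_var + layer$momentum * va
  } else {
    mu <- st$running_mean
    va <- st$running_var
  }
  ivar <- 1 / sqrt(va + eps)
  gv <- ag_val(gamma); bv <- ag_val(beta)
  xhat <- chaffine(xv, ivar, -mu * ivar)
  y <- chaffine(xhat, gv, bv)
  ag_record(y, list(x, gamma, beta), function(dy) {
    dgamma <- chdot(dy, xhat)
    dbeta <- chsum(dy)
    gx <- if (ag_requires(x)) {
      if (training) {
        dxhat <- chaffine(dy, gv, numeric(length(gv)))
        s1 <- chsum(dxhat)
        s2 <- chdot(dxhat, xhat)
        chaffine(dxhat, ivar, -(s1 / cnt) * ivar) -
          chaffine(xhat, (s2 / cnt) * ivar, numeric(length(gv)))
      } else {
        chaffine(dy, gv * ivar, numeric(length(gv)))
      }
    }
    list(gx, dgamma, dbeta)
  })
}

# softmax over the channel axis (plain array helper, inference side)
softmax_channels <- function(x) {
  d <- dim(x)
  xr <- array(x, c(prod(d[1:3]), d[4], d[5]))
  mx <- xr[, 1, , drop = FALSE]
  for (cc in seq_len(d[4])[-1]) mx <- pmax(mx, xr[, cc, , drop = FALSE])
  ex <- exp(xr - array(mx[, rep(1, d[4]), ], dim(xr)))
  tot <- ex[, 1, , drop = FALSE]
  for (cc in seq_len(d[4])[-1]) tot <- tot + ex[, cc, , drop = FALSE]
  array(ex / array(tot[, rep(1, d[4]), ], dim(xr)), d)
}

# Class-weighted cross-entropy on logits, fused with softmax.
# y_onehot: plain array, same 5D shape as logits; w: length-C weights.
op_wce_logits <- function(logits, y_onehot, w) {
  lv <- ag_val(logits)
  d <- dim(lv)
  n <- prod(d[1:3]) * d[5]
  p <- softmax_channels(lv)
  we <- chexpand(w, d)
  loss <- -sum(we * y_onehot * log(pmax(p, 1e-12))) / n
  ag_record(loss, list(logits), function(dy) {
    wtrue <- array(0, d[c(1:3, 5)])
    pr <- array(p, c(prod(d[1:3]), d[4], d[5]))
    yr <- array(y_onehot, c(prod(d[1:3]), d[4], d[5]))
    wt <- 0
    for (cc in seq_len(d[4])) wt <- wt + w[cc] * yr[, cc, ]
    dz <- array(0, dim(pr))
    for (cc in seq_len(d[4])) dz[, cc, ] <- wt * (pr[, cc, ] - yr[, cc, ])
    list(array(dz * dy / n, d))
  })
}
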