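# Layer constructors. A layer is a named list carrying its parameters
# (ag_tensor) and hyperparameters; ly_fwd() dispatches on $type. Weight
# initialisation is He-normal and draws from the R RNG, so set.seed() makes
# model construction reproducible.

he_init <- function(dims, fan_in) {
  nn_param(array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims))
}

ly_conv <- function(kernel, cin, cout, stride = c(1L, 1L, 1L), pad = NULL) {
  kernel <- as.integer(rep(kernel, length.out = 3L))
  list(type = "conv",
       w = he_init(c(kernel, cin, cout), prod(kernel) * cin),
       b = nn_param(numeric(cout)),
       stride = as.integer(stride),
       pad = if (is.null(pad)) same_pad(kernel) else as.integer(pad))
}

ly_convtr <- function(kernel, cin, cout) {
  kernel <- as.integer(rep(kernel, length.out = 3L))
  list(type = "convtr",
       w = he_init(c(kernel, cin, cout), prod(kernel) * cin),
       b = nn_param(numeric(cout)))
}

ly_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(channels)
  st$running_var <- rep(1, channels)
  list(type = "bn",
       gamma = nn_param(rep(1, channels)),
       beta = nn_param(numeric(channels)),
       momentum = momentum, eps = eps, stats = st)
}

ly_linear <- function(cin, cout) {
  list(type = "linear",
       w = he_init(c(cin, cout), cin),
       b = nn_param(numeric(cout)))
}

ly_fwd <- function(ly, x, training = FALSE) {
  switch(ly$type,
    conv = op_conv(x, ly$w, ly$b, ly$stride, ly$pad),
    convtr = op_convtr(x, ly$w, ly$b),
    bn = op_batchnorm(x, ly$gamma, ly$beta, ly, training),
    linear = op_linear(x, ly$w, ly$b),
    stop("unknown layer type: ", ly$type)
  )
}

#' Squeeze-and-excitation block
#'
#' Channel attention: global average pool, a two-layer bottleneck
#' (ReLU then sigmoid), and per-channel rescaling of the input. The squeeze
#' width is `max(1, ceiling(channels / reduction))`.
#'
#' @param channels number of input/output channels.
#' @param reduction bottleneck reduction ratio (default 16).
#' @return an SE layer list usable with [se_forward()].
#' @export
se_block <- function(channels, reduction = 16L) {
  hidden <- max(1L, as.integer(ceiling(channels / reduction)))
  list(type = "se",
       fc1 = ly_linear(channels, hidden),
       fc2 = ly_linear(hidden, channels))
}

#' Forward pass of a squeeze-and-excitation block
#'
#' @param se layer from [se_block()].
#' @param x 5D activation array (H, W, D, C, N) or `ag_tensor`.
#' @param training unused; present for interface symmetry.
#' @return the gated activation, same shape as `x`.
#' @export
se_forward <- function(se, x, training = FALSE) {
  s <- op_gap(x)
  s <- op_relu(ly_fwd(se$fc1, s))
  gate <- op_sigmoid(ly_fwd(se$fc2, s))
  op_scale_channels(x, gate)
}

# ---- optimiser ----

#' Stochastic gradient descent with momentum and weight decay
#'
#' Defaults follow the training recipe used throughout the package:
#' learning rate 0.008, weight decay 0.00005, momentum 0.9.
#'
#' @param params flat list of `ag_tensor` parameters (see `collect_params`).
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @return an optimiser object for [sgd_step()].
#' @export
sgd_new <- function(params, lr = 0.008, momentum = 0.9, weight_decay = 5e-5) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$vel <- lapply(params, function(p) 0)
  e$lr <- lr; e$momentum <- momentum; e$wd <- weight_decay
  class(e) <- "vseg_sgd"
  e
}

#' Apply one SGD update and clear gradients
#' @param opt optimiser from [sgd_new()].
#' @export
sgd_step <- function(opt) {
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    v <- opt$momentum * opt$vel[[i]] - opt$lr * (p$grad + opt$wd * p$value)
    opt$vel[[i]] <- v
    p$value <- p$value + v
    p$grad <- NULL
  }
  invisible(opt)
}

# ---- state (de)serialisation ----

# Extract all parameter values and BN running stats as a nested plain list.
net_state <- function(x) {
  if (is_ag(x)) return(x$value)
  if (is.list(x)) {
    st <- lapply(x, net_state)
    if (!is.null(x$type) && x$type == "bn") {
      st$stats <- list(running_mean = x$stats$running_mean,
                       running_var = x$stats$running_var)
    }
    return(st)
  }
  x
}

# Load a state produced by net_state() back into a structurally identical net.
net_load_state <- function(x, state) {
  if (is_ag(x)) {
    stopifnot(length(x$value) == length(state))
    x$value <- if (is.null(dim(x$value))) as.numeric(state) else
      array(as.numeric(state), dim(x$value))
    return(invisible(x))
  }
  if (is.list(x)) {
    if (!is.null(x$type) && x$type == "bn") {
      x$stats$running_mean <- state$stats$running_mean
      x$stats$running_var <- state$stats$running_var
    }
    nms <- names(x)
    for (i in seq_along(x)) {
      if (!is.null(nms) && identical(nms[i], "stats")) next
      if (is_ag(x[[i]]) || is.list(x[[i]])) net_load_state(x[[i]], state[[i]])
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
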