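# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (triple loops, all-pairs distances) and
# independent of the package's implementation paths.

# Dice by direct voxel counting
bf_dsc <- function(a, b) {
  a <- as.array(a); b <- as.array(b)
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    inter <- inter + (a[i] == 1 && b[i] == 1)
    sa <- sa + (a[i] == 1); sb <- sb + (b[i] == 1)
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

# surface voxels by exhaustive 6-neighbour check
bf_surface <- function(m) {
  m <- as.array(m)
  d <- dim(m)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (m[i, j, k] != 1) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
      if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
      if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
    if (any(nb == 0)) out <- rbind(out, c(i, j, k))
  }
  if (is.null(out)) matrix(numeric(0), 0, 3) else out
}

bf_directed_means <- function(a, b, spacing) {
  sa <- sweep(bf_surface(a), 2, spacing, "*")
  sb <- sweep(bf_surface(b), 2, spacing, "*")
  dmin <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i) {
      min(sqrt(colSums((t(q) - p[i, ])^2)))
    }, numeric(1))
  }
  list(ab = dmin(sa, sb), ba = dmin(sb, sa))
}

bf_asd <- function(a, b, spacing) {
  d <- bf_directed_means(a, b, spacing)
  (sum(d$ab) + sum(d$ba)) / (length(d$ab) + length(d$ba))
}

bf_avd <- function(a, b, spacing) {
  d <- bf_directed_means(a, b, spacing)
  max(mean(d$ab), mean(d$ba))
}

bf_hausdorff <- function(a, b, spacing) {
  d <- bf_directed_means(a, b, spacing)
  max(max(d$ab), max(d$ba))
}

# plain unweighted cross-entropy, double loop
bf_cross_entropy <- function(y, y_pred, w = c(1, 1)) {
  tot <- 0
  for (i in seq_len(nrow(y))) for (cc in seq_len(ncol(y))) {
    tot <- tot - w[cc] * y[i, cc] * log(max(y_pred[i, cc], 1e-12))
  }
  tot / nrow(y)
}

# random blobby mask (a few random boxes/balls) within a small grid
random_small_mask <- function(d = c(10L, 10L, 6L), p_empty = 0) {
  if (runif(1) < p_empty) return(array(0L, d))
  m <- array(0L, d)
  for (s in seq_len(sample(1:2, 1))) {
    ctr <- sapply(d, function(n) runif(1, 1, n))
    r <- runif(1, 1, 3)
    g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
    inside <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2 <= r^2
    m[as.matrix(g)[inside, , drop = FALSE]] <- 1L
  }
  m
}

# in-memory phantom cases for training smoke tests
make_cases <- function(n, seed_base, split = rep("train", n),
                       spec = phantom_spec()) {
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- seed_base + i
    ph <- generate_phantom(sp)
    list(case_id = sprintf("case_%02d", i), volume = ph$volume, mask = ph$mask,
         split = split[i])
  })
}

# reduced network configurations used by the trainability smoke tests
tiny2d_cfg <- function() {
  net2d_config(channels = c(8L, 16L, 24L, 32L, 32L), se_reduction = 4L)
}
tiny3d_cfg <- function(stem = NULL) {
  if (is.null(stem)) {
    densunet3d_config(growth_rate = 4L, block_layers = c(1L, 1L, 2L, 1L))
  } else {
    densunet3d_config(growth_rate = 4L, block_layers = c(1L, 1L, 2L, 1L),
                      stem_channels = stem)
  }
}

# finite-difference gradient check of a scalar-valued op composition:
# loss = sum(f(args) * probe). Returns max abs deviation over sampled entries.
fd_gradcheck <- function(f, args, wrt, n_probe = 12L, eps = 1e-5) {
  probe <- NULL
  loss_of <- function(a) {
    y <- do.call(f, a)
    v <- if (inherits(y, "ag_tensor")) y$value else y
    if (is.null(probe)) probe <<- array(rnorm(length(v)), dim(v) %||% length(v))
    sum(v * probe)
  }
  loss_of(args)
  ag <- asNamespace("vestibuleseg")
  ag$ag_tape_start()
  args2 <- args
  for (nm in wrt) args2[[nm]] <- ag$ag_tensor(args[[nm]], TRUE)
  y <- do.call(f, args2)
  node <- ag$ag_record(sum(y$value * probe), list(y), function(dy) list(dy * probe))
  ag$ag_backward(node)
  worst <- 0
  for (nm in wrt) {
    g <- args2[[nm]]$grad
    v <- as.array(args[[nm]])
    for (ii in sample(length(v), min(n_probe, length(v)))) {
      a <- args
      vp <- v; vp[ii] <- vp[ii] + eps
      a[[nm]] <- if (is.null(dim(v))) as.numeric(vp) else array(vp, dim(v))
      lp <- loss_of(a)
      vm <- v; vm[ii] <- vm[ii] - eps
      a[[nm]] <- if (is.null(dim(v))) as.numeric(vm) else array(vm, dim(v))
      lm <- loss_of(a)
      worst <- max(worst, abs((lp - lm) / (2 * eps) - g[ii]))
    }
  }
  worst
}

`%||%` <- function(a, b) if (is.null(a)) b else a
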