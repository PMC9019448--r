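# Synthetic CT phantoms emulating the vestibule regime: a tiny (< 1% of
# voxels) ellipsoidal structure with blurred boundaries, embedded in a
# homogeneous background with additive noise. Labels always come from the
# noise-free geometry.

#' Specification of a synthetic CT phantom
#'
#' The defaults describe the regime the package targets: a small fluid-filled
#' structure (around 100 HU) inside dense temporal bone (around 1900 HU),
#' boundary softened by the scanner point-spread function, mild noise, and a
#' foreground occupancy well below 1% of voxels.
#'
#' @param volume_shape integer triple (H, W, D) of voxels.
#' @param voxel_spacing mm triple.
#' @param n_structures number of ellipsoids (>= 1); they may overlap.
#' @param radii_range mm pair (min, max) for ellipsoid semi-axes.
#' @param foreground_hu intensity inside the structure.
#' @param background_hu intensity elsewhere.
#' @param blur_sigma Gaussian blur, in voxels (>= 0).
#' @param noise_sigma additive Gaussian noise, intensity units (>= 0).
#' @param seed integer; the same spec always produces bit-identical output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 16L),
                         voxel_spacing = c(0.25, 0.25, 0.5),
                         n_structures = 1L,
                         radii_range = c(0.8, 1.6),
                         foreground_hu = 100,
                         background_hu = 1900,
                         blur_sigma = 0.7,
                         noise_sigma = 40,
                         seed = 1L) {
  spec <- structure(list(volume_shape = as.integer(volume_shape),
                         voxel_spacing = as.numeric(voxel_spacing),
                         n_structures = as.integer(n_structures),
                         radii_range = as.numeric(radii_range),
                         foreground_hu = foreground_hu,
                         background_hu = background_hu,
                         blur_sigma = blur_sigma,
                         noise_sigma = noise_sigma,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$volume_shape <= 0)) stop("phantom_spec: volume_shape must be positive")
  if (any(spec$voxel_spacing <= 0)) stop("phantom_spec: voxel_spacing must be positive")
  if (spec$n_structures < 1L) stop("phantom_spec: n_structures must be >= 1")
  if (spec$radii_range[1] <= 0 || diff(spec$radii_range) < 0) {
    stop("phantom_spec: radii_range must be an increasing positive pair")
  }
  if (spec$blur_sigma < 0 || spec$noise_sigma < 0) {
    stop("phantom_spec: blur_sigma and noise_sigma must be >= 0")
  }
  # expected foreground fraction bound: worst case every structure is a ball
  # of the maximum radius and none overlap
  vol_mm3 <- prod(spec$volume_shape) * prod(spec$voxel_spacing)
  max_fg <- spec$n_structures * 4 / 3 * pi * spec$radii_range[2]^3
  if (max_fg / vol_mm3 >= 0.01) {
    stop("phantom_spec: radii too large; worst-case foreground fraction ",
         sprintf("%.2f%%", 100 * max_fg / vol_mm3), " must stay below 1%")
  }
  invisible(spec)
}

# Rasterize one ellipsoid at voxel centres: voxel (i,j,k) is foreground iff
# its centre ((i-0.5)*sp, ...) satisfies |diag(1/semiaxes) R^T (x - center)| <= 1.
rasterize_ellipsoid <- function(shape, spacing, center, semiaxes,
                                rotation = diag(3)) {
  mask <- array(0L, shape)
  centers <- lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * spacing[a])
  half <- sqrt(rowSums((rotation %*% diag(semiaxes))^2))
  box <- lapply(1:3, function(a) {
    which(centers[[a]] >= center[a] - half[a] - spacing[a] &
            centers[[a]] <= center[a] + half[a] + spacing[a])
  })
  if (any(lengths(box) == 0)) return(mask)
  g <- as.matrix(expand.grid(centers[[1]][box[[1]]], centers[[2]][box[[2]]],
                             centers[[3]][box[[3]]]))
  local_ <- sweep(g, 2, center) %*% rotation  # rotate into the ellipsoid frame
  inside <- rowSums(sweep(local_, 2, semiaxes, "/")^2) <= 1
  gi <- as.matrix(expand.grid(box[[1]], box[[2]], box[[3]]))[inside, , drop = FALSE]
  mask[gi] <- 1L
  mask
}

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# separable Gaussian blur with replicate edge handling
gaussian_blur3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (axis in 1:3) {
    if (d[axis] == 1L) next
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    x <- aperm(arr, perm)
    dm <- dim(x)
    m <- matrix(x, nrow = dm[1])
    pad_idx <- c(rep(1L, r), seq_len(dm[1]), rep(dm[1], r))
    mp <- m[pad_idx, , drop = FALSE]
    out <- matrix(0, dm[1], ncol(m))
    for (t in seq_along(k)) {
      out <- out + k[t] * mp[(t - 1L) + seq_len(dm[1]), , drop = FALSE]
    }
    arr <- aperm(array(out, dm), order(perm))
  }
  arr
}

#' Generate a synthetic CT volume and its ground-truth mask
#'
#' Ellipsoids with random centres, semi-axes and orientations are rasterized
#' at voxel centres (a voxel is foreground iff its centre satisfies the
#' ellipsoid inequality). The intensity image is
#' `background + (foreground - background) * mask`, Gaussian-blurred by
#' `blur_sigma` and corrupted with additive Gaussian noise; the mask is the
#' pre-blur, noise-free geometry. Structures are rejection-sampled to lie
#' fully inside the volume.
#'
#' @param spec a [phantom_spec()].
#' @param max_retries retry limit per structure before erroring.
#' @return `list(volume = ct_volume, mask = label_mask)`.
#' @export
generate_phantom <- function(spec, max_retries = 100L) {
  validate_phantom_spec(spec)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(spec$seed)
  d <- spec$volume_shape
  sp <- spec$voxel_spacing
  extent <- d * sp
  mask <- array(0L, d)
  for (s in seq_len(spec$n_structures)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      ax <- runif(3, spec$radii_range[1], spec$radii_range[2])
      rot <- random_rotation()
      # half-extent of the rotated ellipsoid along each world axis
      half <- sqrt(rowSums((rot %*% diag(ax))^2))
      if (any(2 * half >= extent)) next
      ctr <- runif(3, half, extent - half)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("generate_phantom: could not place structure ", s,
           " inside the volume after ", max_retries, " attempts")
    }
    mask <- mask | rasterize_ellipsoid(d, sp, ctr, ax, rot)
    storage.mode(mask) <- "integer"
  }
  img <- spec$background_hu + (spec$foreground_hu - spec$background_hu) * mask
  img <- gaussian_blur3d(img, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    img <- img + array(rnorm(prod(d), sd = spec$noise_sigma), d)
  }
  list(volume = ct_volume(img, sp), mask = label_mask(mask, sp))
}

# largest-remainder apportionment of n cases to split fractions
split_counts <- function(n, split) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  raw <- n * split
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_ <- order(raw - counts, decreasing = TRUE)
    counts[order_[seq_len(rem)]] <- counts[order_[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Generate a phantom dataset on disk with a train/val/test manifest
#'
#' Writes `n_cases` volume/mask NIfTI pairs and a `manifest.csv` assigning
#' each case to a split. Per-case seeds are derived deterministically from
#' the template seed, and split sizes use largest-remainder rounding.
#'
#' @param n_cases number of cases (>= 3).
#' @param spec_template a [phantom_spec()]; its seed seeds the whole dataset.
#' @param split fractions (train, val, test) summing to 1.
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data.frame (case_id, volume, mask, split),
#'   invisibly also written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_cases, spec_template,
                             split = c(0.8, 0.1, 0.1), out_dir) {
  if (n_cases < 3) stop("generate_dataset: n_cases must be >= 3")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("generate_dataset: cannot create ", out_dir)
  counts <- split_counts(n_cases, split)
  assignment <- rep(c("train", "val", "test"), counts)
  manifest <- data.frame(case_id = sprintf("case_%03d", seq_len(n_cases)),
                         volume = character(n_cases), mask = character(n_cases),
                         split = assignment, stringsAsFactors = FALSE)
  for (i in seq_len(n_cases)) {
    spec_i <- spec_template
    spec_i$seed <- spec_template$seed + i * 9973L
    ph <- generate_phantom(spec_i)
    vpath <- file.path(out_dir, sprintf("%s_ct.nii.gz", manifest$case_id[i]))
    mpath <- file.path(out_dir, sprintf("%s_mask.nii.gz", manifest$case_id[i]))
    write_volume(ph$volume, vpath)
    write_volume(ph$mask, mpath)
    manifest$volume[i] <- vpath
    manifest$mask[i] <- mpath
  }
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset manifest into memory
#'
#' @param manifest path to a `manifest.csv` written by [generate_dataset()],
#'   or the manifest data.frame itself.
#' @return list of cases `list(case_id, volume, mask, split)` with volumes
#'   and masks loaded.
#' @export
load_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    list(case_id = manifest$case_id[i],
         volume = read_volume(manifest$volume[i], "volume"),
         mask = read_volume(manifest$mask[i], "mask"),
         split = manifest$split[i])
  })
}
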