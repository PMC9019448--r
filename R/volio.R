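# Volume containers, NIfTI I/O, Hounsfield windowing, patch tiling, the
# f / f-inverse volume<->slice conversions, and paired geometric augmentation.

#' CT volume container
#'
#' A 3D intensity array plus voxel spacing (mm) and a normalisation flag.
#'
#' @param data numeric 3D array (H, W, D), in HU unless `normalized`.
#' @param spacing positive mm triple (row, column, slice).
#' @param normalized has [window_normalize()] already been applied?
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), normalized = FALSE) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("ct_volume: data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("ct_volume: spacing must be a positive mm triple")
  }
  structure(list(data = data, spacing = spacing, normalized = isTRUE(normalized)),
            class = "ct_volume")
}

#' Binary label mask co-registered with a CT volume
#'
#' @param labels integer 3D array with values in {0, 1}.
#' @param spacing positive mm triple.
#' @return object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing = c(1, 1, 1)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("label_mask: labels must be a 3D array")
  if (!all(labels %in% c(0L, 1L))) stop("label_mask: labels must be 0/1")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("label_mask: spacing must be a positive mm triple")
  }
  structure(list(labels = labels, spacing = spacing), class = "label_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              if (x$normalized) "normalized [0,1]" else "HU"))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s voxels, %d foreground (%.3f%%)\n",
              paste(dim(x$labels), collapse = "x"),
              sum(x$labels), 100 * mean(x$labels)))
  invisible(x)
}

mask_array <- function(m) {
  if (inherits(m, "label_mask")) m$labels else as.array(m)
}

#' Read a CT volume or mask from a NIfTI file
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param as one of "volume" (returns [ct_volume()]) or "mask"
#'   (returns [label_mask()]; values must be within 1e-6 of 0/1).
#' @return `ct_volume` or `label_mask`.
#' @export
read_volume <- function(path, as = c("volume", "mask")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop NIfTI header attributes
  if (length(dim(arr)) != 3L) {
    stop("read_volume: expected a 3D image in ", path, " but found ",
         length(dim(arr)), " dimensions")
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (as == "mask") {
    lab <- round(arr)
    if (max(abs(arr - lab)) > 1e-6 || !all(lab %in% c(0, 1))) {
      stop("read_volume: ", path, " is not a binary mask (values beyond 0/1)")
    }
    label_mask(lab, spacing)
  } else {
    ct_volume(arr, spacing)
  }
}

#' Write a CT volume or mask to a NIfTI file
#'
#' Spacing is stored in the header so a read/write cycle is lossless.
#'
#' @param x `ct_volume` or `label_mask`.
#' @param path destination path (`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_volume: directory does not exist: ", dir)
  if (inherits(x, "label_mask")) {
    arr <- x$labels
    spacing <- x$spacing
  } else if (inherits(x, "ct_volume")) {
    arr <- x$data
    spacing <- x$spacing
  } else {
    stop("write_volume: x must be a ct_volume or label_mask")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Hounsfield windowing and [0, 1] normalisation
#'
#' Clips intensities to `[level - width/2, level + width/2]` and maps the
#' window linearly to `[0, 1]`. The defaults are the temporal-bone window
#' (width 4000 HU, level 700 HU).
#'
#' @param vol a non-normalized [ct_volume()].
#' @param width window width in HU (> 0).
#' @param level window level (centre) in HU.
#' @return normalized `ct_volume`.
#' @export
window_normalize <- function(vol, width = 4000, level = 700) {
  stopifnot(inherits(vol, "ct_volume"))
  if (width <= 0) stop("window_normalize: width must be positive")
  if (vol$normalized) {
    stop("window_normalize: volume is already normalized (double-normalization guard)")
  }
  lo <- level - width / 2
  x <- pmin(pmax(vol$data, lo), level + width / 2)
  ct_volume((x - lo) / width, vol$spacing, normalized = TRUE)
}

# start offsets tiling `len` with windows of `size` and the given stride;
# a final offset is appended so the last window touches the end.
tile_starts <- function(len, size, stride) {
  if (size >= len) return(0L)
  s <- seq.int(0L, len - size, by = stride)
  if (s[length(s)] + size < len) s <- c(s, len - size)
  as.integer(s)
}

pad_to <- function(arr, target) {
  d <- dim(arr)
  if (all(d >= target)) return(arr)
  pads <- pmax(target - d, 0L)
  lo <- pads %/% 2L
  out_d <- pmax(d, target)
  # symmetric (reflect-style replicate) padding via index clamping
  idx <- lapply(1:3, function(a) {
    i <- seq_len(out_d[a]) - lo[a]
    pmin(pmax(i, 1L), d[a])
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Tile a volume (and optional mask) into fixed-size patches
#'
#' Patches tile the volume with the given stride; the final patch along each
#' axis is shifted so the volume edge is covered, and volumes smaller than the
#' patch are symmetrically padded. Origins (0-based voxel offsets into the
#' padded volume) are recorded for reassembly.
#'
#' @param vol [ct_volume()].
#' @param mask optional [label_mask()] with the same shape.
#' @param patch_shape integer triple, default `c(224, 224, 8)`.
#' @param stride integer triple of positive strides, default `patch_shape`.
#' @return list of entries `list(patch, patch_mask, origin)`; `patch` and
#'   `patch_mask` are 3D arrays.
#' @export
extract_patches <- function(vol, mask = NULL, patch_shape = c(224L, 224L, 8L),
                            stride = patch_shape) {
  stopifnot(inherits(vol, "ct_volume"))
  stride <- as.integer(stride)
  patch_shape <- as.integer(patch_shape)
  if (any(stride <= 0)) stop("extract_patches: stride must be positive")
  arr <- pad_to(vol$data, patch_shape)
  marr <- if (!is.null(mask)) pad_to(mask_array(mask), patch_shape)
  d <- dim(arr)
  starts <- list(tile_starts(d[1], patch_shape[1], stride[1]),
                 tile_starts(d[2], patch_shape[2], stride[2]),
                 tile_starts(d[3], patch_shape[3], stride[3]))
  out <- list()
  for (k in starts[[3]]) for (j in starts[[2]]) for (i in starts[[1]]) {
    sel <- list(i + seq_len(patch_shape[1]), j + seq_len(patch_shape[2]),
                k + seq_len(patch_shape[3]))
    out[[length(out) + 1L]] <- list(
      patch = arr[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
      patch_mask = if (!is.null(marr)) marr[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
      origin = c(i, j, k))
  }
  out
}

# Overlap-average per-voxel fields (e.g. probabilities) from patches back
# into a volume of shape `vol_shape`.
reassemble_patches <- function(patches, fields, vol_shape) {
  acc <- array(0, vol_shape)
  cnt <- array(0, vol_shape)
  for (i in seq_along(patches)) {
    o <- patches[[i]]$origin
    f <- fields[[i]]
    d <- dim(f)
    sel <- list(o[1] + seq_len(d[1]), o[2] + seq_len(d[2]), o[3] + seq_len(d[3]))
    acc[sel[[1]], sel[[2]], sel[[3]]] <- acc[sel[[1]], sel[[2]], sel[[3]]] + f
    cnt[sel[[1]], sel[[2]], sel[[3]]] <- cnt[sel[[1]], sel[[2]], sel[[3]]] + 1
  }
  if (any(cnt == 0)) stop("reassemble_patches: patches do not cover the volume")
  acc / cnt
}

#' Tagged 4D feature tensor
#'
#' Axis conventions: `"volume"` is (H, W, D, C); `"slices"` is (N, H, W, C)
#' with the slice index first. Conversions between the two go through
#' [f_volume_to_slices()] and [f_inverse_slices_to_volume()] only.
#'
#' @param data 4D numeric array.
#' @param axes `"volume"` or `"slices"`.
#' @return object of class `feature_stack`.
#' @export
feature_stack <- function(data, axes = c("volume", "slices")) {
  axes <- match.arg(axes)
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("feature_stack: data must be 4D")
  structure(list(data = data, axes = axes), class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack:%s> %s\n", x$axes, paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Convert a feature volume to a stack of 2D slices (f)
#'
#' Pure axis reordering: slice k of the output is the depth-k plane of the
#' input; `(H, W, D, C)` becomes `(D, H, W, C)`.
#'
#' @param x `feature_stack` with volume axes.
#' @return `feature_stack` with slices axes.
#' @export
f_volume_to_slices <- function(x) {
  stopifnot(inherits(x, "feature_stack"))
  if (x$axes != "volume") stop("f_volume_to_slices: input must have volume axes")
  feature_stack(aperm(x$data, c(3, 1, 2, 4)), "slices")
}

#' Convert a stack of 2D slices back to a feature volume (f-inverse)
#'
#' Inverse of [f_volume_to_slices()]: `(D, H, W, C)` becomes `(H, W, D, C)`.
#'
#' @param x `feature_stack` with slices axes.
#' @return `feature_stack` with volume axes.
#' @export
f_inverse_slices_to_volume <- function(x) {
  stopifnot(inherits(x, "feature_stack"))
  if (x$axes != "slices") stop("f_inverse_slices_to_volume: input must have slices axes")
  feature_stack(aperm(x$data, c(2, 3, 1, 4)), "volume")
}

# trilinear (linear) or nearest resample of `arr` at source coordinates that
# zoom by `scale` about the array centre, output shape preserved
zoom3d <- function(arr, scale, nearest = FALSE) {
  d <- dim(arr)
  ctr <- (d + 1) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  src <- cbind(ctr[1] + (g$i - ctr[1]) / scale,
               ctr[2] + (g$j - ctr[2]) / scale,
               ctr[3] + (g$k - ctr[3]) / scale)
  if (nearest) {
    idx <- round(src)
    valid <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
      idx[, 3] >= 1 & idx[, 3] <= d[3]
    out <- numeric(nrow(src))
    ii <- pmin(pmax(idx, 1), matrix(d, nrow(idx), 3, byrow = TRUE))
    out <- arr[cbind(ii[, 1], ii[, 2], ii[, 3])]
    out[!valid] <- 0
    return(array(out, d))
  }
  f0 <- pmin(pmax(floor(src), 1), matrix(d, nrow(src), 3, byrow = TRUE))
  f1 <- pmin(f0 + 1, matrix(d, nrow(src), 3, byrow = TRUE))
  t <- pmin(pmax(src - f0, 0), 1)
  out <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ii <- cbind(if (a) f1[, 1] else f0[, 1],
                if (b) f1[, 2] else f0[, 2],
                if (cc) f1[, 3] else f0[, 3])
    wgt <- (if (a) t[, 1] else 1 - t[, 1]) *
      (if (b) t[, 2] else 1 - t[, 2]) *
      (if (cc) t[, 3] else 1 - t[, 3])
    out <- out + wgt * arr[ii]
  }
  outside <- src[, 1] < 1 | src[, 1] > d[1] | src[, 2] < 1 | src[, 2] > d[2] |
    src[, 3] < 1 | src[, 3] > d[3]
  out[outside] <- 0
  array(out, d)
}

#' Paired geometric augmentation of a patch and its mask
#'
#' Applies the same random isotropic scaling (drawn from `scale_range`) and
#' per-axis random flips to both arrays; intensities are interpolated
#' linearly, labels by nearest neighbour, and the output keeps the input
#' shape. The default scale range 0.8-1.2 matches the training recipe.
#'
#' @param patch 3D intensity array.
#' @param patch_mask 3D 0/1 array of the same shape.
#' @param scale_range length-2 range for the scale factor; every admissible
#'   factor must lie inside (0.5, 2).
#' @param flip logical length-3: is a random flip allowed along each axis
#'   (each applied with probability 0.5)?
#' @param seed optional integer seed for a self-contained draw.
#' @return `list(patch, patch_mask)` after identical transforms.
#' @export
augment <- function(patch, patch_mask, scale_range = c(0.8, 1.2),
                    flip = c(TRUE, TRUE, TRUE), seed = NULL) {
  if (!identical(dim(patch), dim(patch_mask))) {
    stop("augment: patch and mask shapes differ")
  }
  if (any(scale_range <= 0.5) || any(scale_range >= 2)) {
    stop("augment: scale_range must lie within (0.5, 2)")
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  s <- runif(1, scale_range[1], scale_range[2])
  do_flip <- rep(FALSE, 3)
  do_flip[flip] <- runif(sum(flip)) < 0.5
  p <- patch
  m <- patch_mask
  if (abs(s - 1) > 1e-12) {
    p <- zoom3d(p, s, nearest = FALSE)
    m <- zoom3d(m, s, nearest = TRUE)
  }
  for (a in which(do_flip)) {
    idx <- rev(seq_len(dim(p)[a]))
    if (a == 1) { p <- p[idx, , , drop = FALSE]; m <- m[idx, , , drop = FALSE] }
    if (a == 2) { p <- p[, idx, , drop = FALSE]; m <- m[, idx, , drop = FALSE] }
    if (a == 3) { p <- p[, , idx, drop = FALSE]; m <- m[, , idx, drop = FALSE] }
  }
  list(patch = p, patch_mask = array(as.integer(round(m)), dim(m)))
}
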