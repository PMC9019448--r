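test_that("NIfTI round trip preserves data and anisotropic spacing", {
  ph <- generate_phantom(phantom_spec(volume_shape = c(24L, 24L, 10L),
                                      voxel_spacing = c(0.1, 0.1, 0.625),
                                      radii_range = c(0.2, 0.4), seed = 5L))
  dir <- withr::local_tempdir()
  vpath <- file.path(dir, "vol.nii.gz")
  write_volume(ph$volume, vpath)
  back <- read_volume(vpath)
  expect_identical(back$data, ph$volume$data)
  expect_equal(back$spacing, c(0.1, 0.1, 0.625), tolerance = 1e-6)
  mpath <- file.path(dir, "mask.nii.gz")
  write_volume(ph$mask, mpath)
  mback <- read_volume(mpath, "mask")
  expect_identical(mback$labels, ph$mask$labels)
  expect_error(read_volume(file.path(dir, "missing.nii.gz")), "no such file")
})

test_that("float-valued masks are cast to integers within tolerance", {
  dir <- withr::local_tempdir()
  m <- array(c(0, 1, 1, 0, 0, 1, 0, 0), c(2, 2, 2))
  write_volume(ct_volume(m + 1e-8, c(1, 1, 1)), file.path(dir, "f.nii.gz"))
  got <- read_volume(file.path(dir, "f.nii.gz"), "mask")
  expect_identical(got$labels, array(as.integer(m), dim(m)))
  write_volume(ct_volume(m + 0.2, c(1, 1, 1)), file.path(dir, "bad.nii.gz"))
  expect_error(read_volume(file.path(dir, "bad.nii.gz"), "mask"), "binary")
})

test_that("windowing clips, rescales and guards against double application", {
  vol <- ct_volume(array(c(-1500, -1300, 700, 2700, 5000, 0), c(1, 2, 3)))
  norm <- window_normalize(vol, 4000, 700)
  expect_equal(as.vector(norm$data)[1:5], c(0, 0, 0.5, 1, 1))
  expect_equal(norm$data[1, 2, 3], (0 + 1300) / 4000)
  expect_true(norm$normalized)
  expect_error(window_normalize(norm), "already normalized")
  expect_error(window_normalize(vol, width = 0), "positive")
  # monotone non-decreasing in input intensity
  x <- sort(runif(50, -3000, 5000))
  y <- window_normalize(ct_volume(array(x, c(50, 1, 1))))$data
  expect_true(all(diff(as.vector(y)) >= 0))
})

test_that("patch tiling covers the volume and reassembly is exact on constants", {
  vol <- ct_volume(array(7, c(224, 224, 16)))
  one <- extract_patches(ct_volume(array(1, c(224, 224, 8))),
                         patch_shape = c(224L, 224L, 8L))
  expect_length(one, 1L)
  expect_equal(one[[1]]$origin, c(0L, 0L, 0L))
  two <- extract_patches(vol, patch_shape = c(224L, 224L, 8L),
                         stride = c(224L, 224L, 8L))
  expect_length(two, 2L)
  expect_error(extract_patches(vol, stride = c(0L, 1L, 1L)), "stride")
  # overlapping tiling of a constant volume reassembles exactly
  small <- ct_volume(array(3.5, c(48, 48, 12)))
  patches <- extract_patches(small, patch_shape = c(32L, 32L, 8L),
                             stride = c(16L, 16L, 4L))
  rec <- vestibuleseg:::reassemble_patches(
    patches, lapply(patches, `[[`, "patch"), dim(small$data))
  expect_equal(rec, small$data)
  # a paired mask is cropped identically
  ph <- generate_phantom(phantom_spec(seed = 31L))
  pm <- extract_patches(ph$volume, ph$mask, patch_shape = c(32L, 32L, 8L),
                        stride = c(32L, 32L, 8L))
  expect_true(all(vapply(pm, function(p) identical(dim(p$patch), dim(p$patch_mask)),
                         logical(1))))
  expect_equal(sum(vapply(pm, function(p) sum(p$patch_mask), numeric(1))),
               sum(ph$mask$labels))
})

test_that("f and f-inverse are mutually inverse axis reorderings", {
  # the printed conversion: an 8-slice stack of 224x224x64 features becomes
  # a 224x224x8x64 volume
  x <- feature_stack(array(rnorm(8 * 224 * 224 * 2), c(8, 224, 224, 2)), "slices")
  v <- f_inverse_slices_to_volume(x)
  expect_equal(dim(v$data), c(224, 224, 8, 2))
  expect_equal(v$axes, "volume")
  # slice k of f(x) is the depth-k plane of x
  set.seed(10)
  vol <- feature_stack(array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3)), "volume")
  sl <- f_volume_to_slices(vol)
  for (k in 1:4) expect_equal(sl$data[k, , , ], vol$data[, , k, ])
  # property: f-inverse(f(x)) == x over random shapes
  for (i in 1:100) {
    d <- c(sample(2:7, 3, replace = TRUE), sample(1:4, 1))
    a <- feature_stack(array(rnorm(prod(d)), d), "volume")
    expect_identical(f_inverse_slices_to_volume(f_volume_to_slices(a))$data, a$data)
  }
  expect_error(f_volume_to_slices(sl), "volume axes")
  expect_error(f_inverse_slices_to_volume(vol), "slices axes")
})

test_that("augmentation applies identical transforms to patch and mask", {
  ph <- generate_phantom(phantom_spec(seed = 21L))
  p <- ph$volume$data
  m <- ph$mask$labels
  # fixed scale 1, flips disabled: identity
  a <- augment(p, m, scale_range = c(1, 1), flip = c(FALSE, FALSE, FALSE))
  expect_equal(a$patch, p)
  expect_identical(a$patch_mask, m)
  # same seed twice: deterministic
  a1 <- augment(p, m, seed = 42L)
  a2 <- augment(p, m, seed = 42L)
  expect_identical(a1$patch, a2$patch)
  expect_identical(a1$patch_mask, a2$patch_mask)
  # flips are involutions: applying the same flip-only transform twice
  # returns the original
  b1 <- augment(p, m, scale_range = c(1, 1), seed = 7L)
  b2 <- augment(b1$patch, b1$patch_mask, scale_range = c(1, 1), seed = 7L)
  expect_equal(b2$patch, p)
  expect_identical(b2$patch_mask, m)
  # labels stay binary under arbitrary augmentation
  for (s in 1:5) {
    aa <- augment(p, m, seed = s)
    expect_true(all(aa$patch_mask %in% c(0L, 1L)))
    expect_identical(dim(aa$patch), dim(p))
  }
  expect_error(augment(p, m, scale_range = c(0.4, 1.2)), "within")
  expect_error(augment(p, m[1:10, , ]), "shapes differ")
})

test_that("upscaling a centred cube grows its volume by about scale cubed", {
  d <- c(24L, 24L, 24L)
  m <- array(0L, d)
  m[9:16, 9:16, 9:16] <- 1L  # 8^3 cube
  z <- vestibuleseg:::zoom3d(m, 1.2, nearest = TRUE)
  ratio <- sum(z) / sum(m)
  expect_gt(ratio, 1.2^3 * 0.85)
  expect_lt(ratio, 1.2^3 * 1.15)
})
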