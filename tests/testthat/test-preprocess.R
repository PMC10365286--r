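test_that("HU windowing maps the window endpoints and clips", {
  vol <- ct_volume(array(c(-1200, 600, -2000, 1000, -300, 0, -600, -900),
                         dim = c(2, 2, 2)))
  g <- hu_to_gray(vol)
  expect_identical(g$intensity_space, "GRAY255")
  v <- as.numeric(g$data)
  expect_equal(v[1], 0)       # low endpoint
  expect_equal(v[2], 255)     # high endpoint
  expect_equal(v[3], 0)       # clipped below
  expect_equal(v[4], 255)     # clipped above
  expect_equal(v[5], 128)     # 255*900/1800 = 127.5, round half up
})

test_that("HU windowing is monotone and rejects non-HU input", {
  set.seed(4)
  h <- sort(runif(50, -1500, 800))
  vol <- ct_volume(array(rep(h, each = 2), dim = c(2, 5, 10)))
  g <- hu_to_gray(vol)
  flat <- as.numeric(g$data)[seq(1, 100, by = 2)]
  expect_true(all(diff(flat) >= 0))
  expect_error(hu_to_gray(g), "HU")
})

test_that("isotropic resampling preserves extent and constants", {
  # already isotropic at target: untouched
  v1 <- ct_volume(array(rnorm(8^3), dim = c(8, 8, 8)))
  expect_identical(resample_isotropic(v1)$data, v1$data)

  # 10 voxels at 2 mm along z -> 20 voxels at 1 mm (20 mm extent kept)
  v2 <- ct_volume(array(rnorm(10 * 8 * 8), dim = c(10, 8, 8)),
                  spacing = c(1, 1, 2))
  r2 <- resample_isotropic(v2)
  expect_identical(dim(r2$data), c(20L, 8L, 8L))
  expect_equal(r2$spacing, c(1, 1, 1))

  # constant volume stays constant under trilinear interpolation
  v3 <- ct_volume(array(7, dim = c(6, 6, 6)), spacing = c(1.7, 0.9, 2.3))
  expect_true(all(abs(resample_isotropic(v3)$data - 7) < 1e-12))

  expect_error(preprocess_config(target_spacing = 0), "target_spacing")
})

test_that("repeated resampling at the same spacing is stable", {
  set.seed(5)
  v <- ct_volume(array(rnorm(9 * 7 * 11), dim = c(9, 7, 11)),
                 spacing = c(1.3, 0.8, 2.1))
  r1 <- resample_isotropic(v)
  r2 <- resample_isotropic(r1)
  expect_equal(r2$data, r1$data, tolerance = 1e-6)
})

test_that("lung mask covers embedded low-density regions and stays binary", {
  # phantom: bright body with two dark ellipsoids
  spec <- phantom_spec(shape = c(48, 48, 48), seed = 9, noise_sd = 4)
  ph <- generate_phantom(spec)
  m <- lung_mask(ph$volume)
  expect_true(all(m %in% c(0L, 1L)))
  # ground-truth lung voxels from the generator's geometry
  nz <- 48; ny <- 48; nx <- 48
  cz <- (nz - 1) / 2; cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  zt <- ((seq_len(nz) - 1 - cz) / (0.47 * nz))^2
  yt <- ((seq_len(ny) - 1 - (cy - 0.04 * ny)) / (0.30 * ny))^2
  truth <- array(FALSE, dim = c(nz, ny, nx))
  for (side in c(-1, 1)) {
    xt <- ((seq_len(nx) - 1 - (cx + side * 0.22 * nx)) / (0.17 * nx))^2
    truth <- truth | (outer(outer(zt, yt, "+"), xt, "+") <= 0.9)
  }
  expect_gt(sum(m[truth]) / sum(truth), 0.95)
  # never outside the body envelope: no mask on the outer air shell
  expect_identical(sum(m[, c(1, ny), ]) + sum(m[, , c(1, nx)]), 0L)
})

test_that("lung mask on a uniform volume is empty with a warning", {
  v <- ct_volume(array(200, dim = c(16, 16, 16)), intensity_space = "HU")
  g <- hu_to_gray(v)
  expect_warning(m <- lung_mask(g), "empty mask")
  expect_identical(sum(m), 0L)
})

test_that("apply_mask zeroes outside and optionally crops", {
  v <- ct_volume(array(5, dim = c(6, 6, 6)), intensity_space = "GRAY255")
  m <- array(0L, dim = c(6, 6, 6))
  m[2:4, 3:5, 2:3] <- 1L
  z <- apply_mask(v, m)
  expect_identical(dim(z$data), dim(v$data))
  expect_equal(sum(z$data != 0), sum(m))
  cr <- apply_mask(v, m, crop = TRUE)
  expect_identical(dim(cr$data), c(3L, 3L, 2L))
  expect_equal(cr$origin, c(1, 2, 1))  # (x, y, z) of voxel (2,3,2)-1
})
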