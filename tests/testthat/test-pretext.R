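test_that("axial rotation follows the stated permutation convention", {
  a <- array(0, dim = c(2, 4, 4))
  a[1, 1, 1] <- 1  # lit voxel at (y, x) = (0, 0)
  r <- rotate_axial(a, 1)
  expect_equal(r[1, 1, 4], 1)  # moves to (y, x) = (0, 3)
  expect_equal(sum(r), 1)

  expect_identical(rotate_axial(a, 0), a)
  r4 <- a
  for (i in 1:4) r4 <- rotate_axial(r4, 1)
  expect_identical(r4, a)
  expect_error(rotate_axial(a, 4), "0..3")
})

test_that("axial rotation is a pure permutation of voxel values", {
  set.seed(10)
  a <- array(rnorm(4 * 6 * 6), dim = c(4, 6, 6))
  for (k in 0:3) {
    r <- rotate_axial(a, k)
    expect_identical(sort(as.numeric(r)), sort(as.numeric(a)))
  }
  # composition: k-fold single steps equal one k-step call
  expect_identical(rotate_axial(rotate_axial(a, 1), 1), rotate_axial(a, 2))
})

test_that("rotation loss matches analytic values and clamps zeros", {
  uni <- matrix(0.25, 4, 4)
  expect_equal(rotation_loss(uni), log(4), tolerance = 1e-12)
  expect_equal(rotation_loss(diag(4) * 0.9999997 + 1e-7), 0,
               tolerance = 1e-5)
  p <- matrix(0.1, 4, 4)
  diag(p) <- 0.7
  expect_equal(rotation_loss(p), -mean(log(rep(0.7, 4))))
  bad <- matrix(c(0, 1, 0, 0,
                  0, 1, 0, 0,
                  0, 0, 1, 0,
                  0, 0, 0, 1), 4, 4, byrow = TRUE)
  expect_warning(v <- rotation_loss(bad), "clamp")
  expect_gt(v, 0)
  expect_error(rotation_loss(matrix(0.5, 2, 4)), "square")
})

test_that("a tiny pretext run memorises one asymmetric volume", {
  spec <- sample_phantom_spec("m", 77, shape = c(32, 32, 32), n_nodules = 1,
                              diameter_range = c(4, 6), n_vessels = 1)
  vol <- generate_phantom(spec)$volume
  cfg <- rotation_task_config(epochs = 12, batch = 4, lr = 0.02,
                              backbone_channels = c(2, 4, 8, 8, 8),
                              fc_width = 16)
  m <- train_pretext(list(vol), cfg, seed = 5)
  expect_length(m$loss_log, 12)
  expect_lt(m$loss_log[12], m$loss_log[1])
  hits <- vapply(0:3, function(k)
    which.max(predict(m, rotate_axial(vol, k))) == k + 1, logical(1))
  expect_true(all(hits))
})

test_that("training is seed-deterministic and weight transfer is exact", {
  spec <- sample_phantom_spec("d", 78, shape = c(32, 32, 32), n_nodules = 1,
                              diameter_range = c(4, 6))
  vol <- generate_phantom(spec)$volume
  cfg <- rotation_task_config(epochs = 2, batch = 4, lr = 0.02,
                              backbone_channels = c(2, 4, 8, 8, 8),
                              fc_width = 16)
  m1 <- train_pretext(list(vol), cfg, seed = 9)
  m2 <- train_pretext(list(vol), cfg, seed = 9)
  expect_identical(m1$par, m2$par)

  dcfg <- detector_config(input_window = 16,
                          backbone_channels = c(2, 4, 8, 8, 8),
                          pyramid_channels = 4, anchor_sides = c(3, 5),
                          epochs = 1)
  dpar <- pulmo3d:::fpn_par(dcfg)
  out <- transfer_weights(m1, dpar)
  expect_identical(out$backbone, m1$par$backbone)

  bad <- detector_config(input_window = 16,
                         backbone_channels = c(3, 4, 8, 8, 8),
                         pyramid_channels = 4, anchor_sides = c(3, 5))
  expect_error(transfer_weights(m1, pulmo3d:::fpn_par(bad)), "mismatch")
})
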