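test_that("phantom generation is seed-deterministic with exact bookkeeping", {
  spec <- phantom_spec(shape = c(32, 32, 32), seed = 11,
                       nodules = list(list(center = c(10, 14, 16),
                                           diameter_mm = 6, contrast = 80)))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(nrow(a$annotations), 1L)
  expect_equal(as.numeric(a$annotations[1, c("coordX", "coordY", "coordZ")]),
               c(10, 14, 16))
  expect_equal(a$annotations$diameter_mm, 6)

  empty <- generate_phantom(phantom_spec(shape = c(16, 16, 16), seed = 1))
  expect_identical(nrow(empty$annotations), 0L)
})

test_that("rendered nodules carry their requested contrast", {
  spec <- phantom_spec(shape = c(40, 40, 40), seed = 3, body = FALSE,
                       background_level = 30, noise_sd = 8,
                       nodules = list(list(center = c(20, 20, 20),
                                           diameter_mm = 10,
                                           contrast = 80)))
  ph <- generate_phantom(spec)
  arr <- ph$volume$data
  idx <- which(outer(outer((0:39 - 20)^2, (0:39 - 20)^2, "+"),
                     (0:39 - 20)^2, "+") <= 4.5^2)
  inside_mean <- mean(arr[idx])
  outside_mean <- mean(arr[-idx])
  expect_gt(inside_mean - outside_mean, 0.5 * 80)
})

test_that("phantom spec validates diameters and contrast", {
  expect_error(phantom_spec(nodules = list(list(center = c(0, 0, 0),
                                                diameter_mm = 40,
                                                contrast = 80))),
               "\\[3, 30\\]")
  expect_error(phantom_spec(noise_sd = 90,
                            nodules = list(list(center = c(0, 0, 0),
                                                diameter_mm = 10,
                                                contrast = 80))),
               "contrast")
  expect_warning(generate_phantom(phantom_spec(
    shape = c(32, 32, 32), body = FALSE, seed = 2,
    nodules = list(list(center = c(15, 15, 15), diameter_mm = 8,
                        contrast = 80),
                   list(center = c(16, 16, 16), diameter_mm = 8,
                        contrast = 80)))), "overlap")
})

test_that("candidate sequences show the two LHI location patterns", {
  cfg <- lhi_config()
  nod <- make_candidate_sequence("nodule", seed = 21)
  tis <- make_candidate_sequence("tissue", params = list(drift = c(2, 0)),
                                 seed = 21)
  expect_identical(dim(nod$slices)[1], 11L)
  l_nod <- compute_lhi(nod$slices, 30, cfg$tau)
  l_tis <- compute_lhi(tis$slices, 30, cfg$tau)
  centre <- (dim(l_nod) - 1) / 2
  cm_n <- com2d(l_nod)
  expect_lt(sqrt(sum((cm_n - rev(centre))^2)), 2)
  cm_t <- com2d(l_tis)
  # drift (2, 0) px/slice displaces the history trail along +x
  expect_gt(cm_t[1] - centre[2], 2)
  # seeded reproducibility
  again <- make_candidate_sequence("nodule", seed = 21)
  expect_identical(nod$slices, again$slices)
})

test_that("sequence kinds separate by LHI centre-of-mass displacement", {
  cfg <- lhi_config()
  n <- 200
  disp <- numeric(n)
  lab <- rep(c(TRUE, FALSE), length.out = n)  # TRUE = nodule
  for (i in seq_len(n)) {
    ang <- i %% 7
    sq <- make_candidate_sequence(
      if (lab[i]) "nodule" else "tissue",
      params = list(radius = 5 + (i %% 5),
                    drift = 2 * c(cos(ang), sin(ang))),
      seed = 3000 + i)
    l <- compute_lhi(sq$slices, 30, cfg$tau)
    centre <- rev((dim(l) - 1) / 2)
    disp[i] <- sqrt(sum((com2d(l) - centre)^2))
  }
  # best single threshold on displacement alone classifies >= 90%
  acc <- max(vapply(sort(disp), function(t)
    mean((disp <= t) == lab), numeric(1)))
  expect_gte(acc, 0.9)
})
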