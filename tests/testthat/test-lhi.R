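test_that("LHI recurrence matches hand-checked cases and bounds", {
  # constant stack: the update never fires
  const <- array(42, dim = c(5, 4, 4))
  expect_true(all(compute_lhi(const, 30, 10) == 0))

  # 2x2x3 hand case: fire at (1,1) on pair 1 then decay; fire at (2,2) last
  stack <- array(0, dim = c(3, 2, 2))
  stack[2, 1, 1] <- 100
  stack[3, 1, 1] <- 100
  stack[3, 2, 2] <- 40
  out <- compute_lhi(stack, 30, 2)
  expect_identical(out, matrix(c(1, 0, 0, 2), 2, 2))

  set.seed(6)
  rnd <- array(sample(0:255, 8 * 8 * 12, replace = TRUE), dim = c(12, 8, 8))
  f <- compute_lhi(rnd, 30, 10)
  expect_gte(min(f), 0)
  expect_lte(max(f), 10)
  expect_error(compute_lhi(array(0, dim = c(1, 4, 4))), "at least 2")
  expect_error(compute_lhi(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "one shape")
})

test_that("LHI equals the per-pixel recurrence oracle on random stacks", {
  set.seed(7)
  for (i in 1:50) {
    S <- sample(3:12, 1)
    H <- sample(2:8, 1); W <- sample(2:8, 1)
    stack <- array(sample(0:255, S * H * W, replace = TRUE),
                   dim = c(S, H, W))
    thr <- sample(c(10, 30, 40), 1)
    tau <- sample(c(2, 5, 10), 1)
    expect_identical(compute_lhi(stack, thr, tau),
                     lhi_oracle(stack, thr, tau))
  }
})

test_that("LHI is pixelwise independent (permutation equivariance)", {
  set.seed(8)
  stack <- array(sample(0:255, 6 * 5 * 5, replace = TRUE), dim = c(6, 5, 5))
  base <- compute_lhi(stack, 30, 10)
  perm_r <- sample(5)
  perm_c <- sample(5)
  permuted <- stack[, perm_r, perm_c]
  expect_identical(compute_lhi(permuted, 30, 10), base[perm_r, perm_c])
})

test_that("support of the LHI is tau-invariant once tau covers the stack", {
  set.seed(9)
  stack <- array(sample(0:255, 10 * 6 * 6, replace = TRUE),
                 dim = c(10, 6, 6))
  a <- compute_lhi(stack, 30, 9)    # tau = S - 1
  b <- compute_lhi(stack, 30, 50)
  expect_identical(a > 0, b > 0)
})

test_that("patch extraction pads borders and yields one LHI per threshold", {
  spec <- phantom_spec(shape = c(24, 24, 24), seed = 13, body = FALSE,
                       nodules = list(list(center = c(12, 12, 12),
                                           diameter_mm = 8,
                                           contrast = 80)))
  ph <- generate_phantom(spec)
  cfg <- lhi_config()
  corner <- data.frame(seriesuid = "p", coordX = 0, coordY = 0, coordZ = 0,
                       diameter_mm = 8, score = 0.9, label = "unfiltered")
  patches <- extract_lhi_patch(ph$volume, corner, cfg)
  expect_length(patches, 2)  # thresholds 30 and 40
  expect_identical(dim(patches[[1]]$image), c(48L, 48L))
  expect_true(all(patches[[1]]$image >= 0 &
                  patches[[1]]$image <= cfg$tau))
  centre <- data.frame(seriesuid = "p", coordX = 12, coordY = 12,
                       coordZ = 12, diameter_mm = 8, score = 0.9,
                       label = "unfiltered")
  p2 <- extract_lhi_patch(ph$volume, centre, cfg)
  expect_identical(vapply(p2, function(p) p$threshold, numeric(1)),
                   c(30, 40))
})
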