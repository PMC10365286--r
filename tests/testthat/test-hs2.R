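# tiny patches with an obvious linear separation: bright top half vs
# bright bottom half
toy_patch <- function(kind, seed, n = 16) {
  set.seed(seed)
  img <- matrix(abs(rnorm(n * n, 0, 0.4)), n, n)
  if (kind == 1) img[1:(n / 2), ] <- img[1:(n / 2), ] + 6
  else img[(n / 2 + 1):n, ] <- img[(n / 2 + 1):n, ] + 6
  pmin(img, 10)
}

tiny_cfg <- function(epochs = 12)
  hs2_config(conv_channels = c(2, 4), fc_widths = c(16, 8, 8),
             epochs = epochs, batch = 8, lr = 0.02, lr_decay_every = 1000,
             augment = FALSE)

test_that("training balances classes and fits separable data", {
  patches <- c(lapply(1:12, function(i) toy_patch(1, i)),
               lapply(1:12, function(i) toy_patch(0, 100 + i)))
  labels <- rep(c(1L, 0L), each = 12)
  m <- train_hs2(patches, labels, tiny_cfg(), seed = 3)
  expect_identical(unname(m$n_train), c(12L, 12L))
  probs <- predict(m, patches)
  expect_identical(as.integer(probs >= 0.5), labels)

  # unbalanced input is undersampled to the minority count
  unb <- c(patches[1:4], patches[13:24])
  m2 <- train_hs2(unb, c(rep(1L, 4), rep(0L, 12)), tiny_cfg(4), seed = 3)
  expect_identical(unname(m2$n_train), c(4L, 4L))

  expect_error(train_hs2(patches[1:5], rep(1L, 5), tiny_cfg()),
               "both classes")
})

test_that("training is seed-deterministic", {
  patches <- c(lapply(1:6, function(i) toy_patch(1, i)),
               lapply(1:6, function(i) toy_patch(0, 50 + i)))
  labels <- rep(c(1L, 0L), each = 6)
  m1 <- train_hs2(patches, labels, tiny_cfg(3), seed = 8)
  m2 <- train_hs2(patches, labels, tiny_cfg(3), seed = 8)
  expect_identical(m1$par, m2$par)
})

test_that("candidate filtering relabels without touching geometry", {
  patches <- c(lapply(1:8, function(i) toy_patch(1, i)),
               lapply(1:8, function(i) toy_patch(0, 200 + i)))
  labels <- rep(c(1L, 0L), each = 8)
  m <- train_hs2(patches, labels, tiny_cfg(), seed = 4)
  cands <- data.frame(seriesuid = "s", coordX = c(1, 2, 3), coordY = 0,
                      coordZ = 0, diameter_mm = 8,
                      score = c(0.9, 0.8, 0.7), label = "unfiltered")
  per_cand <- list(list(toy_patch(1, 301)), list(toy_patch(0, 302)),
                   list())
  expect_warning(out <- classify_candidates(cands, per_cand, m),
                 "without patches")
  expect_identical(nrow(out), nrow(cands))
  expect_identical(out[, c("coordX", "score")], cands[, c("coordX", "score")])
  expect_identical(out$label, c("nodule", "tissue", "unfiltered"))

  # the decision rule is >= : probability exactly at threshold keeps nodule
  p <- predict(m, list(toy_patch(1, 301)))
  cfg2 <- m$cfg
  cfg2$threshold <- as.numeric(p)
  out2 <- classify_candidates(cands[1, ], list(list(toy_patch(1, 301))), m,
                              cfg2)
  expect_identical(out2$label, "nodule")
})

test_that("a degenerate always-nodule filter leaves the FROC unchanged", {
  set.seed(14)
  toy <- random_toy_matchset(42)
  m_unf <- match_candidates(toy$cands, toy$truths, scans = toy$scans)
  f_unf <- froc_sensitivities(m_unf, toy$n_scans)
  all_kept <- toy$cands
  all_kept$label <- "nodule"   # degenerate classifier keeps everything
  m_fil <- match_candidates(all_kept[all_kept$label != "tissue", ],
                            toy$truths, scans = toy$scans)
  f_fil <- froc_sensitivities(m_fil, toy$n_scans)
  expect_equal(f_fil$sensitivities, f_unf$sensitivities)
  expect_equal(f_fil$cpm, f_unf$cpm)
})
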