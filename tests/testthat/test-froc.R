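scan1 <- function(...) data.frame(seriesuid = "s1", ..., label = "unfiltered")

test_that("hit criterion and per-truth bookkeeping follow the convention", {
  truths <- data.frame(seriesuid = "s1", coordX = 0, coordY = 0, coordZ = 0,
                       diameter_mm = 10)
  exact <- scan1(coordX = 0, coordY = 0, coordZ = 0, diameter_mm = 8,
                 score = 0.9)
  m <- match_candidates(exact, truths)
  expect_identical(m$candidates$match, "TP")

  far <- scan1(coordX = 20, coordY = 0, coordZ = 0, diameter_mm = 8,
               score = 0.9)
  expect_identical(match_candidates(far, truths)$candidates$match, "FP")

  # boundary: distance exactly the radius is a miss (strict <)
  edge <- scan1(coordX = 5, coordY = 0, coordZ = 0, diameter_mm = 8,
                score = 0.9)
  expect_identical(match_candidates(edge, truths)$candidates$match, "FP")

  two <- rbind(scan1(coordX = 1, coordY = 0, coordZ = 0, diameter_mm = 8,
                     score = 0.6),
               scan1(coordX = -1, coordY = 0, coordZ = 0, diameter_mm = 8,
                     score = 0.8))
  m2 <- match_candidates(two, truths)
  expect_setequal(m2$candidates$match, c("ignored", "TP"))
  expect_identical(m2$candidates$match[2], "TP")  # higher score wins
  expect_identical(sum(m2$candidates$match == "FP"), 0L)

  expect_error(match_candidates(
    data.frame(seriesuid = "zzz", coordX = 0, coordY = 0, coordZ = 0,
               diameter_mm = 5, score = 0.5, label = "unfiltered"),
    truths), "zzz")
})

test_that("every candidate and truth is accounted for exactly once", {
  for (seed in c(1, 2, 3)) {
    toy <- random_toy_matchset(seed)
    m <- match_candidates(toy$cands, toy$truths, scans = toy$scans)
    expect_identical(nrow(m$candidates), nrow(toy$cands))
    expect_true(all(m$candidates$match %in% c("TP", "FP", "ignored")))
    expect_identical(sum(m$candidates$match == "TP"), sum(m$truths$hit))
    # TP + FN partitions the truths
    expect_identical(sum(m$truths$hit) + sum(!m$truths$hit),
                     nrow(toy$truths))
  }
})

test_that("FROC sensitivities equal the exhaustive sweep oracle", {
  # empty candidate list
  truths <- data.frame(seriesuid = c("s1", "s2"), coordX = 0, coordY = 0,
                       coordZ = 0, diameter_mm = 10)
  empty <- data.frame(seriesuid = character(), coordX = numeric(),
                      coordY = numeric(), coordZ = numeric(),
                      diameter_mm = numeric(), score = numeric(),
                      label = character())
  m <- match_candidates(empty, truths)
  fr <- froc_sensitivities(m, n_scans = 2)
  expect_identical(fr$sensitivities, rep(0, 7))

  # hand-built: 2 scans, 4 truths, 6 candidates with known scores
  truths <- data.frame(seriesuid = c("a", "a", "b", "b"),
                       coordX = c(0, 30, 0, 30), coordY = 0, coordZ = 0,
                       diameter_mm = 10)
  cands <- data.frame(
    seriesuid = c("a", "a", "a", "b", "b", "b"),
    coordX = c(0, 30, 60, 0, 60, 90),
    coordY = 0, coordZ = 0, diameter_mm = 8,
    score = c(0.9, 0.5, 0.8, 0.7, 0.6, 0.4), label = "unfiltered")
  m <- match_candidates(cands, truths)
  fr <- froc_sensitivities(m, n_scans = 2)
  oracle <- froc_oracle(cands, truths, 2, fr$fp_levels)
  expect_equal(fr$sensitivities, oracle)
  expect_true(all(diff(fr$sensitivities) >= 0))

  for (seed in 11:20) {
    toy <- random_toy_matchset(seed)
    m <- match_candidates(toy$cands, toy$truths, scans = toy$scans)
    fr <- froc_sensitivities(m, n_scans = toy$n_scans)
    expect_equal(fr$sensitivities,
                 froc_oracle(toy$cands, toy$truths, toy$n_scans,
                             fr$fp_levels))
    expect_true(all(diff(fr$sensitivities) >= 0))
  }
  expect_error(froc_sensitivities(m, n_scans = 0), "positive")
})

test_that("interpolated FROC bounds the step-function reading from above", {
  for (seed in 31:35) {
    toy <- random_toy_matchset(seed)
    m <- match_candidates(toy$cands, toy$truths, scans = toy$scans)
    step <- froc_sensitivities(m, n_scans = toy$n_scans)
    lin <- froc_sensitivities(m, n_scans = toy$n_scans, interpolate = TRUE)
    expect_true(all(lin$sensitivities >= step$sensitivities - 1e-12))
    expect_true(all(lin$sensitivities <= 1))
    expect_true(all(diff(lin$sensitivities) >= -1e-12))
  }
})

test_that("CPM is the 3-decimal mean of seven sensitivities", {
  expect_equal(cpm_score(c(0.848, 0.876, 0.905, 0.933, 0.943, 0.957,
                           0.970)), 0.919)
  expect_equal(cpm_score(c(0.906, 0.923, 0.948, 0.981, 0.981, 0.981,
                           0.981)), 0.957)
  expect_equal(cpm_score(rep(0.5, 7)), 0.5)
  expect_error(cpm_score(rep(0.5, 6)), "seven")
  expect_error(cpm_score(c(rep(0.5, 6), 1.2)), "\\[0, 1\\]")
})

test_that("size strata partition diameters with the stated boundaries", {
  expect_identical(as.character(size_strata(c(3, 4.99, 5, 7, 10, 10.01))),
                   c("small", "small", "medium", "medium", "medium",
                     "large"))
})

test_that("stratified CPM matches per-stratum sweeps", {
  # all truths medium: medium CPM equals the overall CPM, others NA
  truths <- data.frame(seriesuid = c("a", "a"), coordX = c(0, 30),
                       coordY = 0, coordZ = 0, diameter_mm = c(6, 8))
  cands <- data.frame(seriesuid = "a", coordX = c(0, 30, 60),
                      coordY = 0, coordZ = 0, diameter_mm = 6,
                      score = c(0.9, 0.4, 0.6), label = "unfiltered")
  m <- match_candidates(cands, truths)
  overall <- froc_sensitivities(m, n_scans = 1)
  st <- stratified_cpm(m, n_scans = 1)
  expect_equal(unname(st$cpm["medium"]), overall$cpm)
  expect_true(is.na(st$cpm["small"]))
  expect_true(is.na(st$cpm["large"]))

  # three-stratum toy case against a brute-force per-stratum sweep
  truths <- data.frame(seriesuid = c("a", "a", "b"),
                       coordX = c(0, 40, 0), coordY = 0, coordZ = 0,
                       diameter_mm = c(4, 8, 14))
  cands <- data.frame(seriesuid = c("a", "a", "b", "b"),
                      coordX = c(0.5, 40, 0, 50), coordY = 0, coordZ = 0,
                      diameter_mm = c(4, 8, 14, 6),
                      score = c(0.7, 0.9, 0.6, 0.8), label = "unfiltered")
  m <- match_candidates(cands, truths)
  st <- stratified_cpm(m, n_scans = 2)
  for (s in c("small", "medium", "large")) {
    sub <- truths[as.character(size_strata(truths$diameter_mm)) == s, ]
    # brute force: sweep every cut; global FP rate, stratum sensitivity
    cuts <- c(Inf, sort(unique(cands$score), decreasing = TRUE))
    mm <- match_candidates(cands, truths, scans = c("a", "b"))
    fp_scores <- mm$candidates$score[mm$candidates$match == "FP"]
    hit <- mm$truths[as.character(size_strata(mm$truths$diameter_mm)) == s,
                     ]
    sens <- vapply(st$strata[[s]]$fp_levels, function(L) {
      best <- 0
      for (t in cuts) {
        if (sum(fp_scores >= t) / 2 <= L)
          best <- max(best, sum(hit$hit_score >= t, na.rm = TRUE) /
                        nrow(hit))
      }
      best
    }, numeric(1))
    expect_equal(st$strata[[s]]$sensitivities, sens)
  }
})

test_that("candidate-level confusion yields sensitivity and specificity", {
  truths <- data.frame(seriesuid = "a", coordX = 0, coordY = 0, coordZ = 0,
                       diameter_mm = 10)
  cands <- data.frame(seriesuid = "a", coordX = c(0, 40, 60),
                      coordY = 0, coordZ = 0, diameter_mm = 6,
                      score = c(0.9, 0.8, 0.7),
                      label = c("nodule", "tissue", "nodule"))
  m <- match_candidates(cands, truths)
  conf <- candidate_confusion(m)
  expect_equal(unname(conf["tp"]), 1)
  expect_equal(unname(conf["tn"]), 1)
  expect_equal(unname(conf["fp"]), 1)
  expect_equal(unname(conf["fn"]), 0)
  expect_equal(unname(conf["sensitivity"]), 1)
  expect_equal(unname(conf["specificity"]), 0.5)
})
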