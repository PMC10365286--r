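# Desk-scale study conditions shared by the heavier tests. Results are
# memoised so several test blocks can reuse one training run.

.experiments <- new.env(parent = emptyenv())

desk_detector_config <- function() {
  detector_config(input_window = 64, backbone_channels = c(4, 8, 16, 16, 16),
                  pyramid_channels = 16, anchor_sides = c(3, 5, 10),
                  epochs = 10, window_overlap = 32)
}

desk_pretext_config <- function() {
  rotation_task_config(epochs = 6, batch = 16, lr = 0.02,
                       backbone_channels = c(4, 8, 16, 16, 16),
                       fc_width = 32)
}

desk_hs2_config <- function() {
  hs2_config(conv_channels = c(6, 12), fc_widths = c(48, 24, 16),
             epochs = 15, batch = 16, lr = 0.01, lr_decay_every = 10,
             lr_factor = 0.5)
}

# 40 seeded 32^3 phantoms; 30 train / 10 held out, all four rotations
pretext_experiment <- function() {
  if (!is.null(.experiments$pretext)) return(.experiments$pretext)
  vols <- lapply(1:40, function(i)
    generate_phantom(sample_phantom_spec(sprintf("pre%02d", i), 1000 + i,
                                         shape = c(32, 32, 32),
                                         n_nodules = 1,
                                         diameter_range = c(4, 8)))$volume)
  model <- train_pretext(vols[1:30], desk_pretext_config(), seed = 7)
  hits <- 0
  for (v in vols[31:40]) for (k in 0:3)
    hits <- hits + (which.max(predict(model, rotate_axial(v, k))) == k + 1)
  res <- list(model = model, accuracy = hits / 40)
  .experiments$pretext <- res
  res
}

# 200 train / 100 test nodule-vs-vessel LHI patches from seeded sequences
hs2_sequence_experiment <- function() {
  if (!is.null(.experiments$hs2seq)) return(.experiments$hs2seq)
  lcfg <- lhi_config()
  gen <- function(n, offset) {
    kinds <- rep(c("nodule", "tissue"), length.out = n)
    ps <- vector("list", n)
    for (i in seq_len(n)) {
      ang <- (offset + i) %% 7
      sq <- make_candidate_sequence(
        kinds[i],
        params = list(radius = 6 + (i %% 5),
                      drift = 2 * c(cos(ang), sin(ang))),
        seed = offset + i)
      ps[[i]] <- pulmo3d:::sequence_lhi(sq, lcfg)[[1]]
    }
    list(patches = ps, labels = as.integer(kinds == "nodule"))
  }
  tr <- gen(200, 5000)
  te <- gen(100, 9000)
  model <- train_hs2(tr$patches, tr$labels, desk_hs2_config(), seed = 11)
  probs <- predict(model, te$patches)
  res <- list(model = model,
              accuracy = mean((probs >= 0.5) == (te$labels == 1)))
  .experiments$hs2seq <- res
  res
}

# end-to-end: tiny-config detector on 30 train phantoms, evaluated on 10
# held-out phantoms, HS2 trained on the detector's own training-scan
# candidates
e2e_experiment <- function() {
  if (!is.null(.experiments$e2e)) return(.experiments$e2e)
  mk <- function(id, seed) generate_phantom(sample_phantom_spec(id, seed))
  train <- lapply(1:30, function(i) mk(sprintf("tr%02d", i), 2000 + i))
  test <- lapply(1:10, function(i) mk(sprintf("te%02d", i), 8000 + i))
  train_ids <- sprintf("tr%02d", 1:30)
  test_ids <- sprintf("te%02d", 1:10)
  det <- train_detector(lapply(train, `[[`, "volume"),
                        lapply(train, `[[`, "annotations"),
                        desk_detector_config(), seed = 7)
  detect_set <- function(set, ids)
    do.call(rbind, lapply(seq_along(set), function(i)
      sliding_window_detect(set[[i]]$volume, det, seriesuid = ids[i])))
  cands_train <- detect_set(train, train_ids)
  cands_test <- detect_set(test, test_ids)
  lcfg <- lhi_config()
  patch_set <- function(set, ids, cands) {
    out <- vector("list", nrow(cands))
    for (i in seq_along(set)) {
      rows <- which(cands$seriesuid == ids[i])
      if (length(rows))
        out[rows] <- pulmo3d:::extract_lhi_patches(
          set[[i]]$volume, cands[rows, , drop = FALSE], lcfg)
    }
    out
  }
  patches_train <- patch_set(train, train_ids, cands_train)
  patches_test <- patch_set(test, test_ids, cands_test)
  truths_train <- do.call(rbind, lapply(train, `[[`, "annotations"))
  truths_test <- do.call(rbind, lapply(test, `[[`, "annotations"))
  m_tr <- match_candidates(cands_train, truths_train, scans = train_ids)
  keep <- m_tr$candidates$match != "ignored"
  labels <- as.integer(m_tr$candidates$match[keep] == "TP")
  flat <- unlist(patches_train[keep], recursive = FALSE)
  flat_lab <- rep(labels, vapply(patches_train[keep], length, integer(1)))
  hs2 <- train_hs2(flat, flat_lab, desk_hs2_config(), seed = 13)
  filtered <- classify_candidates(cands_test, patches_test, hs2)
  m_unf <- match_candidates(cands_test, truths_test, scans = test_ids)
  froc_unf <- froc_sensitivities(m_unf, n_scans = 10)
  kept <- filtered[filtered$label != "tissue", , drop = FALSE]
  m_fil <- match_candidates(kept, truths_test, scans = test_ids)
  froc_fil <- froc_sensitivities(m_fil, n_scans = 10)
  res <- list(detector = det, hs2 = hs2,
              cands_test = cands_test, filtered = filtered,
              truths_test = truths_test, test_ids = test_ids,
              m_unf = m_unf, m_fil = m_fil,
              froc_unf = froc_unf, froc_fil = froc_fil)
  .experiments$e2e <- res
  res
}

# minimum FP/scan needed to reach sensitivity >= s from a matched set
min_fp_for_sensitivity <- function(matched, n_scans, s) {
  cands <- matched$candidates
  truths <- matched$truths
  hit_scores <- truths$hit_score[truths$hit]
  fp_scores <- cands$score[cands$match == "FP"]
  thr <- c(Inf, sort(unique(cands$score[cands$match != "ignored"]),
                     decreasing = TRUE))
  best <- Inf
  for (t in thr) {
    sens <- sum(hit_scores >= t) / nrow(truths)
    if (sens >= s - 1e-12)
      best <- min(best, sum(fp_scores >= t) / n_scans)
  }
  best
}
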