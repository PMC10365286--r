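#' Randomised chest-phantom specification
#'
#' Draws a [phantom_spec()] whose nodules and vessel distractors are placed
#' at random inside the phantom's lung regions. Used to build seeded
#' training/evaluation cohorts for the desk-scale experiments.
#'
#' @param id scan identifier.
#' @param seed integer seed (placement and rendering noise).
#' @param shape voxel grid `(nz, ny, nx)`.
#' @param n_nodules,n_vessels structure counts.
#' @param diameter_range nodule diameters, mm (uniform draw).
#' @param contrast,vessel_contrast additive gray contrast.
#' @param drift_range vessel lateral drift magnitude, voxels per slice.
#' @param noise_sd noise level.
#' @return a `phantom_spec`.
#' @export
sample_phantom_spec <- function(id, seed, shape = c(64, 64, 64),
                                n_nodules = 2, n_vessels = 3,
                                diameter_range = c(6, 12), contrast = 80,
                                vessel_contrast = 70,
                                drift_range = c(1, 2.5), noise_sd = 8) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  cz <- (nz - 1) / 2; cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  with_seed(seed, {
    lung_point <- function() {
      side <- sample(c(-1, 1), 1)
      repeat {
        u <- runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      c(x = cx + side * 0.22 * nx + 0.6 * 0.17 * nx * u[1],
        y = cy - 0.04 * ny + 0.6 * 0.30 * ny * u[2],
        z = cz + 0.6 * 0.47 * nz * u[3])
    }
    nodules <- list()
    tries <- 0
    while (length(nodules) < n_nodules && tries < 200) {
      tries <- tries + 1
      p <- lung_point()
      d <- runif(1, diameter_range[1], diameter_range[2])
      ok <- TRUE
      for (nd in nodules) {
        if (sqrt(sum((p - nd$center)^2)) < (d + nd$diameter_mm) / 2 + 4)
          ok <- FALSE
      }
      if (ok)
        nodules[[length(nodules) + 1L]] <-
          list(center = unname(p), diameter_mm = d, contrast = contrast)
    }
    vessels <- lapply(seq_len(n_vessels), function(i) {
      p <- lung_point()
      ang <- runif(1, 0, 2 * pi)
      mag <- runif(1, drift_range[1], drift_range[2])
      list(center = unname(p[1:2]), radius_mm = runif(1, 1.5, 2.5),
           contrast = vessel_contrast,
           drift = mag * c(cos(ang), sin(ang)))
    })
    phantom_spec(shape = shape, nodules = nodules, vessels = vessels,
                 noise_sd = noise_sd, id = id,
                 seed = sample.int(.Machine$integer.max, 1))
  })
}

#' Pipeline run configuration
#'
#' Bundles the per-stage configurations, cohort sizes and the global seed.
#' The global seed fans out to per-stage seeds by fixed offsets so stages
#' can be re-run independently. Serialises to/from a single JSON document;
#' unknown keys are rejected.
#'
#' @param n_train,n_test training/evaluation cohort sizes.
#' @param shape phantom grid.
#' @param pretrain run the rotation pretext stage and initialise the
#'   detector backbone from it.
#' @param n_pretrain,pretrain_shape pretext cohort (smaller volumes).
#' @param preprocess,pretext,detector,lhi,hs2 stage configurations.
#' @param seed global integer seed.
#' @param out_dir output directory for `froc.json` and `manifest.json`
#'   (`NULL` to skip writing).
#' @return a `run_config` list.
#' @export
run_config <- function(n_train = 30, n_test = 10, shape = c(64, 64, 64),
                       pretrain = FALSE, n_pretrain = 20,
                       pretrain_shape = c(32, 32, 32),
                       preprocess = preprocess_config(),
                       pretext = rotation_task_config(),
                       detector = detector_config(),
                       lhi = lhi_config(), hs2 = hs2_config(),
                       seed = 1L, out_dir = NULL) {
  structure(list(n_train = n_train, n_test = n_test, shape = shape,
                 pretrain = isTRUE(pretrain), n_pretrain = n_pretrain,
                 pretrain_shape = pretrain_shape, preprocess = preprocess,
                 pretext = pretext, detector = detector, lhi = lhi,
                 hs2 = hs2, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' Top-level and stage-level keys must be known configuration fields;
#' anything else raises an error.
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
run_config_from_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(js), known)
  if (length(extra))
    stop("run_config_from_json: unknown key(s): ",
         paste(extra, collapse = ", "))
  ctor <- list(preprocess = preprocess_config, pretext = rotation_task_config,
               detector = detector_config, lhi = lhi_config,
               hs2 = hs2_config)
  args <- js
  for (nm in names(ctor)) {
    if (is.null(js[[nm]])) next
    sub <- js[[nm]]
    bad <- setdiff(names(sub), names(formals(ctor[[nm]])))
    if (length(bad))
      stop("run_config_from_json: unknown ", nm, " key(s): ",
           paste(bad, collapse = ", "))
    args[[nm]] <- do.call(ctor[[nm]], sub)
  }
  do.call(run_config, args)
}

# small FNV-1a hash of the serialised config, for the manifest
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b)) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

# stage seeds derived from the global seed by fixed offsets
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, pretrain = 202L, detector = 303L, hs2 = 404L,
            test = 505L)
  (seed + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full detection pipeline on synthetic phantoms
#'
#' Executes simulate, preprocess, optional rotation pre-training, detector
#' training, sliding-window detection, LHI extraction, HS2 training and
#' filtering, and FROC evaluation, end to end. HS2 is trained on LHI
#' patches of the detector's own candidates on the training scans,
#' labelled by the hit criterion. Writes `froc.json` and a `manifest.json`
#' (stages, seeds, config hash) when `out_dir` is set.
#'
#' @param cfg a [run_config()].
#' @return report list with unfiltered/filtered `froc_result`s, candidate
#'   tables, the trained models and the manifest.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- character(0)
  done <- function(s) {
    log_msg(s, "done")
    stages <<- c(stages, s)
  }
  sim_seed <- stage_seed(cfg$seed, "simulate")
  train_specs <- lapply(seq_len(cfg$n_train), function(i)
    sample_phantom_spec(sprintf("train_%03d", i), sim_seed + i,
                        shape = cfg$shape))
  test_specs <- lapply(seq_len(cfg$n_test), function(i)
    sample_phantom_spec(sprintf("test_%03d", i),
                        stage_seed(cfg$seed, "test") + i,
                        shape = cfg$shape))
  train <- lapply(train_specs, generate_phantom)
  test <- lapply(test_specs, generate_phantom)
  done("simulate")
  prep <- function(ph) {
    v <- resample_isotropic(ph$volume, cfg$preprocess)
    if (cfg$preprocess$mask_enabled)
      v <- apply_mask(v, lung_mask(v, cfg$preprocess),
                      crop = cfg$preprocess$mask_crop)
    list(volume = v, annotations = ph$annotations)
  }
  train <- lapply(train, prep)
  test <- lapply(test, prep)
  done("preprocess")
  pretext_model <- NULL
  if (cfg$pretrain) {
    pre_specs <- lapply(seq_len(cfg$n_pretrain), function(i)
      sample_phantom_spec(sprintf("pre_%03d", i),
                          stage_seed(cfg$seed, "pretrain") + i,
                          shape = cfg$pretrain_shape, n_nodules = 1,
                          diameter_range = c(4, 8)))
    pre_vols <- lapply(pre_specs, function(s) generate_phantom(s)$volume)
    pcfg <- cfg$pretext
    pcfg$backbone_channels <- cfg$detector$backbone_channels
    pretext_model <- train_pretext(pre_vols, pcfg,
                                   seed = stage_seed(cfg$seed, "pretrain"))
    done("pretrain")
  }
  detector <- train_detector(lapply(train, `[[`, "volume"),
                             lapply(train, `[[`, "annotations"),
                             cfg$detector,
                             seed = stage_seed(cfg$seed, "detector"),
                             init = pretext_model)
  done("train_detector")
  train_ids <- vapply(train_specs, `[[`, "", "id")
  test_ids <- vapply(test_specs, `[[`, "", "id")
  for (i in seq_along(train)) train[[i]]$annotations$seriesuid <-
    train_ids[i]
  for (i in seq_along(test)) test[[i]]$annotations$seriesuid <- test_ids[i]
  cands_train <- do.call(rbind, lapply(seq_along(train), function(i) {
    df <- sliding_window_detect(train[[i]]$volume, detector,
                                seriesuid = train_ids[i])
    df
  }))
  cands_test <- do.call(rbind, lapply(seq_along(test), function(i)
    sliding_window_detect(test[[i]]$volume, detector,
                          seriesuid = test_ids[i])))
  done("detect")
  lhi_for <- function(set, ids, cands) {
    out <- vector("list", nrow(cands))
    for (i in seq_along(set)) {
      rows <- which(cands$seriesuid == ids[i])
      if (!length(rows)) next
      out[rows] <- extract_lhi_patches(set[[i]]$volume,
                                       cands[rows, , drop = FALSE],
                                       cfg$lhi)
    }
    out
  }
  patches_train <- lhi_for(train, train_ids, cands_train)
  patches_test <- lhi_for(test, test_ids, cands_test)
  done("lhi")
  truths_train <- do.call(rbind, lapply(train, `[[`, "annotations"))
  truths_test <- do.call(rbind, lapply(test, `[[`, "annotations"))
  m_train <- match_candidates(cands_train, truths_train, scans = train_ids)
  lab_train <- ifelse(m_train$candidates$match == "FP", 0L, 1L)
  hs2_model <- NULL
  filtered <- cands_test
  if (length(unique(lab_train[m_train$candidates$match != "ignored"])) >=
      2) {
    keep <- m_train$candidates$match != "ignored"
    flat_patches <- unlist(patches_train[keep], recursive = FALSE)
    flat_labels <- rep(lab_train[keep],
                       vapply(patches_train[keep], length, integer(1)))
    hs2_model <- train_hs2(flat_patches, flat_labels, cfg$hs2,
                           seed = stage_seed(cfg$seed, "hs2"))
    filtered <- classify_candidates(cands_test, patches_test, hs2_model,
                                    cfg$hs2)
  } else {
    warning("run_pipeline: single-class training candidates; ",
            "HS2 stage skipped")
  }
  done("hs2_filter")
  m_unf <- match_candidates(cands_test, truths_test, scans = test_ids)
  froc_unf <- froc_sensitivities(m_unf, n_scans = length(test_ids))
  kept <- filtered[filtered$label != "tissue", , drop = FALSE]
  m_fil <- match_candidates(kept, truths_test, scans = test_ids)
  froc_fil <- froc_sensitivities(m_fil, n_scans = length(test_ids))
  m_conf <- match_candidates(filtered, truths_test, scans = test_ids)
  done("evaluate")
  manifest <- list(package = "pulmo3d",
                   version = as.character(utils::packageVersion("pulmo3d")),
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   stages = stages,
                   n_train = cfg$n_train, n_test = cfg$n_test)
  report <- list(froc_unfiltered = froc_unf, froc_filtered = froc_fil,
                 confusion = candidate_confusion(m_conf),
                 candidates_test = cands_test,
                 candidates_filtered = filtered,
                 detector = detector, hs2 = hs2_model,
                 pretext = pretext_model, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(fp_levels = froc_unf$fp_levels,
           unfiltered = list(sensitivities = froc_unf$sensitivities,
                             cpm = froc_unf$cpm),
           filtered = list(sensitivities = froc_fil$sensitivities,
                           cpm = froc_fil$cpm)),
      file.path(cfg$out_dir, "froc.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  report
}
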