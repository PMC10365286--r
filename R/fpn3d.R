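#' Detector configuration
#'
#' Configuration of the 3D feature-pyramid nodule detector. The detector
#' tiles the (isotropically resampled, gray-windowed) volume with cubic
#' windows, extracts a 5-stage backbone pyramid whose P-levels each fuse
#' all four backbone stages C2..C5 (transposed-convolution upsampling from
#' coarser stages, max-pooling from finer ones, 1x1x1 lateral projections
#' to `pyramid_channels`), and predicts per-anchor confidence and cube
#' offsets with a 3x3x3 conv head followed by two 1x1x1 sibling convs.
#'
#' Anchors are cubes whose sides default to `{3,5,10,15,20,25,30}` voxels;
#' they are placed on pyramid levels by scale (sides < 8 on P2, < 16 on P3,
#' < 28 on P4, the rest on P5). Training labels anchors by IoU against
#' ground-truth cubes: below `iou_neg` negative, above `iou_pos` positive,
#' in between ignored.
#'
#' @param input_window cubic sliding-window side in voxels (default 96).
#' @param pyramid_channels channels of every P-level (default 64).
#' @param backbone_channels channels of backbone stages C1..C5.
#' @param anchor_sides ascending cube sides in voxels.
#' @param iou_neg,iou_pos anchor-assignment IoU thresholds (0.02 / 0.4).
#' @param score_threshold candidate-selection probability (0.1), applied
#'   before non-maximum suppression.
#' @param nms_iou IoU above which a lower-scoring candidate is suppressed.
#' @param window_overlap sliding-window overlap in voxels (default 32, at
#'   least the largest nodule so no nodule is split by every boundary).
#' @param neg_ratio sampled negatives per positive anchor during training.
#' @param neg_floor lower bound on the positive count used to size the
#'   negative sample, so background is trained even in nodule-free windows.
#' @param hard_negatives take half of the negative sample from the
#'   currently highest-scoring background anchors (online hard-negative
#'   mining), the other half at random; `FALSE` samples all at random.
#' @param augment_rot randomly rotate each training window (and its truth
#'   cubes) in the axial plane by a multiple of 90 degrees each epoch.
#' @param topk_per_window cap on score-filtered boxes fed to NMS per window.
#' @param epochs,lr,lr_milestones,lr_factor,momentum,weight_decay training
#'   schedule (`lr_milestones` as fractions of `epochs`).
#' @param optimizer `"adam"` (default) or `"sgd"` with momentum.
#' @return a `detector_config` list.
#' @export
detector_config <- function(input_window = 96, pyramid_channels = 64,
                            backbone_channels = c(16, 32, 64, 64, 64),
                            anchor_sides = c(3, 5, 10, 15, 20, 25, 30),
                            iou_neg = 0.02, iou_pos = 0.4,
                            score_threshold = 0.1, nms_iou = 0.1,
                            window_overlap = 32, neg_ratio = 3,
                            neg_floor = 32, hard_negatives = TRUE,
                            augment_rot = TRUE, topk_per_window = 200,
                            epochs = 10, lr = 1e-3,
                            optimizer = c("adam", "sgd"),
                            lr_milestones = c(0.7, 0.85), lr_factor = 0.5,
                            momentum = 0.9, weight_decay = 1e-4) {
  optimizer <- match.arg(optimizer)
  if (iou_neg >= iou_pos)
    stop("detector_config: iou_neg must be below iou_pos")
  if (is.unsorted(anchor_sides))
    stop("detector_config: anchor_sides must be ascending")
  if (input_window %% 16 != 0)
    stop("detector_config: input_window must be a multiple of 16")
  structure(list(input_window = input_window,
                 pyramid_channels = pyramid_channels,
                 backbone_channels = backbone_channels,
                 anchor_sides = anchor_sides, iou_neg = iou_neg,
                 iou_pos = iou_pos, score_threshold = score_threshold,
                 nms_iou = nms_iou, window_overlap = window_overlap,
                 neg_ratio = neg_ratio, neg_floor = neg_floor,
                 hard_negatives = isTRUE(hard_negatives),
                 augment_rot = isTRUE(augment_rot),
                 topk_per_window = topk_per_window,
                 epochs = epochs, lr = lr, optimizer = optimizer,
                 lr_milestones = lr_milestones,
                 lr_factor = lr_factor, momentum = momentum,
                 weight_decay = weight_decay),
            class = "detector_config")
}

# anchor side -> pyramid level (2..5), by receptive-field scale
anchor_level <- function(side) {
  ifelse(side < 8, 2L, ifelse(side < 16, 3L, ifelse(side < 28, 4L, 5L)))
}

#' Intersection-over-union of axis-aligned cubes
#'
#' Cubes are given as `(z, y, x, side)` (centre plus side length, any
#' consistent unit). Symmetric, in `[0, 1]`.
#'
#' @param a,b numeric length-4 cubes, or matrices with 4 columns (in which
#'   case the elementwise row-by-row IoU is returned).
#' @return scalar or vector of IoU values.
#' @export
iou_cube <- function(a, b) {
  A <- if (is.matrix(a)) a else matrix(a, ncol = 4)
  B <- if (is.matrix(b)) b else matrix(b, ncol = 4)
  inter <- rep(1, nrow(A))
  for (ax in 1:3) {
    lo <- pmax(A[, ax] - A[, 4] / 2, B[, ax] - B[, 4] / 2)
    hi <- pmin(A[, ax] + A[, 4] / 2, B[, ax] + B[, 4] / 2)
    inter <- inter * pmax(0, hi - lo)
  }
  un <- A[, 4]^3 + B[, 4]^3 - inter
  out <- ifelse(un > 0, inter / un, 0)
  if (!is.matrix(a) && !is.matrix(b)) out[1] else out
}

# IoU of every anchor (N x 4) against every truth (M x 4): N x M matrix
iou_matrix <- function(anchors, truths) {
  N <- nrow(anchors); M <- nrow(truths)
  out <- matrix(0, N, M)
  for (m in seq_len(M))
    out[, m] <- iou_cube(anchors, matrix(truths[m, ], N, 4, byrow = TRUE))
  out
}

# anchors for one pyramid level: grid (gz,gy,gx), stride st, sides
# rows ordered to match the column-major flattening of a (gz,gy,gx,A) array
level_anchors <- function(grid, stride, sides) {
  cells <- expand.grid(z = seq_len(grid[1]) - 1, y = seq_len(grid[2]) - 1,
                       x = seq_len(grid[3]) - 1)
  ctr <- as.matrix(cells) * stride + (stride - 1) / 2
  do.call(rbind, lapply(sides, function(s) cbind(ctr, side = s)))
}

# all anchors of a window, per level, with bookkeeping
window_anchors <- function(cfg, dims = rep(cfg$input_window, 3)) {
  lv <- anchor_level(cfg$anchor_sides)
  out <- list()
  for (L in sort(unique(lv))) {
    st <- 2^(L - 1)
    grid <- dims %/% st
    sides <- cfg$anchor_sides[lv == L]
    out[[as.character(L)]] <- list(level = L, stride = st, grid = grid,
                                   sides = sides,
                                   anchors = level_anchors(grid, st, sides))
  }
  out
}

#' Assign anchors to ground-truth cubes
#'
#' IoU below `iou_neg` makes an anchor negative, above `iou_pos` positive
#' (matched to the argmax truth), anything between is ignored. With no
#' truths every anchor is negative.
#'
#' With `force_match = TRUE` (used on the training path) a truth whose
#' best-overlapping anchor did not clear `iou_pos` still claims that
#' anchor as positive, provided the overlap exceeds `iou_neg`. Cubic IoU
#' is unforgiving between anchor scales — a nodule of diameter 7 against
#' the 5/10 anchor ladder peaks at IoU 0.36 even perfectly centred — and
#' without the fallback such nodules would receive no positive
#' supervision at all.
#'
#' @param anchors `N x 4` matrix of `(z, y, x, side)` cubes.
#' @param truths `M x 4` matrix (may have zero rows).
#' @param cfg a [detector_config()].
#' @param force_match also mark each truth's best-IoU anchor positive.
#' @return list with `label` (1 positive, 0 negative, `NA` ignored),
#'   `truth_idx` (matched truth for positives, `NA` otherwise) and
#'   `iou_max`.
#' @export
assign_anchors <- function(anchors, truths, cfg = detector_config(),
                           force_match = FALSE) {
  N <- nrow(anchors)
  if (is.null(truths) || nrow(truths) == 0)
    return(list(label = rep(0L, N), truth_idx = rep(NA_integer_, N),
                iou_max = rep(0, N)))
  iou <- iou_matrix(anchors, truths)
  iou_max <- apply(iou, 1, max)
  best <- max.col(iou, ties.method = "first")
  label <- rep(NA_integer_, N)
  label[iou_max < cfg$iou_neg] <- 0L
  label[iou_max > cfg$iou_pos] <- 1L
  truth_idx <- ifelse(label == 1L, best, NA_integer_)
  if (force_match) {
    for (m in seq_len(ncol(iou))) {
      a <- which.max(iou[, m])
      if (iou[a, m] > cfg$iou_neg &&
          !(!is.na(label[a]) && label[a] == 1L)) {
        label[a] <- 1L
        truth_idx[a] <- m
      }
    }
  }
  list(label = label, truth_idx = as.integer(truth_idx), iou_max = iou_max)
}

#' Encode ground-truth cubes as anchor offsets
#'
#' Parameterisation: `(dz, dy, dx) = (truth_centre - anchor_centre) /
#' anchor_side` and `dlog = log(truth_side / anchor_side)`; decoding is the
#' exact inverse.
#'
#' @param anchors,truths `N x 4` cube matrices (row-aligned).
#' @return `N x 4` offset matrix.
#' @export
encode_boxes <- function(anchors, truths) {
  A <- if (is.matrix(anchors)) anchors else matrix(anchors, ncol = 4)
  T_ <- if (is.matrix(truths)) truths else matrix(truths, ncol = 4)
  cbind((T_[, 1:3, drop = FALSE] - A[, 1:3, drop = FALSE]) / A[, 4],
        log(T_[, 4] / A[, 4]))
}

#' Decode anchor offsets into cubes
#'
#' @param anchors `N x 4` cube matrix.
#' @param offsets `N x 4` offset matrix (see [encode_boxes()]).
#' @return `N x 4` cube matrix.
#' @export
decode_boxes <- function(anchors, offsets) {
  A <- if (is.matrix(anchors)) anchors else matrix(anchors, ncol = 4)
  O <- if (is.matrix(offsets)) offsets else matrix(offsets, ncol = 4)
  cbind(A[, 1:3, drop = FALSE] + O[, 1:3, drop = FALSE] * A[, 4],
        A[, 4] * exp(O[, 4]))
}

smooth_l1 <- function(d) ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)
smooth_l1_grad <- function(d) ifelse(abs(d) < 1, d, sign(d))

#' Detection loss (classification + box regression)
#'
#' Binary cross-entropy over positive and negative anchors (ignored anchors
#' excluded) plus smooth-L1 over the positives' offset errors, averaged per
#' component. With no positives the regression term is 0; with nothing but
#' ignored anchors the loss is 0 with a warning.
#'
#' @param cls_scores per-anchor probabilities in `[0, 1]`.
#' @param reg_offsets `N x 4` predicted offsets.
#' @param assignment result of [assign_anchors()].
#' @param anchors `N x 4` anchor cubes.
#' @param truths `M x 4` truth cubes.
#' @return named vector `c(cls, reg, total)`.
#' @export
detection_loss <- function(cls_scores, reg_offsets, assignment, anchors,
                           truths) {
  lab <- assignment$label
  used <- which(!is.na(lab))
  if (!length(used)) {
    warning("detection_loss: all anchors ignored; loss is 0")
    return(c(cls = 0, reg = 0, total = 0))
  }
  p <- pmin(pmax(cls_scores[used], 1e-12), 1 - 1e-12)
  y <- lab[used]
  cls <- -mean(y * log(p) + (1 - y) * log(1 - p))
  pos <- which(lab == 1L)
  reg <- 0
  if (length(pos)) {
    tgt <- encode_boxes(anchors[pos, , drop = FALSE],
                        truths[assignment$truth_idx[pos], , drop = FALSE])
    reg <- mean(smooth_l1(reg_offsets[pos, , drop = FALSE] - tgt))
  }
  c(cls = cls, reg = reg, total = cls + reg)
}

# ---- pyramid network ----------------------------------------------------

fpn_par <- function(cfg) {
  ch <- cfg$backbone_channels
  P <- cfg$pyramid_channels
  lv <- anchor_level(cfg$anchor_sides)
  par <- list(backbone = backbone_par(ch))
  for (l in 2:5)
    par[[paste0("lat", l)]] <- conv_par(ch[l], P, 1, 1, 0)
  for (L in 2:5)
    for (l in (L + 1):5)
      if (l <= 5)
        for (j in seq_len(l - L))
          par[[sprintf("up_%d_%d_%d", l, L, j)]] <- convt_par(P, P)
  for (L in 2:5) {
    par[[paste0("head", L)]] <- conv_par(P, P, 3, 1)
    par[[paste0("head", L, "_n")]] <- inorm_par(P)
    A <- sum(lv == L)
    if (A > 0) {
      par[[paste0("cls", L)]] <- conv_par(P, A, 1, 1, 0)
      par[[paste0("reg", L)]] <- conv_par(P, 4 * A, 1, 1, 0)
    }
  }
  par
}

fpn_forward <- function(x, par, cfg) {
  lv <- anchor_level(cfg$anchor_sides)
  bb <- backbone_fwd(x, par$backbone)
  lat <- list()
  for (l in 2:5)
    lat[[l]] <- conv_fwd(bb[[paste0("c", l)]], par[[paste0("lat", l)]])
  paths <- list()   # cached intermediates for backward
  plevels <- list()
  for (L in 2:5) {
    acc <- NULL
    for (l in 2:5) {
      v <- lat[[l]]
      steps <- list()
      if (l > L) {
        for (j in seq_len(l - L)) {
          v_in <- v
          v <- convt_fwd(v_in, par[[sprintf("up_%d_%d_%d", l, L, j)]])
          steps[[j]] <- list(x = v_in)
        }
      } else if (l < L) {
        for (j in seq_len(L - l)) {
          pf <- pool_fwd(v)
          steps[[j]] <- list(arg = pf$arg, dims = dim(v))
          v <- pf$y
        }
      }
      paths[[sprintf("%d_%d", l, L)]] <- steps
      acc <- if (is.null(acc)) v else acc + v
    }
    ch <- cin_fwd(acc, par[[paste0("head", L)]],
                  par[[paste0("head", L, "_n")]])
    h <- relu(ch$y)
    lvl <- list(P = acc, h = h, head_cache = ch)
    if (!is.null(par[[paste0("cls", L)]])) {
      lvl$cls <- conv_fwd(h, par[[paste0("cls", L)]])
      lvl$reg <- conv_fwd(h, par[[paste0("reg", L)]])
    }
    plevels[[as.character(L)]] <- lvl
  }
  list(bb = bb, lat = lat, paths = paths, plevels = plevels)
}

# gheads: list keyed by level character with gcls, greg arrays (or NULL)
fpn_backward <- function(par, cfg, fw, gheads) {
  grads <- list()
  glat <- vector("list", 5)
  for (L in 2:5) {
    lvl <- fw$plevels[[as.character(L)]]
    gh <- NULL
    gg <- gheads[[as.character(L)]]
    if (!is.null(gg)) {
      bc <- conv_bwd(lvl$h, par[[paste0("cls", L)]], gg$gcls)
      grads[[paste0("cls", L)]] <- list(W = bc$gW, b = bc$gb)
      br <- conv_bwd(lvl$h, par[[paste0("reg", L)]], gg$greg)
      grads[[paste0("reg", L)]] <- list(W = br$gW, b = br$gb)
      gh <- bc$gx + br$gx
    }
    if (is.null(gh)) next
    gh <- relu_bwd(gh, lvl$h)
    bh <- cin_bwd(lvl$head_cache, par[[paste0("head", L)]],
                  par[[paste0("head", L, "_n")]], gh)
    grads[[paste0("head", L)]] <- bh$conv
    grads[[paste0("head", L, "_n")]] <- bh$norm
    gacc <- bh$gx
    for (l in 2:5) {
      steps <- fw$paths[[sprintf("%d_%d", l, L)]]
      g <- gacc
      if (l > L) {
        for (j in rev(seq_len(l - L))) {
          key <- sprintf("up_%d_%d_%d", l, L, j)
          bu <- convt_bwd(steps[[j]]$x, par[[key]], g)
          grads[[key]] <- acc_grads(grads[[key]],
                                    list(W = bu$gW, b = bu$gb))
          g <- bu$gx
        }
      } else if (l < L) {
        for (j in rev(seq_len(L - l)))
          g <- pool_bwd(g, steps[[j]]$arg, steps[[j]]$dims)
      }
      glat[[l]] <- if (is.null(glat[[l]])) g else glat[[l]] + g
    }
  }
  gc <- list()
  for (l in 2:5) {
    if (is.null(glat[[l]])) next
    bl <- conv_bwd(fw$bb[[paste0("c", l)]], par[[paste0("lat", l)]],
                   glat[[l]])
    grads[[paste0("lat", l)]] <- list(W = bl$gW, b = bl$gb)
    gc[[paste0("c", l)]] <- bl$gx
  }
  grads$backbone <- backbone_bwd(par$backbone, fw$bb, gc)
  grads
}

# ---- training -----------------------------------------------------------

# truth cubes (z,y,x,side in voxels) for one scan
truth_cubes_voxel <- function(ann, vol) {
  if (is.null(ann) || nrow(ann) == 0) return(matrix(0, 0, 4))
  v <- world_to_voxel(as.matrix(ann[, c("coordX", "coordY", "coordZ")]), vol)
  v <- matrix(v, ncol = 3)
  cbind(v[, 3], v[, 2], v[, 1], ann$diameter_mm / vol$spacing[1])
}

# sliding-window start offsets along one axis
window_starts <- function(n, win, overlap) {
  if (n <= win) return(0L)
  s <- seq(0L, n - win, by = win - overlap)
  if (s[length(s)] + win < n) s <- c(s, n - win)
  unique(as.integer(s))
}

# extract a zero-padded cubic window, 0-based start
extract_window <- function(arr, start, win) {
  d <- dim(arr)
  out <- array(0, dim = rep(win, 3))
  zi <- (start[1] + 1):min(start[1] + win, d[1])
  yi <- (start[2] + 1):min(start[2] + win, d[2])
  xi <- (start[3] + 1):min(start[3] + win, d[3])
  out[seq_along(zi), seq_along(yi), seq_along(xi)] <- arr[zi, yi, xi]
  out
}

#' Train the 3D feature-pyramid detector
#'
#' Fits the detector on gray-windowed volumes with ground-truth annotations
#' by SGD with momentum over sliding windows: anchors are assigned per
#' window, negatives are randomly sampled at `neg_ratio` per positive, and
#' the loss is binary cross-entropy on anchor confidences plus smooth-L1 on
#' the positive anchors' offsets. Deterministic given `seed`
#' (single-threaded).
#'
#' @param volumes list of `GRAY255` `ct_volume`s.
#' @param annotations list (parallel to `volumes`) of annotation
#'   data.frames, or one data.frame with a `seriesuid` column matching the
#'   volumes' names.
#' @param cfg a [detector_config()].
#' @param seed integer seed.
#' @param init optional `pretext_model` whose backbone initialises the
#'   detector (see [transfer_weights()]).
#' @return an `fpn3d_model` with parameters, config and per-epoch loss log.
#' @export
train_detector <- function(volumes, annotations, cfg = detector_config(),
                           seed = 1L, init = NULL) {
  if (!length(volumes)) stop("train_detector: empty dataset")
  if (is.data.frame(annotations)) {
    ids <- names(volumes)
    if (is.null(ids)) stop("train_detector: volumes must be named to join ",
                           "a single annotation table")
    annotations <- lapply(ids, function(id)
      annotations[annotations$seriesuid == id, , drop = FALSE])
  }
  win <- cfg$input_window
  anch <- window_anchors(cfg)
  levels_used <- names(anch)
  # precompute training windows: (volume index, start offset)
  jobs <- list()
  for (i in seq_along(volumes)) {
    d <- dim(volumes[[i]]$data)
    st <- expand.grid(z = window_starts(d[1], win, cfg$window_overlap),
                      y = window_starts(d[2], win, cfg$window_overlap),
                      x = window_starts(d[3], win, cfg$window_overlap))
    for (r in seq_len(nrow(st)))
      jobs[[length(jobs) + 1L]] <- list(i = i,
                                        start = as.integer(unlist(st[r, ])))
  }
  truths_vox <- lapply(seq_along(volumes), function(i)
    truth_cubes_voxel(annotations[[i]], volumes[[i]]))
  # rotate cubes (z,y,x,side) within a cubic window by k axial 90-degree
  # steps: (y, x) -> (x, win-1-y)
  rot_cubes <- function(cu, k) {
    for (i in seq_len(k %% 4)) {
      y <- cu[, 2]
      cu[, 2] <- cu[, 3]
      cu[, 3] <- (win - 1) - y
    }
    cu
  }
  # anchor assignments are fixed per (window, rotation): precompute
  n_rot <- if (cfg$augment_rot) 4L else 1L
  for (j in seq_along(jobs)) {
    job <- jobs[[j]]
    tr <- truths_vox[[job$i]]
    if (nrow(tr)) {
      tr_w <- tr
      tr_w[, 1:3] <- sweep(tr[, 1:3, drop = FALSE], 2, job$start, "-")
      keep <- apply(tr_w[, 1:3, drop = FALSE] >= 0 &
                    tr_w[, 1:3, drop = FALSE] < win, 1, all)
      tr_w <- tr_w[keep, , drop = FALSE]
    } else tr_w <- tr
    by_rot <- vector("list", n_rot)
    for (k in seq_len(n_rot) - 1L) {
      tr_k <- rot_cubes(tr_w, k)
      asgs <- list()
      for (Lc in levels_used) {
        LA <- anch[[Lc]]
        asg <- assign_anchors(LA$anchors, tr_k, cfg, force_match = TRUE)
        pos <- which(asg$label == 1L)
        tgt <- if (length(pos))
          encode_boxes(LA$anchors[pos, , drop = FALSE],
                       tr_k[asg$truth_idx[pos], , drop = FALSE])
        else NULL
        asgs[[Lc]] <- list(pos = pos, neg = which(asg$label == 0L),
                           tgt = tgt)
      }
      by_rot[[k + 1L]] <- asgs
    }
    jobs[[j]]$by_rot <- by_rot
  }
  model <- with_seed(seed, {
    par <- fpn_par(cfg)
    if (!is.null(init)) par <- transfer_weights(init, par)
    vel <- zero_like(par)
    adam <- adam_init(par)
    lr <- cfg$lr
    miles <- ceiling(cfg$lr_milestones * cfg$epochs)
    loss_log <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(seq_along(jobs))
      ep_loss <- 0
      for (j in ord) {
        job <- jobs[[j]]
        vol <- volumes[[job$i]]
        x <- extract_window(vol$data, job$start, win) / 128 - 1
        k_rot <- if (cfg$augment_rot) sample(0:3, 1) else 0L
        if (k_rot > 0) x <- rotate_axial(x, k_rot)
        fw <- fpn_forward(x, par, cfg)
        gheads <- list()
        win_loss <- 0
        for (Lc in levels_used) {
          LA <- anch[[Lc]]
          lvl <- fw$plevels[[Lc]]
          asg <- job$by_rot[[k_rot + 1L]][[Lc]]
          pos <- asg$pos
          neg <- asg$neg
          zall <- as.numeric(lvl$cls)
          n_neg <- min(length(neg),
                       cfg$neg_ratio * max(length(pos), cfg$neg_floor))
          neg_s <- integer(0)
          if (length(neg) && n_neg > 0) {
            if (cfg$hard_negatives) {
              nh <- min(length(neg), ceiling(n_neg / 2))
              hard <- neg[order(-zall[neg])[seq_len(nh)]]
              rest <- setdiff(neg, hard)
              rnd <- if (length(rest))
                sample(rest, min(length(rest), n_neg - nh)) else integer(0)
              neg_s <- c(hard, rnd)
            } else {
              neg_s <- sample(neg, n_neg)
            }
          }
          sel <- c(pos, neg_s)
          if (!length(sel)) next
          # class-balanced BCE: positives and negatives contribute equal
          # weight however many of each were sampled
          p <- 1 / (1 + exp(-zall[sel]))
          np <- length(pos)
          nn <- length(neg_s)
          # weight denominators floored so a lone positive cannot dominate
          wp <- if (np) 0.5 / max(np, 8L) else 0
          wn <- if (nn) (if (np) 0.5 else 1) / nn else 0
          y <- c(rep(1, np), rep(0, nn))
          w <- c(rep(wp, np), rep(wn, nn))
          win_loss <- win_loss -
            sum(w * (y * log(pmax(p, 1e-12)) +
                     (1 - y) * log(pmax(1 - p, 1e-12))))
          gcls <- array(0, dim = dim(lvl$cls))
          gcls[sel] <- w * (p - y)
          greg <- array(0, dim = dim(lvl$reg))
          if (length(pos)) {
            nA <- nrow(LA$anchors)
            regm <- matrix(as.numeric(lvl$reg), nA, 4)
            diffs <- regm[pos, , drop = FALSE] - asg$tgt
            win_loss <- win_loss + mean(smooth_l1(diffs))
            gr <- smooth_l1_grad(diffs) / length(diffs)
            gm <- matrix(0, nA, 4)
            gm[pos, ] <- gr
            greg <- array(gm, dim = dim(lvl$reg))
          }
          gheads[[Lc]] <- list(gcls = gcls, greg = greg)
        }
        if (!length(gheads)) next
        grads <- fpn_backward(par, cfg, fw, gheads)
        if (cfg$optimizer == "adam") {
          upd <- adam_update(par, grads, adam, lr, wd = cfg$weight_decay)
          par <- upd$p
          adam <- upd$state
        } else {
          upd <- sgd_update(par, grads, vel, lr, momentum = cfg$momentum,
                            wd = cfg$weight_decay)
          par <- upd$p
          vel <- upd$v
        }
        ep_loss <- ep_loss + win_loss
      }
      loss_log[ep] <- ep_loss / length(jobs)
      if (ep %in% miles) lr <- lr * cfg$lr_factor
    }
    list(par = par, loss_log = loss_log)
  })
  structure(list(par = model$par, cfg = cfg, loss_log = model$loss_log),
            class = "fpn3d_model")
}

#' @export
print.fpn3d_model <- function(x, ...) {
  cat("fpn3d_model: 3D feature-pyramid nodule detector\n")
  cat(sprintf("  window %d^3, anchors {%s} voxels, pyramid %d channels\n",
              x$cfg$input_window,
              paste(x$cfg$anchor_sides, collapse = ","),
              x$cfg$pyramid_channels))
  cat(sprintf("  trained %d epochs, final loss %.4f\n",
              length(x$loss_log), utils::tail(x$loss_log, 1)))
  invisible(x)
}

#' Detect nodule candidates with a sliding window
#'
#' Tiles the volume with overlapping cubic windows (edge windows clamped to
#' the volume, short volumes zero-padded), runs the pyramid on each window,
#' keeps anchors whose confidence exceeds `score_threshold`, decodes them
#' to cubes, maps them to world coordinates, merges across windows and
#' applies 3D non-maximum suppression.
#'
#' @param vol a `GRAY255` `ct_volume`.
#' @param model a trained `fpn3d_model`.
#' @param cfg detector config (defaults to the model's).
#' @param seriesuid scan identifier for the output table.
#' @return a candidate data.frame
#'   (`seriesuid, coordX, coordY, coordZ, diameter_mm, score, label`).
#' @export
sliding_window_detect <- function(vol, model, cfg = model$cfg,
                                  seriesuid = "scan") {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity_space != "GRAY255")
    stop("sliding_window_detect: preprocess to GRAY255 first")
  win <- cfg$input_window
  d <- dim(vol$data)
  anch <- window_anchors(cfg)
  starts <- expand.grid(z = window_starts(d[1], win, cfg$window_overlap),
                        y = window_starts(d[2], win, cfg$window_overlap),
                        x = window_starts(d[3], win, cfg$window_overlap))
  boxes <- list()
  for (r in seq_len(nrow(starts))) {
    s0 <- as.integer(unlist(starts[r, ]))
    x <- extract_window(vol$data, s0, win) / 128 - 1
    fw <- fpn_forward(x, model$par, cfg)
    for (Lc in names(anch)) {
      lvl <- fw$plevels[[Lc]]
      LA <- anch[[Lc]]
      p <- 1 / (1 + exp(-as.numeric(lvl$cls)))
      sel <- which(p > cfg$score_threshold)
      if (!length(sel)) next
      nA <- nrow(LA$anchors)
      regm <- matrix(as.numeric(lvl$reg), nA, 4)
      dec <- decode_boxes(LA$anchors[sel, , drop = FALSE],
                          regm[sel, , drop = FALSE])
      dec[, 1:3] <- sweep(dec[, 1:3, drop = FALSE], 2, s0, "+")
      boxes[[length(boxes) + 1L]] <- cbind(dec, score = p[sel])
    }
  }
  empty <- data.frame(seriesuid = character(), coordX = numeric(),
                      coordY = numeric(), coordZ = numeric(),
                      diameter_mm = numeric(), score = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  if (!length(boxes)) return(empty)
  bx <- do.call(rbind, boxes)
  # keep boxes inside the volume and cap per-volume count before NMS
  inside <- bx[, 1] >= 0 & bx[, 1] < d[1] & bx[, 2] >= 0 & bx[, 2] < d[2] &
            bx[, 3] >= 0 & bx[, 3] < d[3]
  bx <- bx[inside, , drop = FALSE]
  if (!nrow(bx)) return(empty)
  cap <- cfg$topk_per_window * nrow(starts)
  if (nrow(bx) > cap)
    bx <- bx[order(-bx[, 5])[seq_len(cap)], , drop = FALSE]
  world <- voxel_to_world(bx[, c(3, 2, 1), drop = FALSE], vol)
  cands <- data.frame(seriesuid = seriesuid, coordX = world[, 1],
                      coordY = world[, 2], coordZ = world[, 3],
                      diameter_mm = bx[, 4] * vol$spacing[1],
                      score = pmin(pmax(bx[, 5], 0), 1),
                      label = "unfiltered", stringsAsFactors = FALSE)
  nms3d(cands, cfg$nms_iou)
}

#' @export
predict.fpn3d_model <- function(object, vol, ...) {
  sliding_window_detect(vol, object, ...)
}

#' 3D non-maximum suppression
#'
#' Greedy by descending score (ties broken by input order): a candidate is
#' suppressed if its cube IoU with an already-kept candidate exceeds
#' `nms_iou`. Output scores are non-increasing and pairwise IoU is at most
#' `nms_iou`.
#'
#' @param cands candidate data.frame (world mm coordinates + `diameter_mm`,
#'   `score`).
#' @param nms_iou suppression threshold.
#' @return the surviving candidates, ordered by descending score.
#' @export
nms3d <- function(cands, nms_iou = 0.1) {
  if (nrow(cands) <= 1) return(cands)
  ord <- order(-cands$score, seq_len(nrow(cands)))
  cubes <- cbind(cands$coordZ, cands$coordY, cands$coordX,
                 cands$diameter_mm)[ord, , drop = FALSE]
  keep <- logical(length(ord))
  kept_rows <- integer(0)
  for (i in seq_along(ord)) {
    if (length(kept_rows)) {
      iou <- iou_cube(cubes[kept_rows, , drop = FALSE],
                      matrix(cubes[i, ], length(kept_rows), 4, byrow = TRUE))
      if (any(iou > nms_iou)) next
    }
    keep[i] <- TRUE
    kept_rows <- c(kept_rows, i)
  }
  out <- cands[ord[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}
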