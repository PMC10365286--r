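#' Rotation pretext-task configuration
#'
#' Self-supervised pre-training: each volume is rotated in the axial plane
#' by every multiple of 90 degrees, and the shared backbone plus a two-layer
#' classification head is trained to predict which rotation was applied.
#' Reference training schedule: learning rate 0.1 halved after epochs 70
#' and 85, weight decay 5e-4, 100 epochs, batch 16. The desk-scale schedule
#' used in examples and tests shrinks epochs and volume size, not the
#' mechanism.
#'
#' @param K number of rotation classes (must equal `length(angles)`).
#' @param angles rotation angles in degrees, multiples of 90.
#' @param epochs,batch training schedule.
#' @param lr,lr_milestones,lr_factor learning-rate schedule: `lr` multiplied
#'   by `lr_factor` after each epoch in `lr_milestones`.
#' @param weight_decay L2 penalty.
#' @param backbone_channels channels of the shared 5-stage backbone; must
#'   match the detector configuration the weights will be transferred to.
#' @param fc_width width of the first fully connected head layer.
#' @return a `rotation_task_config` list.
#' @export
rotation_task_config <- function(K = 4, angles = c(0, 90, 180, 270),
                                 epochs = 100, batch = 16, lr = 0.1,
                                 lr_milestones = c(70, 85), lr_factor = 0.5,
                                 weight_decay = 5e-4,
                                 backbone_channels = c(16, 32, 64, 64, 64),
                                 fc_width = 64) {
  if (K != length(angles))
    stop("rotation_task_config: K must equal the number of angles")
  if (any(angles %% 90 != 0))
    stop("rotation_task_config: angles must be multiples of 90 degrees")
  structure(list(K = K, angles = angles, epochs = epochs, batch = batch,
                 lr = lr, lr_milestones = lr_milestones,
                 lr_factor = lr_factor, weight_decay = weight_decay,
                 backbone_channels = backbone_channels, fc_width = fc_width),
            class = "rotation_task_config")
}

#' Rotate a volume in the axial plane
#'
#' Rotates every axial `(y, x)` slice by `k * 90` degrees; the z axis is
#' untouched. The convention for one 90-degree step maps pixel `(y, x)` to
#' `(x, H - 1 - y)` where `H` is the number of rows. The operation is a
#' pure permutation of voxels (lossless); applying it four times with
#' `k = 1` restores the input.
#'
#' @param vol a `ct_volume` or a bare 3D array `(z, y, x)`.
#' @param k rotation class index in `0 .. 3`.
#' @return the rotated volume, same type as the input.
#' @export
rotate_axial <- function(vol, k) {
  if (!is.numeric(k) || length(k) != 1 || k %% 1 != 0 || k < 0 || k > 3)
    stop("rotate_axial: k must be an integer in 0..3")
  arr <- if (inherits(vol, "ct_volume")) vol$data else vol
  k <- as.integer(k)
  if (k > 0) {
    for (i in seq_len(k)) {
      arr <- aperm(arr, c(1, 3, 2))
      arr <- arr[, , dim(arr)[3]:1, drop = FALSE]
    }
  }
  if (inherits(vol, "ct_volume")) {
    out <- vol
    out$data <- arr
    out
  } else arr
}

#' Rotation-prediction cross-entropy
#'
#' Mean negative log-probability that each rotated copy assigns to its own
#' rotation class: `-(1/K) * sum_r log p_r(r)` with natural logarithms.
#' Zero probabilities at the true class are clamped at `1e-12` with a
#' warning.
#'
#' @param probs a `K x K` matrix; row `r` is the predicted class
#'   distribution for the copy rotated by class `r` (rows must sum to 1).
#' @return scalar loss (`>= 0`; 0 iff all true classes have probability 1).
#' @export
rotation_loss <- function(probs) {
  probs <- as.matrix(probs)
  K <- nrow(probs)
  if (ncol(probs) != K)
    stop("rotation_loss: probs must be a square K x K matrix")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("rotation_loss: each row must sum to 1")
  p_true <- diag(probs)
  if (any(p_true <= 0)) {
    warning("rotation_loss: zero probability at true class; clamped")
    p_true <- pmax(p_true, 1e-12)
  }
  -mean(log(p_true))
}

# forward the pretext head: global average pool over C5, two FC layers
pretext_head_fwd <- function(c5, par) {
  d <- dim(c5)
  V <- prod(d[1:3])
  z <- colMeans(matrix(c5, V, d[4]))
  a1 <- linear_fwd(z, par$fc1)
  h1 <- pmax(a1, 0)
  logits <- linear_fwd(h1, par$fc2)
  list(z = z, h1 = h1, logits = logits, dims = d)
}

pretext_head_bwd <- function(cache, par, glogits) {
  b2 <- linear_bwd(cache$h1, par$fc2, glogits)
  gh1 <- b2$gx * (cache$h1 > 0)
  b1 <- linear_bwd(cache$z, par$fc1, gh1)
  d <- cache$dims
  V <- prod(d[1:3])
  gc5 <- array(rep(b1$gx / V, each = V), dim = d)
  list(gc5 = gc5,
       grads = list(fc1 = list(W = b1$gW, b = b1$gb),
                    fc2 = list(W = b2$gW, b = b2$gb)))
}

pretext_forward_probs <- function(arr, par) {
  cache <- backbone_fwd(arr, par$backbone)
  head <- pretext_head_fwd(cache$c5, par$head)
  softmax(head$logits)
}

#' Train the rotation-prediction pretext model
#'
#' Expands each input volume into its K rotated copies (the dataset is
#' exactly class-balanced by construction), then trains the shared backbone
#' plus the two-layer head with softmax cross-entropy and SGD with
#' momentum 0.9. Deterministic given `seed` under single-threaded
#' execution.
#'
#' @param volumes list of `ct_volume` (or bare 3D arrays), `GRAY255`.
#' @param cfg a [rotation_task_config()].
#' @param seed integer seed controlling initialisation, shuffling.
#' @return a `pretext_model` with elements `par` (backbone + head
#'   parameters), `cfg`, and `loss_log` (mean loss per epoch).
#' @export
train_pretext <- function(volumes, cfg = rotation_task_config(), seed = 1L) {
  if (!length(volumes)) stop("train_pretext: empty dataset")
  arrs <- lapply(volumes, function(v)
    if (inherits(v, "ct_volume")) v$data else v)
  arrs <- lapply(arrs, function(a) a / 128 - 1)  # centre GRAY255
  K <- cfg$K
  samples <- list()
  for (i in seq_along(arrs))
    for (r in seq_len(K))
      samples[[length(samples) + 1L]] <- list(i = i, r = r)
  model <- with_seed(seed, {
    par <- list(backbone = backbone_par(cfg$backbone_channels),
                head = list(fc1 = linear_par(cfg$backbone_channels[5],
                                             cfg$fc_width),
                            fc2 = linear_par(cfg$fc_width, K)))
    vel <- zero_like(par)
    lr <- cfg$lr
    loss_log <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(seq_along(samples))
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, length(ord), by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1, length(ord))]
        gacc <- NULL
        for (j in idx) {
          s <- samples[[j]]
          x <- rotate_axial(arrs[[s$i]], s$r - 1)
          cache <- backbone_fwd(x, par$backbone)
          head <- pretext_head_fwd(cache$c5, par$head)
          ce <- softmax_ce(head$logits, s$r)
          ep_loss <- ep_loss + ce$loss
          hb <- pretext_head_bwd(head, par$head, ce$grad)
          bg <- backbone_bwd(par$backbone, cache, list(c5 = hb$gc5))
          g <- list(backbone = bg, head = hb$grads)
          gacc <- acc_grads(gacc, g)
        }
        gacc <- scale_grads(gacc, 1 / length(idx))
        upd <- sgd_update(par, gacc, vel, lr, momentum = 0.9,
                          wd = cfg$weight_decay)
        par <- upd$p
        vel <- upd$v
        nb <- nb + 1
      }
      loss_log[ep] <- ep_loss / length(samples)
      if (ep %in% cfg$lr_milestones) lr <- lr * cfg$lr_factor
    }
    list(par = par, loss_log = loss_log)
  })
  structure(list(par = model$par, cfg = cfg, loss_log = model$loss_log),
            class = "pretext_model")
}

#' @export
print.pretext_model <- function(x, ...) {
  cat(sprintf("pretext_model: %d-way rotation classifier\n", x$cfg$K))
  cat(sprintf("  backbone channels: %s\n",
              paste(x$cfg$backbone_channels, collapse = ", ")))
  cat(sprintf("  trained %d epochs, final loss %.4f\n",
              length(x$loss_log), utils::tail(x$loss_log, 1)))
  invisible(x)
}

#' Predict rotation-class probabilities
#'
#' @param object a `pretext_model`.
#' @param vol a `ct_volume` or 3D array (`GRAY255`).
#' @param ... unused.
#' @return numeric vector of K class probabilities.
#' @export
predict.pretext_model <- function(object, vol, ...) {
  arr <- if (inherits(vol, "ct_volume")) vol$data else vol
  pretext_forward_probs(arr / 128 - 1, object$par)
}

#' Transfer pretext backbone weights into a detector
#'
#' Copies the backbone parameter tensors of a trained `pretext_model` into
#' an `fpn3d_model` (or a raw detector parameter list); shapes must match
#' exactly and the copy is bit-identical.
#'
#' @param pretext a trained `pretext_model`.
#' @param detector an `fpn3d_model` or detector parameter list.
#' @return the detector with its backbone replaced.
#' @export
transfer_weights <- function(pretext, detector) {
  stopifnot(inherits(pretext, "pretext_model"))
  src <- pretext$par$backbone
  dst <- if (inherits(detector, "fpn3d_model")) detector$par$backbone
         else detector$backbone
  for (nm in names(src)) {
    if (!identical(dim(dst[[nm]]$W), dim(src[[nm]]$W)))
      stop("transfer_weights: backbone shape mismatch at ", nm)
  }
  if (inherits(detector, "fpn3d_model")) {
    detector$par$backbone <- src
  } else {
    detector$backbone <- src
  }
  detector
}
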