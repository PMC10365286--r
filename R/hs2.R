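#' HS2 false-positive-reduction classifier configuration
#'
#' The HS2 network classifies a candidate's LHI patch as true nodule or
#' tissue. Architecture: two convolution layers (ReLU then batch
#' normalisation after each, 2x2 max-pooling), three fully connected
#' layers, and a 2-way softmax output. Reference widths follow the full
#' configuration (conv channels 30/50, FC 2048/1024/512, 2000 epochs at
#' learning rate 0.01 divided by 10 every 500 epochs); desk-scale runs
#' shrink widths and epochs through the same constructor.
#'
#' @param conv_channels two conv output channel counts.
#' @param fc_widths three fully connected widths.
#' @param kernel conv kernel side (default 5).
#' @param epochs,batch,lr,lr_decay_every,lr_factor training schedule.
#' @param weight_decay L2 penalty.
#' @param threshold decision threshold on the nodule probability; `>=`
#'   keeps the candidate as a nodule.
#' @param balance undersample the majority class to the minority count.
#' @param augment random flip / 90-degree rotation / 0.9-crop per epoch.
#' @return an `hs2_config` list.
#' @export
hs2_config <- function(conv_channels = c(30, 50),
                       fc_widths = c(2048, 1024, 512), kernel = 5,
                       epochs = 2000, batch = 16, lr = 0.01,
                       lr_decay_every = 500, lr_factor = 0.1,
                       weight_decay = 1e-4, threshold = 0.5,
                       balance = TRUE, augment = TRUE) {
  if (length(conv_channels) != 2 || any(conv_channels <= 0))
    stop("hs2_config: need two positive conv channel counts")
  if (length(fc_widths) != 3 || any(fc_widths <= 0))
    stop("hs2_config: need three positive fc widths")
  if (threshold <= 0 || threshold >= 1)
    stop("hs2_config: threshold must lie in (0, 1)")
  structure(list(conv_channels = conv_channels, fc_widths = fc_widths,
                 kernel = kernel, epochs = epochs, batch = batch, lr = lr,
                 lr_decay_every = lr_decay_every, lr_factor = lr_factor,
                 weight_decay = weight_decay, threshold = threshold,
                 balance = isTRUE(balance), augment = isTRUE(augment)),
            class = "hs2_config")
}

hs2_par <- function(cfg, in_size = 48) {
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  flat <- (in_size / 4)^2 * c2
  list(conv1 = conv_par(1, c1, cfg$kernel, 1),
       bn1 = bn_par(c1),
       conv2 = conv_par(c1, c2, cfg$kernel, 1),
       bn2 = bn_par(c2),
       fc1 = linear_par(flat, cfg$fc_widths[1]),
       fc2 = linear_par(cfg$fc_widths[1], cfg$fc_widths[2]),
       fc3 = linear_par(cfg$fc_widths[2], cfg$fc_widths[3]),
       out = linear_par(cfg$fc_widths[3], 2))
}

# patch image (H x W in [0, tau]) -> network input tensor (1, H, W, 1)
hs2_input <- function(img, tau) {
  x <- img / max(tau, 1) * 2 - 1
  array(x, dim = c(1, dim(img), 1))
}

hs2_fwd <- function(xs, par, train = TRUE) {
  a1 <- lapply(xs, conv_fwd, par = par$conv1)
  r1 <- lapply(a1, relu)
  b1 <- bn_fwd(r1, par$bn1, train)
  p1 <- lapply(b1$ys, pool_fwd, kz = 1, ky = 2, kx = 2)
  a2 <- lapply(p1, function(p) conv_fwd(p$y, par$conv2))
  r2 <- lapply(a2, relu)
  b2 <- bn_fwd(r2, par$bn2, train)
  p2 <- lapply(b2$ys, pool_fwd, kz = 1, ky = 2, kx = 2)
  flats <- lapply(p2, function(p) as.numeric(p$y))
  fc <- lapply(flats, function(f) {
    h1 <- pmax(linear_fwd(f, par$fc1), 0)
    h2 <- pmax(linear_fwd(h1, par$fc2), 0)
    h3 <- pmax(linear_fwd(h2, par$fc3), 0)
    list(h1 = h1, h2 = h2, h3 = h3,
         logits = linear_fwd(h3, par$out))
  })
  list(xs = xs, r1 = r1, b1 = b1, p1 = p1, r2 = r2, b2 = b2, p2 = p2,
       flats = flats, fc = fc,
       par = utils::modifyList(par, list(bn1 = b1$par, bn2 = b2$par)))
}

hs2_bwd <- function(fw, par, glogits_list) {
  B <- length(glogits_list)
  grads <- NULL
  gb2_list <- vector("list", B)
  for (i in seq_len(B)) {
    fc <- fw$fc[[i]]
    bo <- linear_bwd(fc$h3, par$out, glogits_list[[i]])
    g3 <- bo$gx * (fc$h3 > 0)
    b3 <- linear_bwd(fc$h2, par$fc3, g3)
    g2 <- b3$gx * (fc$h2 > 0)
    b2l <- linear_bwd(fc$h1, par$fc2, g2)
    g1 <- b2l$gx * (fc$h1 > 0)
    b1l <- linear_bwd(fw$flats[[i]], par$fc1, g1)
    grads <- acc_grads(grads, list(
      out = list(W = bo$gW, b = bo$gb),
      fc3 = list(W = b3$gW, b = b3$gb),
      fc2 = list(W = b2l$gW, b = b2l$gb),
      fc1 = list(W = b1l$gW, b = b1l$gb)))
    gflat <- b1l$gx
    dim(gflat) <- dim(fw$p2[[i]]$y)
    gb2_list[[i]] <- pool_bwd(gflat, fw$p2[[i]]$arg,
                              dim(fw$b2$ys[[i]]))
  }
  bnb2 <- bn_bwd(fw$b2, par$bn2, gb2_list)
  grads$bn2 <- list(gamma = bnb2$ggamma, beta = bnb2$gbeta)
  gb1_list <- vector("list", B)
  for (i in seq_len(B)) {
    gr2 <- relu_bwd(bnb2$gxs[[i]], fw$r2[[i]])
    bc2 <- conv_bwd(fw$p1[[i]]$y, par$conv2, gr2)
    grads$conv2 <- acc_grads(grads$conv2, list(W = bc2$gW, b = bc2$gb))
    gb1_list[[i]] <- pool_bwd(bc2$gx, fw$p1[[i]]$arg,
                              dim(fw$b1$ys[[i]]))
  }
  bnb1 <- bn_bwd(fw$b1, par$bn1, gb1_list)
  grads$bn1 <- list(gamma = bnb1$ggamma, beta = bnb1$gbeta)
  for (i in seq_len(B)) {
    gr1 <- relu_bwd(bnb1$gxs[[i]], fw$r1[[i]])
    bc1 <- conv_bwd(fw$xs[[i]], par$conv1, gr1)
    grads$conv1 <- acc_grads(grads$conv1, list(W = bc1$gW, b = bc1$gb))
  }
  grads
}

augment_patch <- function(img) {
  if (runif(1) < 0.5) img <- img[nrow(img):1, , drop = FALSE]
  if (runif(1) < 0.5) img <- img[, ncol(img):1, drop = FALSE]
  k <- sample(0:3, 1)
  if (k > 0) for (i in seq_len(k)) img <- t(img)[, nrow(img):1]
  if (runif(1) < 0.5) {
    n <- nrow(img)
    cs <- max(4L, as.integer(round(0.9 * n)))
    o1 <- sample.int(n - cs + 1L, 1) - 1L
    o2 <- sample.int(n - cs + 1L, 1) - 1L
    img <- cpp_resize2d(img[(o1 + 1):(o1 + cs), (o2 + 1):(o2 + cs)], n, n)
  }
  img
}

#' Train the HS2 false-positive-reduction classifier
#'
#' Trains on labelled LHI patches with softmax cross-entropy and SGD with
#' momentum 0.9. The majority class is undersampled to the minority count
#' (`balance`), and random flip / 90-degree rotation / 0.9-crop
#' augmentation is applied per epoch (`augment`). Both classes must be
#' present. Deterministic given `seed`.
#'
#' @param patches list of `lhi_patch` objects (or bare matrices).
#' @param labels parallel vector: `"nodule"`/`"tissue"` or 1/0.
#' @param cfg an [hs2_config()].
#' @param seed integer seed.
#' @return an `hs2_model` with parameters, config and per-epoch loss log.
#' @export
train_hs2 <- function(patches, labels, cfg = hs2_config(), seed = 1L) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "nodule")
  labels <- as.integer(labels)
  if (length(patches) != length(labels))
    stop("train_hs2: patches and labels differ in length")
  if (length(unique(labels)) < 2)
    stop("train_hs2: both classes must be present")
  imgs <- lapply(patches, function(p) if (inherits(p, "lhi_patch")) p$image
                 else p)
  tau <- if (inherits(patches[[1]], "lhi_patch")) patches[[1]]$tau else 10
  in_size <- nrow(imgs[[1]])
  model <- with_seed(seed, {
    idx_pos <- which(labels == 1L)
    idx_neg <- which(labels == 0L)
    if (cfg$balance) {
      n <- min(length(idx_pos), length(idx_neg))
      idx_pos <- if (length(idx_pos) > n) sample(idx_pos, n) else idx_pos
      idx_neg <- if (length(idx_neg) > n) sample(idx_neg, n) else idx_neg
    }
    use <- c(idx_pos, idx_neg)
    par <- hs2_par(cfg, in_size)
    vel <- zero_like(par)
    lr <- cfg$lr
    loss_log <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(use)
      ep_loss <- 0
      for (start in seq(1, length(ord), by = cfg$batch)) {
        sel <- ord[start:min(start + cfg$batch - 1, length(ord))]
        xs <- lapply(sel, function(i) {
          im <- imgs[[i]]
          if (cfg$augment) im <- augment_patch(im)
          hs2_input(im, tau)
        })
        fw <- hs2_fwd(xs, par, train = TRUE)
        par <- fw$par  # running BN stats updated
        gl <- vector("list", length(sel))
        for (i in seq_along(sel)) {
          ce <- softmax_ce(fw$fc[[i]]$logits, labels[sel[i]] + 1L)
          ep_loss <- ep_loss + ce$loss
          gl[[i]] <- ce$grad / length(sel)
        }
        grads <- hs2_bwd(fw, par, gl)
        upd <- sgd_update(par, grads, vel, lr, momentum = 0.9,
                          wd = cfg$weight_decay)
        par <- upd$p
        vel <- upd$v
      }
      loss_log[ep] <- ep_loss / length(ord)
      if (ep %% cfg$lr_decay_every == 0) lr <- lr * cfg$lr_factor
    }
    list(par = par, loss_log = loss_log,
         n_train = c(nodule = length(idx_pos), tissue = length(idx_neg)))
  })
  structure(list(par = model$par, cfg = cfg, loss_log = model$loss_log,
                 n_train = model$n_train, tau = tau, in_size = in_size),
            class = "hs2_model")
}

#' @export
print.hs2_model <- function(x, ...) {
  cat("hs2_model: LHI-based nodule/tissue classifier\n")
  cat(sprintf("  conv %s, fc %s, threshold %.2f\n",
              paste(x$cfg$conv_channels, collapse = "/"),
              paste(x$cfg$fc_widths, collapse = "/"), x$cfg$threshold))
  cat(sprintf("  trained %d epochs, final loss %.4f\n",
              length(x$loss_log), utils::tail(x$loss_log, 1)))
  invisible(x)
}

#' Predict nodule probabilities for LHI patches
#'
#' @param object a trained `hs2_model`.
#' @param patches list of `lhi_patch` objects (or bare matrices).
#' @param ... unused.
#' @return numeric vector of probabilities that each patch shows a nodule.
#' @export
predict.hs2_model <- function(object, patches, ...) {
  imgs <- lapply(patches, function(p) if (inherits(p, "lhi_patch")) p$image
                 else p)
  xs <- lapply(imgs, hs2_input, tau = object$tau)
  fw <- hs2_fwd(xs, object$par, train = FALSE)
  vapply(fw$fc, function(f) softmax(f$logits)[2], numeric(1))
}

#' Filter detector candidates with an HS2 classifier
#'
#' Averages the nodule probability over each candidate's LHI patches (one
#' per difference threshold) and relabels: probability `>= threshold`
#' keeps the candidate (`label = "nodule"`), otherwise it becomes
#' `"tissue"`. Coordinates and scores are never altered and no candidate
#' is added or removed; a candidate without patches keeps the label
#' `"unfiltered"` with a warning.
#'
#' @param cands candidate data.frame.
#' @param patches list parallel to candidate rows; each element a list of
#'   `lhi_patch` for that candidate.
#' @param model a trained `hs2_model`.
#' @param cfg an [hs2_config()] (defaults to the model's, which carries
#'   the decision threshold).
#' @return the candidate data.frame with labels filled in and an
#'   `hs2_prob` column.
#' @export
classify_candidates <- function(cands, patches, model, cfg = model$cfg) {
  if (nrow(cands) != length(patches))
    stop("classify_candidates: one patch list per candidate required")
  out <- cands
  out$hs2_prob <- NA_real_
  flat <- unlist(patches, recursive = FALSE)
  counts <- vapply(patches, length, integer(1))
  if (any(counts == 0))
    warning("classify_candidates: candidate(s) without patches left ",
            "unfiltered")
  if (length(flat)) {
    probs <- predict(model, flat)
    idx <- rep(seq_along(patches), counts)
    avg <- tapply(probs, idx, mean)
    rows <- as.integer(names(avg))
    out$hs2_prob[rows] <- as.numeric(avg)
    out$label[rows] <- ifelse(avg >= cfg$threshold, "nodule", "tissue")
  }
  out
}
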