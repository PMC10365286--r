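#' Synthetic chest-CT phantom specification
#'
#' The phantom generator renders desk-scale, chest-like `GRAY255` volumes on
#' which every pipeline stage can be exercised without any external data.
#' A phantom consists of: an elliptic soft-tissue body cylinder surrounded
#' by air, two dark lung ellipsoids, a bright posterior spine rod (which
#' gives every volume a consistent anatomical orientation, so that axial
#' rotations are identifiable), optional spherical nodules whose
#' cross-section grows and shrinks across slices, optional tubular
#' vessel-like distractors whose cross-section translates across slices,
#' and i.i.d. Gaussian noise clipped to `[0, 255]`.
#'
#' @param shape voxel grid `(nz, ny, nx)`.
#' @param spacing mm per voxel `(x, y, z)`.
#' @param origin world mm of voxel `(0,0,0)`.
#' @param background_level gray level of lung parenchyma.
#' @param noise_sd gray-level standard deviation of the additive noise.
#' @param nodules list of `list(center = c(x, y, z) world mm,
#'   diameter_mm, contrast)`; diameters must lie in `[3, 30]` mm and the
#'   contrast must exceed `noise_sd`.
#' @param vessels list of `list(center = c(x, y) world mm at the central
#'   slice, radius_mm, contrast, drift = c(dx, dy) mm per slice)`.
#' @param body render the body/lung/spine background (disable for plain
#'   uniform backgrounds).
#' @param id scan identifier used in annotation tables.
#' @param seed integer seed; all phantom randomness flows through it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), background_level = 30,
                         noise_sd = 8, nodules = list(), vessels = list(),
                         body = TRUE, id = "phantom", seed = 1L) {
  for (nd in nodules) {
    if (nd$diameter_mm < 3 || nd$diameter_mm > 30)
      stop("phantom_spec: nodule diameters must lie in [3, 30] mm")
    if ((nd$contrast %||% 80) <= noise_sd)
      stop("phantom_spec: nodule contrast must exceed noise_sd")
  }
  for (vs in vessels) {
    if ((vs$contrast %||% 70) <= noise_sd)
      stop("phantom_spec: vessel contrast must exceed noise_sd")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 background_level = background_level, noise_sd = noise_sd,
                 nodules = nodules, vessels = vessels, body = isTRUE(body),
                 id = id, seed = as.integer(seed)),
            class = "phantom_spec")
}

# soft-edged sphere/disc weight: 1 inside, linear ramp of one voxel at edge
soft_edge <- function(dist_mm, radius_mm, ramp_mm) {
  pmin(1, pmax(0, (radius_mm + 0.5 * ramp_mm - dist_mm) / ramp_mm))
}

#' Generate a synthetic CT phantom
#'
#' Renders the volume described by a [phantom_spec()] and returns it with
#' its exact ground-truth annotation table. Deterministic given the spec's
#' seed. Overlapping nodules are rendered anyway with a warning.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = ct_volume GRAY255, annotations = data.frame)` with
#'   one annotation row per requested nodule.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  sp <- spec$spacing  # (x, y, z)
  vol <- array(spec$background_level, dim = c(nz, ny, nx))
  if (spec$body) {
    cy <- (ny - 1) / 2; cx <- (nx - 1) / 2; cz <- (nz - 1) / 2
    # body ellipse in (y, x), air outside, soft tissue inside
    e2 <- outer(((seq_len(ny) - 1 - cy) / (0.46 * ny))^2,
                ((seq_len(nx) - 1 - cx) / (0.48 * nx))^2, "+")
    body2 <- e2 <= 1
    base2 <- ifelse(body2, 170, 12)
    vol <- array(rep(base2, each = nz), dim = c(nz, ny, nx))
    # two lung ellipsoids (dark, parenchyma level)
    az <- 0.47 * nz; ay <- 0.30 * ny; ax <- 0.17 * nx
    zt <- ((seq_len(nz) - 1 - cz) / az)^2
    yt <- ((seq_len(ny) - 1 - (cy - 0.04 * ny)) / ay)^2
    for (side in c(-1, 1)) {
      xt <- ((seq_len(nx) - 1 - (cx + side * 0.22 * nx)) / ax)^2
      inside <- outer(outer(zt, yt, "+"), xt, "+") <= 1
      vol[inside] <- spec$background_level
    }
    # posterior spine rod (orientation cue), all slices
    st <- outer(((seq_len(ny) - 1 - (cy + 0.36 * ny)) / (0.07 * ny))^2,
                ((seq_len(nx) - 1 - cx) / (0.06 * nx))^2, "+") <= 1
    vol[array(rep(st, each = nz), dim = c(nz, ny, nx))] <- 230
  }
  # world coordinates of voxel centres along each axis
  xw <- spec$origin[1] + (seq_len(nx) - 1) * sp[1]
  yw <- spec$origin[2] + (seq_len(ny) - 1) * sp[2]
  zw <- spec$origin[3] + (seq_len(nz) - 1) * sp[3]
  ramp <- min(sp)
  add_blob <- function(vol, cw, radius_mm, contrast, zrange = NULL,
                       centers_per_slice = NULL) {
    # spherical blob, or per-slice disc centres for vessels
    if (is.null(centers_per_slice)) {
      zi <- which(abs(zw - cw[3]) <= radius_mm + 2 * ramp)
      yi <- which(abs(yw - cw[2]) <= radius_mm + 2 * ramp)
      xi <- which(abs(xw - cw[1]) <= radius_mm + 2 * ramp)
      if (!length(zi) || !length(yi) || !length(xi)) return(vol)
      d2 <- outer(outer((zw[zi] - cw[3])^2, (yw[yi] - cw[2])^2, "+"),
                  (xw[xi] - cw[1])^2, "+")
      w <- soft_edge(sqrt(d2), radius_mm, ramp)
      vol[zi, yi, xi] <- vol[zi, yi, xi] + contrast * w
    } else {
      for (z in seq_len(nz)) {
        c2 <- centers_per_slice[z, ]
        yi <- which(abs(yw - c2[2]) <= radius_mm + 2 * ramp)
        xi <- which(abs(xw - c2[1]) <= radius_mm + 2 * ramp)
        if (!length(yi) || !length(xi)) next
        d2 <- outer((yw[yi] - c2[2])^2, (xw[xi] - c2[1])^2, "+")
        w <- soft_edge(sqrt(d2), radius_mm, ramp)
        vol[z, yi, xi] <- vol[z, yi, xi] + contrast * w
      }
    }
    vol
  }
  if (length(spec$nodules) > 1) {
    ctr <- t(vapply(spec$nodules, function(n) n$center, numeric(3)))
    dd <- vapply(spec$nodules, function(n) n$diameter_mm, numeric(1))
    dist <- as.matrix(stats::dist(ctr))
    lim <- outer(dd, dd, "+") / 2
    if (any(dist[upper.tri(dist)] < lim[upper.tri(lim)]))
      warning("generate_phantom: overlapping nodules requested")
  }
  for (nd in spec$nodules)
    vol <- add_blob(vol, nd$center, nd$diameter_mm / 2, nd$contrast %||% 80)
  zc_mid <- (zw[1] + zw[nz]) / 2
  for (vs in spec$vessels) {
    drift <- vs$drift %||% c(1, 0)
    centers <- cbind(vs$center[1] + drift[1] * (zw - zc_mid) / sp[3],
                     vs$center[2] + drift[2] * (zw - zc_mid) / sp[3])
    vol <- add_blob(vol, NULL, vs$radius_mm, vs$contrast %||% 70,
                    centers_per_slice = centers)
  }
  vol <- with_seed(spec$seed,
                   vol + array(rnorm(length(vol), 0, spec$noise_sd),
                               dim = dim(vol)))
  vol <- pmin(pmax(vol, 0), 255)
  dim(vol) <- c(nz, ny, nx)
  ann <- if (length(spec$nodules)) {
    data.frame(seriesuid = spec$id,
               coordX = vapply(spec$nodules, function(n) n$center[1], 0),
               coordY = vapply(spec$nodules, function(n) n$center[2], 0),
               coordZ = vapply(spec$nodules, function(n) n$center[3], 0),
               diameter_mm = vapply(spec$nodules,
                                    function(n) n$diameter_mm, 0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(seriesuid = character(), coordX = numeric(),
               coordY = numeric(), coordZ = numeric(),
               diameter_mm = numeric(), stringsAsFactors = FALSE)
  }
  list(volume = ct_volume(vol, spacing = sp, origin = spec$origin,
                          intensity_space = "GRAY255"),
       annotations = ann)
}

#' Generate an 11-slice candidate sequence
#'
#' Emulates the two slice-stack patterns that distinguish true nodules from
#' vessel-like tissue: a `"nodule"` is a centred disc whose radius follows
#' the circular-cap profile of a sphere intersecting consecutive slices
#' (grows toward the central slice, shrinks away from it); `"tissue"` is a
#' constant-radius disc translating at a fixed per-slice drift. Both are
#' rendered over a uniform background with Gaussian noise.
#'
#' @param kind `"nodule"` or `"tissue"`.
#' @param params optional list: `size` (patch side, px, default 32),
#'   `radius` (sphere/tube radius, px, default 8), `contrast` (default 80),
#'   `background` (default 30), `noise_sd` (default 8), `drift`
#'   (`c(dx, dy)` px/slice for tissue, default `c(2, 0)`), `n_slices`
#'   (default 11).
#' @param seed integer seed.
#' @return a `candidate_sequence`: `list(slices = array (S, H, W),
#'   truth_label, params)`.
#' @export
make_candidate_sequence <- function(kind = c("nodule", "tissue"),
                                    params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(size = 32L, radius = 8, contrast = 80,
                              background = 30, noise_sd = 8,
                              drift = c(2, 0), n_slices = 11L), params)
  S <- p$n_slices; H <- p$size; W <- p$size
  s0 <- (S + 1) / 2
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  stack <- array(p$background, dim = c(S, H, W))
  yy <- seq_len(H) - 1; xx <- seq_len(W) - 1
  for (s in seq_len(S)) {
    if (kind == "nodule") {
      r <- sqrt(max(0, p$radius^2 - (s - s0)^2))
      c2 <- c(cx, cy)
    } else {
      r <- p$radius
      c2 <- c(cx + p$drift[1] * (s - s0), cy + p$drift[2] * (s - s0))
    }
    if (r <= 0) next
    d <- sqrt(outer((yy - c2[2])^2, (xx - c2[1])^2, "+"))
    stack[s, , ] <- stack[s, , ] + p$contrast * soft_edge(d, r, 1)
  }
  stack <- with_seed(seed,
                     stack + array(rnorm(length(stack), 0, p$noise_sd),
                                   dim = dim(stack)))
  stack <- pmin(pmax(stack, 0), 255)
  dim(stack) <- c(S, H, W)
  structure(list(slices = stack, truth_label = kind, params = p),
            class = "candidate_sequence")
}
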