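#' Location History Image configuration
#'
#' A Location History Image (LHI) records, per pixel, a decaying history of
#' supra-threshold intensity change across consecutive CT slices: where the
#' absolute difference between two consecutive slices exceeds
#' `diff_threshold` the history is reset to the ceiling `tau`, elsewhere it
#' decays by 1 per slice (floored at 0). True nodules produce a concentric
#' pattern (their cross-section grows/shrinks around a fixed centre) while
#' vessel-like tissue produces a directional trail (its cross-section
#' translates from slice to slice).
#'
#' @param tau decay ceiling; default 10, the number of slice pairs in an
#'   11-slice stack.
#' @param diff_thresholds gray-level difference thresholds; the defaults
#'   `c(30, 40)` yield two LHI variants per candidate, used as data
#'   augmentation.
#' @param patch_scale patch side as a multiple of the candidate diameter
#'   in y and x (default 2).
#' @param out_size output LHI side in pixels after resizing (default 48).
#' @param half_depth slices taken before and after the candidate's central
#'   slice (default 5, giving an 11-slice stack).
#' @return an `lhi_config` list.
#' @export
lhi_config <- function(tau = 10, diff_thresholds = c(30, 40),
                       patch_scale = 2, out_size = 48, half_depth = 5) {
  if (tau < 1) stop("lhi_config: tau must be >= 1")
  if (any(diff_thresholds <= 0))
    stop("lhi_config: diff thresholds must be positive")
  structure(list(tau = tau, diff_thresholds = diff_thresholds,
                 patch_scale = patch_scale, out_size = out_size,
                 half_depth = half_depth),
            class = "lhi_config")
}

#' Compute a Location History Image
#'
#' Per-pixel recurrence over a stack of S aligned slices: the history `f`
#' starts at 0; for each consecutive pair, pixels whose absolute difference
#' strictly exceeds `threshold` are set to `tau`, all others decay as
#' `max(0, f - 1)`. Returns the final history image with values in
#' `[0, tau]`.
#'
#' @param stack slice stack: a 3D array `(S, H, W)` or a list of S
#'   equally-sized matrices, `S >= 2`.
#' @param threshold gray-level difference threshold (strict inequality).
#' @param tau decay ceiling.
#' @return an `H x W` matrix in `[0, tau]`.
#' @export
compute_lhi <- function(stack, threshold = 30, tau = 10) {
  if (is.list(stack)) {
    dims <- lapply(stack, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      stop("compute_lhi: all slices must share one shape")
    S <- length(stack)
    get <- function(s) stack[[s]]
  } else {
    S <- dim(stack)[1]
    get <- function(s) {
      m <- stack[s, , ]
      dim(m) <- dim(stack)[2:3]
      m
    }
  }
  if (S < 2) stop("compute_lhi: need at least 2 slices")
  f <- matrix(0, nrow(get(1)), ncol(get(1)))
  prev <- get(1)
  for (s in 2:S) {
    cur <- get(s)
    fire <- abs(cur - prev) > threshold
    f <- ifelse(fire, tau, pmax(0, f - 1))
    prev <- cur
  }
  f
}

#' Extract LHI patches for a detected candidate
#'
#' Crops an 11-slice stack centred on the candidate (`half_depth` slices
#' each side, zero-padded at volume borders) over a square patch twice the
#' candidate diameter in y and x, computes one LHI per configured
#' difference threshold, and resizes each to `out_size` (bilinear, on the
#' float-valued LHI).
#'
#' @param vol a `GRAY255` `ct_volume`.
#' @param cand one-row candidate data.frame (world mm + `diameter_mm`).
#' @param cfg an [lhi_config()].
#' @return list of `lhi_patch` objects (`image`, `threshold`, `tau`).
#' @export
extract_lhi_patch <- function(vol, cand, cfg = lhi_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  v <- world_to_voxel(c(cand$coordX, cand$coordY, cand$coordZ), vol)
  d <- dim(vol$data)
  zc <- min(max(round_half_up(v[3]), 0), d[1] - 1)
  side <- max(8L, as.integer(round_half_up(
    cfg$patch_scale * cand$diameter_mm / vol$spacing[1])))
  half <- side / 2
  y0 <- as.integer(floor(v[2] - half + 0.5))
  x0 <- as.integer(floor(v[1] - half + 0.5))
  S <- 2L * cfg$half_depth + 1L
  stack <- array(0, dim = c(S, side, side))
  for (s in seq_len(S)) {
    z <- zc - cfg$half_depth + (s - 1)
    if (z < 0 || z >= d[1]) next  # zero-padded slice
    yy <- (y0 + 1):(y0 + side)
    xx <- (x0 + 1):(x0 + side)
    yok <- yy >= 1 & yy <= d[2]
    xok <- xx >= 1 & xx <= d[3]
    if (!any(yok) || !any(xok)) next
    stack[s, which(yok), which(xok)] <-
      vol$data[z + 1, yy[yok], xx[xok]]
  }
  lapply(cfg$diff_thresholds, function(thr) {
    lhi <- compute_lhi(stack, thr, cfg$tau)
    img <- cpp_resize2d(lhi, cfg$out_size, cfg$out_size)
    structure(list(image = img, threshold = thr, tau = cfg$tau),
              class = "lhi_patch")
  })
}

# LHI patches for a candidate table; returns a list (one element per
# candidate) of lists of lhi_patch
extract_lhi_patches <- function(vol, cands, cfg = lhi_config()) {
  lapply(seq_len(nrow(cands)), function(i)
    extract_lhi_patch(vol, cands[i, , drop = FALSE], cfg))
}

# LHI of a candidate_sequence (one image per configured threshold)
sequence_lhi <- function(seq, cfg = lhi_config()) {
  lapply(cfg$diff_thresholds, function(thr) {
    lhi <- compute_lhi(seq$slices, thr, cfg$tau)
    img <- cpp_resize2d(lhi, cfg$out_size, cfg$out_size)
    structure(list(image = img, threshold = thr, tau = cfg$tau),
              class = "lhi_patch")
  })
}
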