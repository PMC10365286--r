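#' Preprocessing configuration
#'
#' CT volumes are prepared for detection by (i) windowing Hounsfield units
#' into `[0, 255]` gray values with a linear map over `hu_window`
#' (default `[-1200, 600]` HU, wide enough for lung parenchyma through
#' calcifications), (ii) resampling to an isotropic grid at
#' `target_spacing` mm (default 1 mm) and (iii) optionally masking the lung
#' region with a classical threshold/connected-component pipeline.
#'
#' @param hu_window length-2 numeric `(low, high)` HU.
#' @param target_spacing positive scalar, mm per voxel after resampling.
#' @param mask_enabled logical, run lung masking in the pipeline.
#' @param mask_threshold gray level below which a (smoothed) voxel counts as
#'   low density; 115 corresponds to roughly -390 HU under the default
#'   window, separating aerated lung from soft tissue.
#' @param mask_crop logical; `FALSE` zeroes non-lung voxels, `TRUE` also
#'   crops the volume to the mask bounding box.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(hu_window = c(-1200, 600), target_spacing = 1,
                              mask_enabled = FALSE, mask_threshold = 115,
                              mask_crop = FALSE) {
  if (length(hu_window) != 2 || hu_window[1] >= hu_window[2])
    stop("preprocess_config: hu_window must satisfy low < high")
  if (target_spacing <= 0)
    stop("preprocess_config: target_spacing must be > 0")
  structure(list(hu_window = as.numeric(hu_window),
                 target_spacing = as.numeric(target_spacing),
                 mask_enabled = isTRUE(mask_enabled),
                 mask_threshold = mask_threshold,
                 mask_crop = isTRUE(mask_crop)),
            class = "preprocess_config")
}

#' Window Hounsfield units to gray values
#'
#' Applies `g = clip(round(255 (h - low) / (high - low)), 0, 255)` with
#' round-half-up, producing a `GRAY255` volume. Monotone non-decreasing in
#' the input intensity.
#'
#' @param vol a `ct_volume` in HU space.
#' @param cfg a [preprocess_config()].
#' @return the windowed `ct_volume` (`GRAY255`).
#' @export
hu_to_gray <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity_space != "HU")
    stop("hu_to_gray: input must be in HU intensity space")
  lo <- cfg$hu_window[1]; hi <- cfg$hu_window[2]
  g <- round_half_up(255 * (vol$data - lo) / (hi - lo))
  g <- pmin(pmax(g, 0), 255)
  dim(g) <- dim(vol$data)
  ct_volume(g, spacing = vol$spacing, origin = vol$origin,
            intensity_space = "GRAY255")
}

#' Resample a volume to an isotropic grid
#'
#' Trilinear interpolation onto a grid with `target_spacing` mm on every
#' axis. The output axis lengths are `round(n * spacing / target)` so the
#' physical extent is preserved to within one output voxel; the origin
#' (centre of voxel 0) is unchanged. A volume already at the target spacing
#' is returned untouched.
#'
#' @param vol a `ct_volume`.
#' @param cfg a [preprocess_config()].
#' @param nearest logical, nearest-neighbour instead of trilinear (used for
#'   label masks).
#' @return the resampled `ct_volume`.
#' @export
resample_isotropic <- function(vol, cfg = preprocess_config(),
                               nearest = FALSE) {
  stopifnot(inherits(vol, "ct_volume"))
  t <- cfg$target_spacing
  if (!is.finite(t) || t <= 0) stop("resample_isotropic: bad target spacing")
  sp_zyx <- rev(vol$spacing)
  if (all(abs(sp_zyx - t) < 1e-9)) return(vol)
  d <- dim(vol$data)
  od <- pmax(1L, as.integer(round_half_up(d * sp_zyx / t)))
  ratio <- t / sp_zyx
  out <- cpp_resample3d(vol$data, d, od, ratio, as.integer(nearest))
  v <- ct_volume(out, spacing = c(t, t, t), origin = vol$origin,
                 intensity_space = "HU")
  v$intensity_space <- vol$intensity_space  # payload flag carried over
  v
}

#' Extract a lung mask from a gray-windowed volume
#'
#' Classical pipeline: Gaussian smoothing, low-density thresholding, 3D
#' connected-component extraction keeping interior low-density components
#' (air outside the body is removed by discarding components that touch the
#' lateral volume borders), then morphological closing. Returns a binary
#' `[z, y, x]` array. If no lung-like component is found the mask is empty
#' and a warning is emitted.
#'
#' @param vol a `GRAY255` `ct_volume`.
#' @param cfg a [preprocess_config()].
#' @param sigma Gaussian smoothing sd in voxels.
#' @return integer array of 0/1 with the volume's dimensions.
#' @export
lung_mask <- function(vol, cfg = preprocess_config(), sigma = 1) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity_space != "GRAY255")
    stop("lung_mask: input must be GRAY255 (window HU first)")
  d <- dim(vol$data)
  sm <- cpp_gauss3d(vol$data, d, rep(sigma, 3))
  low <- array(as.integer(sm < cfg$mask_threshold), dim = d)
  lab <- cpp_label3d(low, d)
  if (max(lab) == 0L) {
    warning("lung_mask: no low-density component found; empty mask")
    return(array(0L, dim = d))
  }
  # drop components touching the lateral (y/x) borders: outside-body air
  border <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  border <- setdiff(border, 0L)
  sizes <- tabulate(lab)
  keep <- setdiff(which(sizes >= max(8, 0.001 * prod(d))), border)
  if (!length(keep)) {
    warning("lung_mask: no interior low-density component; empty mask")
    return(array(0L, dim = d))
  }
  mask <- array(as.integer(lab %in% keep), dim = d)
  mask <- cpp_morph3d(mask, d, 1L, 1L)  # closing: dilate ...
  mask <- cpp_morph3d(mask, d, 1L, 0L)  # ... then erode
  # closing must not leak outside the thresholded body envelope's dilation
  array(as.integer(mask & cpp_morph3d(low, d, 1L, 1L)), dim = d)
}

#' Apply a lung mask to a volume
#'
#' Voxels outside the mask are set to 0; with `crop = TRUE` the volume is
#' additionally cropped to the mask bounding box (origin updated).
#'
#' @param vol a `ct_volume`.
#' @param mask binary array matching `vol`.
#' @param crop logical.
#' @return the masked `ct_volume`.
#' @export
apply_mask <- function(vol, mask, crop = FALSE) {
  stopifnot(inherits(vol, "ct_volume"), all(dim(mask) == dim(vol$data)))
  out <- vol$data * (mask != 0)
  if (crop && any(mask != 0)) {
    idx <- which(mask != 0, arr.ind = TRUE)
    lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
    out <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    new_origin <- vol$origin + (rev(lo) - 1) * vol$spacing
    return(ct_volume(out, spacing = vol$spacing, origin = new_origin,
                     intensity_space = vol$intensity_space))
  }
  ct_volume(out, spacing = vol$spacing, origin = vol$origin,
            intensity_space = vol$intensity_space)
}
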