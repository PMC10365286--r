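#' CT volume container
#'
#' A `ct_volume` bundles a 3D intensity grid with its geometry. The grid is
#' stored as an array indexed `[z, y, x]`; `spacing` and `origin` are given
#' in world millimetres in `(x, y, z)` order, matching the annotation CSV
#' convention. `origin` is the world position of the centre of voxel
#' `(0, 0, 0)`. Two intensity spaces are supported: calibrated Hounsfield
#' units (`"HU"`) and windowed grayscale in `[0, 255]` (`"GRAY255"`).
#'
#' @param data numeric 3D array with dim `(nz, ny, nx)`.
#' @param spacing positive numeric length 3, mm per voxel, `(x, y, z)` order.
#' @param origin numeric length 3, world mm of voxel `(0,0,0)`, `(x, y, z)`.
#' @param intensity_space `"HU"` or `"GRAY255"`.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      intensity_space = c("HU", "GRAY255")) {
  intensity_space <- match.arg(intensity_space)
  if (length(dim(data)) != 3L)
    stop("ct_volume: `data` must have exactly three axes (z, y, x)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: spacing must be strictly positive on all axes")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("ct_volume: origin must be finite length-3")
  if (intensity_space == "GRAY255") {
    rng <- range(data)
    if (rng[1] < -1e-9 || rng[2] > 255 + 1e-9)
      stop("ct_volume: GRAY255 data must lie in [0, 255]")
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 intensity_space = intensity_space),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ct_volume: %d x %d x %d voxels (z,y,x), %s\n",
              d[1], d[2], d[3], x$intensity_space))
  cat(sprintf("  spacing (x,y,z): %s mm\n",
              paste(signif(x$spacing, 6), collapse = " x ")))
  cat(sprintf("  origin  (x,y,z): %s mm\n",
              paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  intensity range: [%.1f, %.1f]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Convert world coordinates to continuous voxel indices
#'
#' Voxel indices are 0-based and continuous: `voxel = (p - origin) / spacing`
#' per axis. Out-of-grid positions are allowed (and flagged via the
#' `"inside"` attribute); no rounding is applied.
#'
#' @param p numeric world point(s) `(x, y, z)` in mm; a length-3 vector or an
#'   `n x 3` matrix.
#' @param vol a [ct_volume].
#' @return voxel indices in `(x, y, z)` order, same shape as `p`, with an
#'   `"inside"` logical attribute marking points within the grid.
#' @export
world_to_voxel <- function(p, vol) {
  pm <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  v <- sweep(sweep(pm, 2, vol$origin, "-"), 2, vol$spacing, "/")
  nmax <- rev(dim(vol$data)) - 1  # (nx, ny, nz)
  inside <- v[, 1] >= 0 & v[, 1] <= nmax[1] &
            v[, 2] >= 0 & v[, 2] <= nmax[2] &
            v[, 3] >= 0 & v[, 3] <= nmax[3]
  out <- if (is.matrix(p)) v else drop(v)
  attr(out, "inside") <- inside
  out
}

#' Convert continuous voxel indices to world coordinates
#'
#' Inverse of [world_to_voxel()]: `p = origin + voxel * spacing`.
#'
#' @param v voxel indices `(x, y, z)`, length-3 vector or `n x 3` matrix.
#' @param vol a [ct_volume].
#' @return world mm coordinates, same shape as `v`.
#' @export
voxel_to_world <- function(v, vol) {
  vm <- if (is.matrix(v)) matrix(as.numeric(v), nrow(v), 3) else
    matrix(as.numeric(v), ncol = 3)
  p <- sweep(sweep(vm, 2, vol$spacing, "*"), 2, vol$origin, "+")
  if (is.matrix(v)) p else drop(p)
}
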