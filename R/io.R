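#' Read a CT volume from disk
#'
#' Supports MetaImage (`.mhd` + raw payload) and NIfTI (`.nii`, `.nii.gz`).
#' Only axis-aligned volumes are supported: a MetaImage `TransformMatrix`
#' other than identity, or a NIfTI xform with off-diagonal rotation terms,
#' raises an unsupported-format error. The returned grid is indexed
#' `[z, y, x]`; spacing and origin are taken from the header and reported in
#' `(x, y, z)` mm. Intensities are assumed calibrated (`intensity_space`
#' `"HU"`) unless the header payload is 8-bit, which is read as `"GRAY255"`.
#'
#' @param path file path to a `.mhd`, `.nii` or `.nii.gz` volume.
#' @return a [ct_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("load_volume: file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.mhd$", lower)) return(read_mhd(path))
  if (grepl("\\.nii(\\.gz)?$", lower)) return(read_nifti_vol(path))
  stop("load_volume: unsupported format (expect .mhd or .nii/.nii.gz): ", path)
}

#' Write a CT volume to disk
#'
#' Format is chosen by extension (`.mhd` or `.nii`/`.nii.gz`). MetaImage is
#' written as MET_DOUBLE so that write -> read round-trips bit-exactly.
#'
#' @param vol a [ct_volume].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  lower <- tolower(path)
  if (grepl("\\.mhd$", lower)) {
    write_mhd(vol, path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    write_nifti_vol(vol, path)
  } else {
    stop("write_volume: unsupported format: ", path)
  }
  invisible(path)
}

mhd_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_FLOAT = "double",
               MET_DOUBLE = "double")
mhd_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
               MET_INT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 "")
  vals <- vapply(kv, function(m) if (length(m) == 3) trimws(m[3]) else
                 NA_character_, "")
  hdr <- stats::setNames(vals[!is.na(keys)], keys[!is.na(keys)])
  need <- c("DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(hdr)))
    stop("read_mhd: malformed header, missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (!is.null(hdr["CompressedData"]) && !is.na(hdr["CompressedData"]) &&
      tolower(hdr["CompressedData"]) == "true")
    stop("read_mhd: compressed MetaImage not supported")
  if ("TransformMatrix" %in% names(hdr)) {
    tm <- as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1]])
    if (length(tm) != 9 || any(abs(tm - c(1,0,0,0,1,0,0,0,1)) > 1e-6))
      stop("read_mhd: non-identity orientation not supported")
  }
  dimsize <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])  # nx ny nz
  if (length(dimsize) != 3) stop("read_mhd: only 3D volumes supported")
  spacing <- if ("ElementSpacing" %in% names(hdr))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if ("Offset" %in% names(hdr))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  etype <- hdr[["ElementType"]]
  if (!etype %in% names(mhd_types))
    stop("read_mhd: unsupported ElementType ", etype)
  msb <- "BinaryDataByteOrderMSB" %in% names(hdr) &&
    tolower(hdr[["BinaryDataByteOrderMSB"]]) == "true"
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL"))
    stop("read_mhd: inline LOCAL payload not supported")
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath)) stop("read_mhd: payload not found: ", rawpath)
  n <- prod(dimsize)
  con <- file(rawpath, "rb")
  on.exit(close(con))
  what <- mhd_types[[etype]]
  size <- mhd_sizes[[etype]]
  signed <- !etype %in% c("MET_UCHAR", "MET_USHORT")
  v <- readBin(con, what = what, n = n, size = size, signed = signed,
               endian = if (msb) "big" else "little")
  if (length(v) != n) stop("read_mhd: payload truncated")
  arr <- aperm(array(as.double(v), dim = dimsize), c(3, 2, 1))  # -> (z,y,x)
  space <- if ("IntensitySpace" %in% names(hdr))
    hdr[["IntensitySpace"]]
  else if (mhd_sizes[[etype]] == 1) "GRAY255" else "HU"
  ct_volume(arr, spacing = spacing, origin = origin, intensity_space = space)
}

write_mhd <- function(vol, path) {
  rawname <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(vol$data)  # (nz, ny, nx)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(vol$origin, digits = 17),
                                   collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 17),
                                           collapse = " ")),
           paste("DimSize =", d[3], d[2], d[1]),
           "ElementType = MET_DOUBLE",
           paste("IntensitySpace =", vol$intensity_space),
           paste("ElementDataFile =", rawname))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(as.double(aperm(vol$data, c(3, 2, 1))), con, size = 8,
           endian = "little")
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot[upper.tri(rot) | lower.tri(rot)]) > 1e-4) ||
      any(diag(rot) < 0))
    stop("read_nifti: non-axis-aligned orientation not supported")
  arr_xyz <- as.array(img)
  if (length(dim(arr_xyz)) != 3) stop("read_nifti: only 3D volumes supported")
  descrip <- RNifti::niftiHeader(img)$descrip
  space <- if (identical(descrip, "GRAY255")) "GRAY255" else "HU"
  ct_volume(aperm(arr_xyz, c(3, 2, 1)),
            spacing = RNifti::pixdim(img)[1:3],
            origin = xf[1:3, 4],
            intensity_space = space)
}

write_nifti_vol <- function(vol, path) {
  img <- RNifti::asNifti(aperm(vol$data, c(3, 2, 1)))
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img$descrip <- vol$intensity_space  # payload flag survives the round trip
  RNifti::writeNifti(img, path, datatype = "double")
}

#' Read nodule annotations (LUNA16 CSV dialect)
#'
#' Expects columns `seriesuid, coordX, coordY, coordZ, diameter_mm` with
#' world-mm coordinates. Rows are returned as a data frame ordered as on
#' disk; group per scan with `split(ann, ann$seriesuid)`.
#'
#' @param path CSV file path.
#' @return data.frame with the five canonical columns.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("load_annotations: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("load_annotations: missing column(s): ", paste(miss, collapse = ", "))
  for (col in need[-1]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("load_annotations: non-numeric ", col, " at row ", bad[1])
    df[[col]] <- v
  }
  if (nrow(df) && any(df$diameter_mm <= 0))
    stop("load_annotations: diameter_mm must be > 0")
  df[, need]
}

#' Read a candidate list CSV
#'
#' Columns `seriesuid, coordX, coordY, coordZ, diameter_mm, score, label`;
#' `label` is one of `unfiltered`, `nodule`, `tissue` (defaults to
#' `unfiltered` when the column is absent), `score` must lie in `[0, 1]`.
#'
#' @param path CSV file path.
#' @return data.frame of candidates.
#' @export
load_candidates <- function(path) {
  if (!file.exists(path)) stop("load_candidates: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("load_candidates: missing column(s): ", paste(miss, collapse = ", "))
  if (!"label" %in% names(df)) df$label <- "unfiltered"
  if (nrow(df) && (any(df$score < 0) || any(df$score > 1)))
    stop("load_candidates: scores must lie in [0, 1]")
  if (!all(df$label %in% c("unfiltered", "nodule", "tissue")))
    stop("load_candidates: labels must be unfiltered/nodule/tissue")
  df[, c(need, "label")]
}

#' Write a candidate list CSV
#'
#' @param cands candidate data.frame (see [load_candidates()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(cands, path) {
  write.csv(cands, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an annotations CSV
#'
#' @param ann annotation data.frame (see [load_annotations()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
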