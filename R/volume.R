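#' Construct a volume
#'
#' A `cmb_volume` bundles a 3D intensity array with the 4x4 affine that maps
#' 0-based homogeneous voxel indices to world RAS+ millimetre coordinates,
#' the convention used by NIfTI-1. Voxel spacing is derived from the affine
#' column norms.
#'
#' @param data 3D numeric array of finite intensities.
#' @param affine 4x4 invertible matrix, voxel (0-based) to RAS+ mm.
#' @return An object of class `cmb_volume` with elements `data` and `affine`.
#' @export
cmb_volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("`affine` must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps^0.5)
    stop("`affine` must be invertible")
  structure(list(data = data, affine = affine), class = "cmb_volume")
}

#' @export
print.cmb_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cmb_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(voxel_spacing(x), 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.cmb_volume <- function(x) dim(x$data)

#' Voxel spacing in millimetres
#'
#' @param volume a `cmb_volume`.
#' @return Numeric length-3 vector, mm per voxel along each axis.
#' @export
voxel_spacing <- function(volume) {
  sqrt(colSums(volume$affine[1:3, 1:3]^2))
}

#' Read a NIfTI-1 volume
#'
#' Reads `.nii` or `.nii.gz` through RNifti and returns a [cmb_volume()]
#' carrying the file's xform affine (voxel-to-RAS+, 0-based indices).
#'
#' @param path path to a NIfTI-1 file.
#' @return A `cmb_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  cmb_volume(array(as.numeric(img), dim = dim(img)[1:3]), aff)
}

#' Write a NIfTI-1 volume
#'
#' @param volume a `cmb_volume`.
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "cmb_volume"))
  # sform carries a full (possibly non-orthogonal) affine; the qform
  # quaternion representation cannot, so only the sform is written
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert world RAS+ coordinates to voxel indices
#'
#' Applies the inverse affine and rounds to the nearest integer voxel
#' (ties to even, the R rounding rule). Indices are 0-based.
#'
#' @param points numeric length-3 vector or n x 3 matrix of RAS+ mm points.
#' @param affine 4x4 voxel-to-world affine.
#' @param dim optional volume dimensions; when given, an `in_bounds`
#'   logical attribute flags converted indices that fall inside the grid.
#' @return Integer vector or n x 3 integer matrix of 0-based voxel indices.
#' @export
ras_to_voxel <- function(points, affine, dim = NULL) {
  affine <- as.matrix(affine)
  if (abs(det(affine)) < .Machine$double.eps^0.5)
    stop("affine is singular; cannot convert RAS to voxel")
  vec <- is.null(base::dim(points))
  pts <- if (vec) matrix(as.numeric(points), nrow = 1L) else as.matrix(points)
  if (ncol(pts) != 3L) stop("points must have 3 coordinates")
  hom <- rbind(t(pts), 1)
  vox <- solve(affine, hom)[1:3, , drop = FALSE]
  idx <- round(t(vox))
  storage.mode(idx) <- "integer"
  inb <- NULL
  if (!is.null(dim)) {
    inb <- idx[, 1] >= 0L & idx[, 1] < dim[1] &
           idx[, 2] >= 0L & idx[, 2] < dim[2] &
           idx[, 3] >= 0L & idx[, 3] < dim[3]
  }
  if (vec) {
    out <- idx[1, ]
    if (!is.null(inb)) attr(out, "in_bounds") <- inb[1]
    return(out)
  }
  if (!is.null(inb)) attr(idx, "in_bounds") <- inb
  idx
}

#' Convert voxel indices to world RAS+ coordinates
#'
#' @param index numeric length-3 vector or n x 3 matrix of 0-based voxels.
#' @param affine 4x4 voxel-to-world affine.
#' @return Numeric vector or n x 3 matrix of RAS+ mm coordinates.
#' @export
voxel_to_ras <- function(index, affine) {
  affine <- as.matrix(affine)
  vec <- is.null(base::dim(index))
  idx <- if (vec) matrix(as.numeric(index), nrow = 1L) else as.matrix(index)
  if (ncol(idx) != 3L) stop("index must have 3 coordinates")
  w <- t((affine %*% rbind(t(idx), 1))[1:3, , drop = FALSE])
  if (vec) w[1, ] else w
}

#' Standardise volume intensities
#'
#' Rescales the whole volume to zero mean and unit variance (population
#' standard deviation, i.e. divisor n), the normalisation applied before
#' patch extraction. The affine is unchanged.
#'
#' @param volume a `cmb_volume`.
#' @return A `cmb_volume` with standardised intensities.
#' @export
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "cmb_volume"))
  x <- volume$data
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev < .Machine$double.eps^0.5)
    stop("cannot normalise a constant volume (zero variance)")
  cmb_volume((x - mu) / sdev, volume$affine)
}

ANNOT_HEADER <- c("scan_id", "x", "y", "z", "coord_space", "kind")

#' Read a lesion annotation table
#'
#' The CSV schema is `scan_id,x,y,z,coord_space,kind` with
#' `coord_space` in `{ras, voxel}` (`voxel` coordinates are 0-based) and
#' `kind` in `{cmb, mimic}`.
#'
#' @param path CSV path.
#' @return A data.frame with the columns above.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, ANNOT_HEADER))
    stop("bad annotation header: expected ",
         paste(ANNOT_HEADER, collapse = ","))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(scan_id = "character"))
  for (col in c("x", "y", "z")) {
    bad <- which(!is.finite(tab[[col]]))
    if (length(bad))
      stop("non-numeric coordinate in column '", col, "' at row ", bad[1])
  }
  bad_space <- which(!tab$coord_space %in% c("ras", "voxel"))
  if (length(bad_space))
    stop("unknown coord_space '", tab$coord_space[bad_space[1]],
         "' at row ", bad_space[1])
  bad_kind <- which(!tab$kind %in% c("cmb", "mimic"))
  if (length(bad_kind))
    stop("unknown kind '", tab$kind[bad_kind[1]], "' at row ", bad_kind[1])
  tab
}

#' Write a lesion annotation table
#'
#' @param table data.frame with columns `scan_id,x,y,z,coord_space,kind`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path) {
  if (nrow(table)) {
    if (!all(ANNOT_HEADER %in% names(table)))
      stop("annotation table must have columns ",
           paste(ANNOT_HEADER, collapse = ","))
    table <- table[, ANNOT_HEADER]
  } else {
    table <- as.data.frame(setNames(rep(list(character(0)), 6), ANNOT_HEADER))
  }
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
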