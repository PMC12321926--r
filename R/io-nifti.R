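# NIfTI I/O via RNifti. The package's canonical frame is dim1 superior ->
# inferior, dim2 anterior -> posterior, dim3 right -> left; in RAS terms the
# array axes point (I, P, L), so the canonical affine has columns
# (0,0,-s1), (0,-s2,0), (-s3,0,0).

canonical_affine <- function(d, sp) {
  m <- matrix(0, 4, 4)
  m[3, 1] <- -sp[1]
  m[2, 2] <- -sp[2]
  m[1, 3] <- -sp[3]
  m[4, 4] <- 1
  # place the world origin at the last voxel so coordinates stay positive
  m[1:3, 4] <- c(sp[3] * (d[3] - 1), sp[2] * (d[2] - 1), sp[1] * (d[1] - 1))
  m
}

as_canonical_nifti <- function(arr, sp) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  aff <- structure(canonical_affine(dim(arr), sp), code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  img
}

#' Write a CT volume to NIfTI-1
#'
#' @param volume A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- as_canonical_nifti(volume$voxels, volume$spacing)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Write a binary or label mask to NIfTI-1
#'
#' @param mask Logical or integer 3-D array, or an `airway_mask` (its label
#'   map is written: 0 background, 1 main passage, 2+ isolated regions).
#' @param path Output path.
#' @param spacing Voxel spacing in mm; taken from the mask object when
#'   available.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = NULL) {
  if (inherits(mask, "airway_mask")) {
    arr <- mask$labels
    spacing <- mask$spacing
  } else {
    arr <- mask
  }
  if (is.null(spacing)) stop("`spacing` is required for plain arrays")
  storage.mode(arr) <- "integer"
  img <- as_canonical_nifti(arr, spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

decompose_affine <- function(aff) {
  lin3 <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(lin3^2))
  if (any(spacing <= 0)) stop("affine has a zero-length axis")
  axes <- integer(3); signs <- integer(3)
  for (j in 1:3) {
    col <- lin3[, j] / spacing[j]
    i <- which.max(abs(col))
    if (any(abs(col[-i]) > 1e-3))
      stop("oblique acquisition: the affine is not axis-aligned; ",
           "resample the image to an axis-aligned grid first")
    axes[j] <- i
    signs[j] <- sign(col[i])
  }
  if (length(unique(axes)) != 3L) stop("degenerate affine")
  list(spacing = spacing, axes = axes, signs = signs)
}

# Reorder an array whose dims point along RAS axes `axes` with signs `signs`
# into the canonical (I, P, L) frame.
canonicalize_array <- function(arr, axes, signs, spacing) {
  # canonical target: dim1 ~ RAS z with sign -1, dim2 ~ y sign -1, dim3 ~ x sign -1
  target_axis <- c(3L, 2L, 1L)
  perm <- match(target_axis, axes)
  arr <- aperm(arr, perm)
  spacing <- spacing[perm]
  signs <- signs[perm]
  idx <- lapply(seq_len(3L), function(k) {
    if (signs[k] == -1) seq_len(dim(arr)[k]) else rev(seq_len(dim(arr)[k]))
  })
  arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  list(arr = arr, spacing = spacing)
}

#' Read a NIfTI volume into the canonical anatomical frame
#'
#' Accepts any axis-aligned acquisition (including negative-spacing /
#' flipped affines, which are reordered to the canonical frame); oblique
#' affines are rejected.
#'
#' @param path Path to a 3-D NIfTI file holding Hounsfield units.
#' @return A [ct_volume()].
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions")
  dec <- decompose_affine(RNifti::xform(img))
  can <- canonicalize_array(arr, dec$axes, dec$signs, dec$spacing)
  ct_volume(clamp_hu(can$arr), can$spacing,
            meta = list(source = path))
}

#' Read a NIfTI mask into the canonical frame
#'
#' @param path Path to a 3-D NIfTI label or binary mask.
#' @return A list with `voxels` (integer array) and `spacing` (mm).
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D mask, got ", length(dim(arr)), " dimensions")
  dec <- decompose_affine(RNifti::xform(img))
  can <- canonicalize_array(arr, dec$axes, dec$signs, dec$spacing)
  arr <- can$arr
  storage.mode(arr) <- "integer"
  list(voxels = arr, spacing = can$spacing)
}
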