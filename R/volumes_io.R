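# NIfTI volume I/O, lesion-centred cube extraction and paste-back.
#
# Coordinates are 0-based voxel indices; a cube's origin is its inclusive
# lower corner in the source volume and all ranges are half-open.

#' Load an image/mask NIfTI pair
#'
#' The mask is binarized (`> 0.5` becomes 1); spacing and affine are taken
#' from the image header.
#'
#' @param image_path,mask_path NIfTI (.nii / .nii.gz) file paths.
#' @return a `volume_pair`: list with `image` (3D array), `mask` (binary
#'   integer array), `voxel_spacing` (mm triple) and `affine` (4x4).
#' @export
load_volume_pair <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(msk)
  if (length(di) != 3L || length(dm) != 3L)
    stop("inputs must be 3D volumes (got ", length(di), "D image, ",
         length(dm), "D mask)")
  if (!all(di == dm))
    stop("image/mask shape mismatch: image ", paste(di, collapse = "x"),
         " vs mask ", paste(dm, collapse = "x"))
  spacing <- RNifti::pixdim(img)[1:3]
  structure(list(image = array(as.numeric(img), di),
                 mask = array(as.integer(msk > 0.5), dm),
                 voxel_spacing = as.numeric(spacing),
                 affine = structure(as.matrix(RNifti::xform(img)), dim = c(4L, 4L))),
            class = "volume_pair")
}

#' Write a volume pair to NIfTI files
#'
#' The mask is written as uint8; both files carry the pair's affine.
#'
#' @param pair a `volume_pair`.
#' @param image_path,mask_path output paths.
#' @export
write_volume_pair <- function(pair, image_path, mask_path) {
  img <- RNifti::asNifti(pair$image)
  img <- RNifti::`sform<-`(img, structure(pair$affine, code = 2L))
  RNifti::writeNifti(img, image_path)
  msk <- RNifti::asNifti(array(as.integer(pair$mask), dim(pair$mask)),
                         datatype = "uint8")
  msk <- RNifti::`sform<-`(msk, structure(pair$affine, code = 2L))
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}

#' Build a volume pair from arrays
#'
#' @param image 3D numeric array.
#' @param mask 3D binary array of the same shape.
#' @param voxel_spacing mm triple.
#' @param affine 4x4 transform; defaults to a scaled identity.
#' @export
volume_pair <- function(image, mask, voxel_spacing = c(1, 1, 1), affine = NULL) {
  if (!all(dim(image) == dim(mask))) stop("image/mask shape mismatch")
  if (is.null(affine)) affine <- diag(c(voxel_spacing, 1))
  structure(list(image = image, mask = array(as.integer(mask > 0.5), dim(mask)),
                 voxel_spacing = voxel_spacing, affine = affine),
            class = "volume_pair")
}

#' Extract a fixed-size cube around the lesion
#'
#' The cube is centred on the mask foreground centroid (rounded), clipped
#' and zero-padded at volume borders so that every foreground voxel is
#' contained.  Intensities are min-max normalized to `[0, 1]` using the
#' cube's own window, which is recorded for inversion.
#'
#' @param pair a `volume_pair` with a nonempty mask.
#' @param side cube side; must cover the mask bounding box.
#' @return a cube record: list with `cube` (side^3, `[0, 1]`), `mask`
#'   (binary), `origin` (0-based lower corner, possibly negative at
#'   borders) and `intensity_window` `(low, high)`.
#' @export
extract_cube <- function(pair, side = 64L) {
  side <- as.integer(side)
  fg <- which(pair$mask > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("cannot extract a cube around an empty mask")
  ext <- apply(fg, 2L, function(v) diff(range(v))) + 1L
  if (any(ext > side))
    stop("mask bounding box (", paste(ext, collapse = "x"),
         ") exceeds cube side; need side >= ", max(ext))
  centroid <- colMeans(fg) - 1  # 0-based
  origin <- as.integer(round(centroid) - side %/% 2L)
  dims <- dim(pair$image)
  cube <- array(0, rep(side, 3L))
  mask <- array(0L, rep(side, 3L))
  src_lo <- pmax(origin, 0L)
  src_hi <- pmin(origin + side, dims) - 1L
  if (any(src_hi < src_lo)) stop("cube does not overlap the volume")
  dst_lo <- src_lo - origin
  ii <- (src_lo[1]:src_hi[1]) + 1L; jj <- (src_lo[2]:src_hi[2]) + 1L
  kk <- (src_lo[3]:src_hi[3]) + 1L
  di <- dst_lo[1] + seq_along(ii); dj <- dst_lo[2] + seq_along(jj)
  dk <- dst_lo[3] + seq_along(kk)
  cube[di, dj, dk] <- pair$image[ii, jj, kk]
  mask[di, dj, dk] <- pair$mask[ii, jj, kk]
  lo <- min(cube); hi <- max(cube)
  cube <- if (hi > lo) (cube - lo) / (hi - lo) else array(0, dim(cube))
  list(cube = cube, mask = mask, origin = origin,
       intensity_window = c(lo, hi))
}

#' Paste a (possibly new) cube back into a host volume
#'
#' Inside the new mask the host intensity is replaced by the de-normalized
#' cube value (inverting the record's intensity window).  With
#' `blend_sigma > 0` the replacement is feathered by a Gaussian-blurred
#' alpha mask to avoid seams; `blend_sigma = 0` gives exact mask-gated
#' replacement.  Voxels away from the (blurred) mask are untouched.
#'
#' @param pair host `volume_pair`.
#' @param record cube record from [extract_cube()] (provides origin and
#'   intensity window).
#' @param new_cube replacement cube in `[0, 1]`, same side as the record.
#' @param new_mask binary mask gating the replacement.
#' @param blend_sigma feathering width in voxels (default 1).
#' @return a new `volume_pair` with the lesion pasted and its mask updated.
#' @export
paste_cube <- function(pair, record, new_cube, new_mask, blend_sigma = 1) {
  side <- dim(record$cube)[1L]
  if (!all(dim(new_cube) == side) || !all(dim(new_mask) == side))
    stop("new cube/mask side must match the record side ", side)
  dims <- dim(pair$image)
  origin <- record$origin
  if (any(origin + side <= 0L) || any(origin >= dims))
    stop("record origin out of bounds for this volume")
  w <- record$intensity_window
  vals <- new_cube * (w[2L] - w[1L]) + w[1L]
  alpha <- if (blend_sigma > 0) gaussian_blur3(new_mask + 0, blend_sigma)
           else new_mask + 0
  alpha <- pmin(pmax(alpha, 0), 1)
  src_lo <- pmax(origin, 0L)
  src_hi <- pmin(origin + side, dims) - 1L
  dst_lo <- src_lo - origin
  ii <- (src_lo[1]:src_hi[1]) + 1L; jj <- (src_lo[2]:src_hi[2]) + 1L
  kk <- (src_lo[3]:src_hi[3]) + 1L
  ci <- dst_lo[1] + seq_along(ii); cj <- dst_lo[2] + seq_along(jj)
  ck <- dst_lo[3] + seq_along(kk)
  img <- pair$image
  msk <- pair$mask
  a <- alpha[ci, cj, ck]
  img[ii, jj, kk] <- a * vals[ci, cj, ck] + (1 - a) * img[ii, jj, kk]
  msk[ii, jj, kk] <- pmax(msk[ii, jj, kk], new_mask[ci, cj, ck])
  volume_pair(img, msk, pair$voxel_spacing, pair$affine)
}

#' Invert the cube normalization
#'
#' @param cube normalized cube in `[0, 1]`.
#' @param intensity_window `(low, high)` recorded at extraction.
#' @return cube in original intensity units.
#' @export
denormalize_cube <- function(cube, intensity_window) {
  cube * (intensity_window[2L] - intensity_window[1L]) + intensity_window[1L]
}
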