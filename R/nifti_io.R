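#' Read a labeled segmentation volume from NIfTI
#'
#' Reads a 3-D (or 4-D with a singleton trailing dimension) integer NIfTI
#' volume and normalizes it to the package's axis convention: arrays indexed
#' `[z, y, x]` with x increasing towards the image right (patient left on a
#' standard radiological axial display), y towards the image bottom
#' (posterior) and z towards the head. Files carrying orientation metadata
#' (a nonzero qform/sform) are reoriented to this convention; files without
#' it are assumed to already be stored that way.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param label_map Named integer vector mapping structure names to the codes
#'   used in the file. Any nonzero code in the volume that is not listed is a
#'   hard error.
#' @return A [labeled_volume()] with spacing taken from the file header.
#' @export
read_labeled_volume <- function(path, label_map = canonical_label_map()) {
  if (!file.exists(path))
    abort_ctpa(sprintf("file not found: %s", path), "ctpa_io_error")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(array(img[], dim = d[1:3]), reference = img)
    d <- d[1:3]
  }
  if (length(d) != 3L)
    abort_ctpa(sprintf("expected a 3-D volume, got %d dimensions", length(d)),
               "ctpa_io_error")
  xf <- RNifti::xform(img)
  has_orient <- !is.null(attr(xf, "code")) && attr(xf, "code") != 0L
  if (has_orient) {
    RNifti::orientation(img) <- "LPS"
    xf <- RNifti::xform(img)
    spacing_xyz <- sqrt(colSums(xf[1:3, 1:3]^2))
  } else {
    spacing_xyz <- RNifti::pixdim(img)[1:3]
  }
  arr <- img[]                        # stored (x, y, z)
  if (any(arr != round(arr)))
    abort_ctpa(sprintf("non-integer voxel data in %s", path), "ctpa_io_error")
  labels <- aperm(array(as.integer(round(arr)), dim = dim(arr)), c(3L, 2L, 1L))
  # NIfTI stores spacings as float32; snap to 6 significant digits so that
  # write -> read round-trips typical mm spacings exactly
  labeled_volume(labels,
                 spacing = signif(rev(spacing_xyz), 6),  # (dz, dy, dx)
                 label_map = label_map)
}

#' Write a labeled segmentation volume to NIfTI
#'
#' The inverse of [read_labeled_volume()]: labels round-trip bit-exactly,
#' spacing to float32 header precision (exact for spacings with at most 6
#' significant digits). The file carries a qform encoding the package's LPS-style
#' axis convention so that standard viewers display it correctly.
#'
#' @param vol A [labeled_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    abort_ctpa(sprintf("directory does not exist: %s", dir), "ctpa_io_error")
  arr <- aperm(vol$labels, c(3L, 2L, 1L))   # to (x, y, z) storage
  img <- RNifti::asNifti(arr)
  sp <- vol$spacing                          # (dz, dy, dx)
  aff <- diag(c(-sp[["dx"]], -sp[["dy"]], sp[["dz"]], 1))
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::pixdim(img) <- c(sp[["dx"]], sp[["dy"]], sp[["dz"]])
  RNifti::writeNifti(img, path)
  invisible(path)
}
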