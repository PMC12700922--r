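#' Canonical structure label codes
#'
#' The default mapping from anatomical structure names to integer label codes
#' used in segmentation volumes: 1 = left ventricle (LV), 2 = right ventricle
#' (RV), 3 = pulmonary artery (PA), 4 = ascending aorta (AA), 5 = lung.
#' Volumes coded differently can be read with a custom `label_map`.
#'
#' @return Named integer vector mapping structure name to label code.
#' @export
#' @examples
#' canonical_label_map()
canonical_label_map <- function() {
  c(LV = 1L, RV = 2L, PA = 3L, AA = 4L, LUNG = 5L)
}

#' Construct a labeled segmentation volume
#'
#' A `labeled_volume` is the universal input of the measurement pipeline: a
#' 3-D integer array of structure labels indexed `[z, y, x]` (1-based;
#' z = cranio-caudal slice, y = in-plane vertical increasing towards the
#' posterior/image bottom, x = in-plane horizontal increasing towards the
#' image right), together with the voxel spacing in mm and a label map.
#'
#' @param labels 3-D integer array indexed `[z, y, x]`. Zero is background;
#'   every nonzero value must appear in `label_map`.
#' @param spacing Numeric length-3 vector `(dz, dy, dx)` in mm/voxel, all
#'   positive.
#' @param label_map Named integer vector mapping structure names to codes.
#' @return An object of class `labeled_volume`.
#' @seealso [read_labeled_volume()], [write_labeled_volume()]
#' @export
labeled_volume <- function(labels, spacing, label_map = canonical_label_map()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    abort_ctpa("'labels' must be a 3-D array indexed (z, y, x)", "ctpa_value_error")
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      abort_ctpa("'labels' contains non-integer voxel values", "ctpa_value_error")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels))
    abort_ctpa("'labels' must be integer-valued", "ctpa_value_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_ctpa("'spacing' must be 3 positive numbers (dz, dy, dx) in mm", "ctpa_value_error")
  names(spacing) <- c("dz", "dy", "dx")
  label_map <- vapply(label_map, as.integer, integer(1))
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, unname(label_map))
  if (length(unknown) > 0L)
    abort_ctpa(
      sprintf("label code(s) %s present in volume but absent from label_map",
              paste(sort(unknown), collapse = ", ")),
      "unknown_label_error")
  structure(
    list(labels = labels, spacing = spacing, label_map = label_map),
    class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels (z,y,x), spacing %.3g/%.3g/%.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  present <- intersect(unname(x$label_map), unique(as.vector(x$labels)))
  nm <- names(x$label_map)[match(present, unname(x$label_map))]
  cat("  structures present:",
      if (length(nm)) paste(nm, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

# Integer code for a structure name under a volume's label map.
structure_code <- function(vol, name) {
  if (!name %in% names(vol$label_map))
    abort_ctpa(sprintf("structure '%s' not in label_map", name), "ctpa_value_error")
  unname(vol$label_map[[name]])
}

# Binary (y, x) mask of one axial slice for the given structure codes.
slice_mask <- function(vol, z, codes) {
  sl <- vol$labels[z, , , drop = TRUE]
  matrix(sl %in% codes, nrow = dim(vol$labels)[2])
}
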