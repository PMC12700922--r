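#' Geometry configuration
#'
#' Bundles the conventions under which the three indices are computed. The
#' tie-break policy is fixed (lowest z for slice selection, lowest y for the
#' chord row, lowest x for extreme pixels) and recorded here so it travels
#' with the output for provenance.
#'
#' @param label_map Named integer vector mapping `LV`, `RV`, `PA`, `AA`,
#'   `LUNG` to label codes.
#' @param septal_mode How the septal line is constructed: `"centers"`
#'   (default; the line through the LV and RV centroids) or
#'   `"closest_midline"` (total-least-squares line through midpoints of
#'   near-closest LV/RV boundary pairs).
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(label_map = canonical_label_map(),
                            septal_mode = c("centers", "closest_midline")) {
  septal_mode <- match.arg(septal_mode)
  structure(list(
    label_map = label_map,
    septal_mode = septal_mode,
    connectivity = 4L,
    tie_break = c(slice = "lowest z", chord_row = "lowest y",
                  extreme_pixel = "lowest x")
  ), class = "geometry_config")
}

#' Axial slice with the largest area of a set of structures
#'
#' Returns the 1-based z index maximizing the voxel count of the union of the
#' given structure codes on each axial slice; ties broken towards the lowest
#' z. Used to pick the measurement plane: the slice where the combined
#' ventricular area peaks (for RV/LV and SA) or where the pulmonary artery
#' area peaks (for PA/AA).
#'
#' @param vol A [labeled_volume()].
#' @param codes Integer vector of structure codes forming the union.
#' @return Integer slice index (1-based).
#' @export
largest_area_slice <- function(vol, codes) {
  stopifnot(inherits(vol, "labeled_volume"))
  areas <- apply(vol$labels, 1L, function(sl) sum(sl %in% codes))
  if (all(areas == 0L))
    abort_structure_absent(sprintf(
      "no slice contains any of label code(s) %s", paste(codes, collapse = ", ")))
  which.max(areas)   # which.max returns the first (lowest z) maximum
}

#' Maximal horizontal chord of a 2-D mask
#'
#' The structure "diameter" used by all ratio indices: over every image row
#' intersecting the mask, consider the chord from the row's leftmost to its
#' rightmost mask pixel (a segment parallel to the x-axis); return the row
#' maximizing the pixel span, ties broken towards the lowest y. Length is
#' measured center-to-center: `(x_right - x_left) * dx` mm.
#'
#' @param mask2d Logical (y, x) matrix.
#' @param dx In-plane horizontal spacing in mm/pixel.
#' @param slice_index 1-based z index recorded in the result.
#' @return A `chord_measurement`: list with `slice_index`, `row`, `x_left`,
#'   `x_right`, `length_mm`.
#' @export
max_horizontal_chord <- function(mask2d, dx, slice_index = NA_integer_) {
  idx <- which(mask2d, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    abort_structure_absent("empty mask: no horizontal chord exists")
  xl <- tapply(idx[, 2], idx[, 1], min)
  xr <- tapply(idx[, 2], idx[, 1], max)
  rows <- as.integer(names(xl))
  width <- xr - xl
  best <- which.max(width)             # ties -> first = lowest y
  structure(list(
    slice_index = as.integer(slice_index),
    row = rows[best],
    x_left = as.integer(xl[best]),
    x_right = as.integer(xr[best]),
    length_mm = unname(width[best]) * dx
  ), class = "chord_measurement")
}

reference_line <- function(point, direction) {
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n == 0)
    abort_ctpa("reference line direction is degenerate", "degenerate_septum_error")
  structure(list(point = as.numeric(point), direction = as.numeric(direction) / n),
            class = "reference_line")
}

#' Spine-parallel reference line from a lung mask
#'
#' The reference axis for the septal angle: the line through the midpoint of
#' the segment connecting the uppermost and lowermost lung pixels of the
#' axial slice, directed along that segment. Ties among extreme pixels are
#' broken towards the lowest x. Coordinates are in (y, x) pixel units.
#'
#' @param lung_mask2d Logical (y, x) matrix of the lung segmentation.
#' @return A `reference_line`: list with `point` (y, x) and unit `direction`.
#' @export
spine_reference_line <- function(lung_mask2d) {
  idx <- which(lung_mask2d, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    abort_structure_absent("empty lung mask: cannot build spine reference line")
  top_rows <- idx[idx[, 1] == min(idx[, 1]), , drop = FALSE]
  bot_rows <- idx[idx[, 1] == max(idx[, 1]), , drop = FALSE]
  p_top <- c(top_rows[1, 1], min(top_rows[, 2]))
  p_bot <- c(bot_rows[1, 1], min(bot_rows[, 2]))
  if (all(p_top == p_bot))
    abort_ctpa("lung mask degenerate: single-row extent", "degenerate_septum_error")
  reference_line(point = (p_top + p_bot) / 2, direction = p_bot - p_top)
}

#' Septal line between the two ventricles
#'
#' Characterizes the interventricular septum position on an axial slice.
#' `mode = "centers"` (the default used for the septal angle) returns the
#' line through the LV and RV mask centroids. `mode = "closest_midline"`
#' finds, for each RV boundary pixel, its nearest LV boundary pixel, keeps
#' the pairs whose distance is within 1.5x the global minimum, and fits a
#' total-least-squares line through the pair midpoints.
#'
#' @param lv_mask2d,rv_mask2d Logical (y, x) matrices.
#' @param mode `"centers"` or `"closest_midline"`.
#' @return A `reference_line` in (y, x) pixel coordinates.
#' @export
septal_line <- function(lv_mask2d, rv_mask2d,
                        mode = c("centers", "closest_midline")) {
  mode <- match.arg(mode)
  lv_idx <- which(lv_mask2d, arr.ind = TRUE)
  rv_idx <- which(rv_mask2d, arr.ind = TRUE)
  if (nrow(lv_idx) == 0L) abort_structure_absent("empty LV mask")
  if (nrow(rv_idx) == 0L) abort_structure_absent("empty RV mask")
  if (mode == "centers") {
    c_lv <- colMeans(lv_idx)
    c_rv <- colMeans(rv_idx)
    if (all(abs(c_rv - c_lv) < .Machine$double.eps^0.5))
      abort_ctpa("LV and RV centroids coincide", "degenerate_septum_error")
    return(reference_line(point = (c_lv + c_rv) / 2, direction = c_rv - c_lv))
  }
  b_lv <- boundary_pixels4(lv_mask2d)
  b_rv <- boundary_pixels4(rv_mask2d)
  # nearest LV boundary pixel for each RV boundary pixel
  d2 <- outer(b_rv[, 1], b_lv[, 1], "-")^2 + outer(b_rv[, 2], b_lv[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(b_rv)), nearest)])
  keep <- dmin <= 1.5 * min(dmin)
  if (sum(keep) < 2L)
    abort_ctpa("fewer than 2 qualifying closest-point midpoints",
               "degenerate_septum_error")
  mids <- (b_rv[keep, , drop = FALSE] + b_lv[nearest[keep], , drop = FALSE]) / 2
  ctr <- colMeans(mids)
  cv <- stats::cov(mids)
  if (!all(is.finite(cv)) || sum(diag(cv)) < .Machine$double.eps)
    abort_ctpa("closest-point midpoints are coincident", "degenerate_septum_error")
  ev <- eigen(cv, symmetric = TRUE)
  reference_line(point = ctr, direction = ev$vectors[, 1])
}

#' Acute angle between two reference lines
#'
#' `arccos(|d1 . d2|)` in degrees: orientation-insensitive, always in
#' \[0, 90\]. Directions must be expressed in the same (isotropic or
#' physically scaled) coordinates.
#'
#' @param septal,spine `reference_line` objects.
#' @return Angle in degrees.
#' @export
septal_angle <- function(septal, spine) {
  stopifnot(inherits(septal, "reference_line"), inherits(spine, "reference_line"))
  d <- abs(sum(septal$direction * spine$direction))
  acos(min(1, d)) * 180 / pi
}

# Scale a pixel-space (y, x) line into physical mm space.
line_to_physical <- function(line, dy, dx) {
  reference_line(point = line$point * c(dy, dx),
                 direction = line$direction * c(dy, dx))
}

# Cleaned (largest component, hole-filled) mask of one structure on a slice,
# with a structure-absent error naming slice and structure when empty.
structure_mask_on <- function(vol, z, name) {
  m <- slice_mask(vol, z, structure_code(vol, name))
  if (!any(m))
    abort_structure_absent(sprintf("structure %s absent on slice %d", name, z))
  clean_mask(m)
}

#' RV/LV diameter ratio
#'
#' Selects the axial slice where the combined LV + RV area is largest,
#' reduces each ventricle to its largest 4-connected component with holes
#' filled, measures each ventricle's maximal horizontal chord, and returns
#' RV diameter / LV diameter. A ratio above 1 suggests right-ventricular
#' dilation.
#'
#' @param vol A [labeled_volume()] containing LV and RV labels.
#' @param config A [geometry_config()].
#' @return List with `ratio`, `rv_chord`, `lv_chord`, `heart_slice`.
#' @export
compute_rv_lv <- function(vol, config = geometry_config()) {
  z <- largest_area_slice(vol, c(structure_code(vol, "LV"), structure_code(vol, "RV")))
  dx <- vol$spacing[["dx"]]
  rv <- max_horizontal_chord(structure_mask_on(vol, z, "RV"), dx, z)
  lv <- max_horizontal_chord(structure_mask_on(vol, z, "LV"), dx, z)
  if (lv$length_mm == 0)
    abort_ctpa("LV chord has zero length", "degenerate_septum_error")
  list(ratio = rv$length_mm / lv$length_mm,
       rv_chord = rv, lv_chord = lv, heart_slice = z)
}

#' PA/AA diameter ratio
#'
#' Selects the axial slice where the pulmonary artery cross-section is
#' largest (PA area alone decides the plane), measures the maximal horizontal
#' chords of PA and ascending aorta on that slice, and returns
#' PA diameter / AA diameter — a surrogate for pulmonary hypertension.
#'
#' @inheritParams compute_rv_lv
#' @return List with `ratio`, `pa_chord`, `aa_chord`, `pa_slice`.
#' @export
compute_pa_aa <- function(vol, config = geometry_config()) {
  z <- largest_area_slice(vol, structure_code(vol, "PA"))
  dx <- vol$spacing[["dx"]]
  pa <- max_horizontal_chord(structure_mask_on(vol, z, "PA"), dx, z)
  aa <- max_horizontal_chord(structure_mask_on(vol, z, "AA"), dx, z)
  if (aa$length_mm == 0)
    abort_ctpa("AA chord has zero length", "degenerate_septum_error")
  list(ratio = pa$length_mm / aa$length_mm,
       pa_chord = pa, aa_chord = aa, pa_slice = z)
}

#' Ventricular septal angle
#'
#' On the slice of largest combined ventricular area, builds the septal line
#' (centroid-to-centroid by default) and the spine-parallel reference line
#' from the lung mask of the same slice, scales both into physical mm
#' coordinates, and returns the acute angle between them in degrees.
#'
#' @inheritParams compute_rv_lv
#' @return List with `angle_deg`, `septal_line`, `spine_line` (both in pixel
#'   (y, x) coordinates), `heart_slice`.
#' @export
compute_septal_angle <- function(vol, config = geometry_config()) {
  z <- largest_area_slice(vol, c(structure_code(vol, "LV"), structure_code(vol, "RV")))
  lv <- structure_mask_on(vol, z, "LV")
  rv <- structure_mask_on(vol, z, "RV")
  lung <- slice_mask(vol, z, structure_code(vol, "LUNG"))
  if (!any(lung))
    abort_structure_absent(sprintf("structure LUNG absent on slice %d", z))
  sep_line <- septal_line(lv, rv, mode = config$septal_mode)
  sp_line <- spine_reference_line(lung)
  dy <- vol$spacing[["dy"]]; dx <- vol$spacing[["dx"]]
  ang <- septal_angle(line_to_physical(sep_line, dy, dx),
                      line_to_physical(sp_line, dy, dx))
  list(angle_deg = ang, septal_line = sep_line, spine_line = sp_line,
       heart_slice = z)
}

#' Compute all three right-heart indices
#'
#' Runs [compute_rv_lv()], [compute_pa_aa()] and [compute_septal_angle()] on
#' one labeled volume and assembles the result. Deterministic for fixed input
#' and configuration. Errors from a missing structure are re-raised naming
#' the index that failed.
#'
#' @inheritParams compute_rv_lv
#' @return An `index_set`: list with `rv_lv`, `pa_aa`, `septal_angle_deg`,
#'   the four chords, both reference lines, `heart_slice` and `pa_slice`,
#'   plus the `config` used.
#' @export
compute_indices <- function(vol, config = geometry_config()) {
  if (!identical(unname(config$label_map), unname(vol$label_map)) ||
      !identical(names(config$label_map), names(vol$label_map))) {
    # config label_map wins: re-validate the volume under it
    vol <- labeled_volume(vol$labels, vol$spacing, config$label_map)
  }
  wrap <- function(index, expr) {
    tryCatch(expr, structure_absent_error = function(e)
      abort_structure_absent(sprintf("%s: %s", index, conditionMessage(e))))
  }
  rvlv <- wrap("RV_LV", compute_rv_lv(vol, config))
  paaa <- wrap("PA_AA", compute_pa_aa(vol, config))
  sa <- wrap("SA", compute_septal_angle(vol, config))
  structure(list(
    rv_lv = rvlv$ratio,
    pa_aa = paaa$ratio,
    septal_angle_deg = sa$angle_deg,
    rv_chord = rvlv$rv_chord, lv_chord = rvlv$lv_chord,
    pa_chord = paaa$pa_chord, aa_chord = paaa$aa_chord,
    heart_slice = rvlv$heart_slice, pa_slice = paaa$pa_slice,
    septal_line = sa$septal_line, spine_line = sa$spine_line,
    config = config
  ), class = "index_set")
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("<index_set> RV/LV = %.3f (slice %d), PA/AA = %.3f (slice %d), SA = %.1f deg\n",
              x$rv_lv, x$heart_slice, x$pa_aa, x$pa_slice, x$septal_angle_deg))
  invisible(x)
}

#' Convert an index set to measurement records
#'
#' @param x An `index_set` from [compute_indices()].
#' @param subject_id Subject identifier for the records.
#' @param source Measurement source label (default `"auto"`).
#' @return A 3-row measurement data frame (see [measurement_records()]).
#' @export
index_set_records <- function(x, subject_id, source = "auto") {
  measurement_records(
    subject_id = subject_id,
    index_name = c("RV_LV", "PA_AA", "SA"),
    value = c(x$rv_lv, x$pa_aa, x$septal_angle_deg),
    source = source,
    slice_index = c(x$heart_slice, x$pa_slice, x$heart_slice))
}
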