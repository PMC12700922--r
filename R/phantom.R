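# Parametric axial chest phantom: two axis-aligned ventricular ellipses
# separated along a controllable direction, two great-vessel circles with a
# z-area profile peaking at a known slice, and two symmetric lung ellipses
# defining a vertical (spine-parallel) reference axis. Every structure has a
# closed-form footprint, so the three indices have analytic ground truth.
#
# In-plane layout is parameterized by fractions of the field of view so the
# same anatomy scales from 256x256 clinical-like grids down to 64x64 toy
# grids for segmentation experiments.

#' Phantom specification
#'
#' Generative parameters of a synthetic axial chest volume with analytically
#' known ground-truth indices. Ellipse semi-axes `a_*` are horizontal (x) and
#' `b_*` vertical (y), in mm; the ventricles are placed on opposite sides of
#' a septum whose direction makes `theta_sep_deg` degrees with the vertical
#' lung (spine) axis, separated by a boundary gap of `gap` mm along that
#' direction. Vessel cross-sections are circles whose radius follows an
#' elliptical z-profile peaking at `z_pa` (pulmonary artery); the ascending
#' aorta has constant radius over the same slices. Ventricular semi-axes
#' follow the same kind of profile peaking at `z_heart`.
#'
#' @param grid Integer (nz, ny, nx) voxel counts.
#' @param spacing Numeric (dz, dy, dx) mm/voxel.
#' @param a_lv,b_lv,a_rv,b_rv Ventricular semi-axes in mm.
#' @param theta_sep_deg Septum direction, degrees from the vertical axis.
#' @param gap Boundary gap between the ventricles along the septum direction, mm.
#' @param r_pa,r_aa Vessel radii in mm.
#' @param z_heart,z_pa 1-based slices of peak ventricular / PA area.
#' @param heart_halfwidth,pa_halfwidth Half-width (slices) of the z-profiles.
#' @param seed Seed recorded for provenance (generation itself is
#'   deterministic).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(nz = 24L, ny = 256L, nx = 256L),
                         spacing = c(dz = 5, dy = 0.7, dx = 0.7),
                         a_lv = 20, b_lv = 16, a_rv = 22, b_rv = 14,
                         theta_sep_deg = 40, gap = 6,
                         r_pa = 16, r_aa = 14,
                         z_heart = 14L, z_pa = 6L,
                         heart_halfwidth = 4L, pa_halfwidth = 4L,
                         seed = 1L) {
  grid <- as.integer(grid); names(grid) <- c("nz", "ny", "nx")
  spacing <- as.numeric(spacing); names(spacing) <- c("dz", "dy", "dx")
  spec <- structure(list(
    grid = grid, spacing = spacing,
    a_lv = a_lv, b_lv = b_lv, a_rv = a_rv, b_rv = b_rv,
    theta_sep_deg = theta_sep_deg, gap = gap,
    r_pa = r_pa, r_aa = r_aa,
    z_heart = as.integer(z_heart), z_pa = as.integer(z_pa),
    heart_halfwidth = as.integer(heart_halfwidth),
    pa_halfwidth = as.integer(pa_halfwidth),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  minvox <- 2 * max(spec$spacing[c("dy", "dx")])
  dims <- c(spec$a_lv, spec$b_lv, spec$a_rv, spec$b_rv, spec$r_pa, spec$r_aa)
  if (any(dims <= minvox))
    abort_ctpa(sprintf("all semi-axes/radii must exceed %.2f mm (2 voxels)", minvox),
               "phantom_spec_error")
  if (spec$gap < max(spec$spacing[c("dy", "dx")]))
    abort_ctpa("ventricular gap must be at least one voxel", "phantom_spec_error")
  nz <- spec$grid[["nz"]]
  if (spec$z_heart < 1L || spec$z_heart > nz || spec$z_pa < 1L || spec$z_pa > nz)
    abort_ctpa("z_heart and z_pa must lie within the grid", "phantom_spec_error")
  if (spec$heart_halfwidth < 2L || spec$pa_halfwidth < 2L)
    abort_ctpa("profile half-widths must be >= 2 slices", "phantom_spec_error")
  spec
}

# Fixed in-plane layout as fractions of the half-field-of-view.
phantom_layout <- function(spec) {
  fovy <- spec$grid[["ny"]] * spec$spacing[["dy"]]
  fovx <- spec$grid[["nx"]] * spec$spacing[["dx"]]
  hy <- fovy / 2; hx <- fovx / 2
  list(
    lung_cx_off = 0.74 * hx, lung_a = 0.22 * hx, lung_b = 0.72 * hy,
    vessel_y = hy - 0.56 * hy, vessel_x_off = 0.22 * hx,
    heart_y = hy + 0.17 * hy,
    cy = hy, cx = hx)
}

# Radius of an axis-aligned ellipse (a horizontal, b vertical) along the
# unit direction u = (u_y, u_x).
ellipse_radius_along <- function(a, b, u) 1 / sqrt((u[2] / a)^2 + (u[1] / b)^2)

# Symmetric elliptical z-profile: scale factor in (0, 1], peaking at z_peak,
# zero outside |z - z_peak| < halfwidth.
z_profile <- function(z, z_peak, halfwidth) {
  t <- (z - z_peak) / halfwidth
  ifelse(abs(t) < 1, sqrt(pmax(0, 1 - t^2)), 0)
}

# Snap a physical (y mm, x mm) position to the nearest pixel center.
snap_to_pixel <- function(y_mm, x_mm, dy, dx) {
  c(y = round(y_mm / dy + 0.5), x = round(x_mm / dx + 0.5))
}

pixel_center_mm <- function(idx, d) (idx - 0.5) * d

#' Generate a phantom volume with its ground truth
#'
#' Rasterizes the five structures of a [phantom_spec()] into a
#' [labeled_volume()] and returns the closed-form ground truth alongside.
#' Ellipse/circle centers are snapped to pixel centers so every rasterized
#' footprint is exactly symmetric about its center; ground-truth chords and
#' the septal direction therefore have exact analytic values. Generation is
#' fully deterministic.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a `labeled_volume`) and `truth` (class
#'   `phantom_truth`): `rv_lv`, `pa_aa` (continuous analytic ratios),
#'   `rv_lv_raster`, `pa_aa_raster` (pixel-quantized chord ratios at the peak
#'   slices), `sa_deg` (requested septum angle folded into \[0, 90\]),
#'   `sa_deg_realized` (angle of the pixel-snapped centers), `z_heart`,
#'   `z_pa`.
#' @export
generate_phantom <- function(spec) {
  spec <- validate_phantom_spec(spec)
  lay <- phantom_layout(spec)
  nz <- spec$grid[["nz"]]; ny <- spec$grid[["ny"]]; nx <- spec$grid[["nx"]]
  dz <- spec$spacing[["dz"]]; dy <- spec$spacing[["dy"]]; dx <- spec$spacing[["dx"]]
  py <- pixel_center_mm(seq_len(ny), dy)
  px <- pixel_center_mm(seq_len(nx), dx)

  theta <- spec$theta_sep_deg * pi / 180
  u <- c(cos(theta), sin(theta))                  # (y, x), from vertical axis
  d_sep <- ellipse_radius_along(spec$a_lv, spec$b_lv, u) +
           ellipse_radius_along(spec$a_rv, spec$b_rv, u) + spec$gap
  ctr_mm <- c(lay$heart_y, lay$cx)
  lv_idx <- snap_to_pixel(ctr_mm[1] + u[1] * d_sep / 2, ctr_mm[2] + u[2] * d_sep / 2, dy, dx)
  rv_idx <- snap_to_pixel(ctr_mm[1] - u[1] * d_sep / 2, ctr_mm[2] - u[2] * d_sep / 2, dy, dx)
  pa_idx <- snap_to_pixel(lay$vessel_y, lay$cx + lay$vessel_x_off, dy, dx)
  aa_idx <- snap_to_pixel(lay$vessel_y, lay$cx - lay$vessel_x_off, dy, dx)
  lungL_idx <- snap_to_pixel(lay$cy, lay$cx - lay$lung_cx_off, dy, dx)
  lungR_idx <- snap_to_pixel(lay$cy, lay$cx + lay$lung_cx_off, dy, dx)

  ellipse_mask <- function(center_idx, a, b) {
    cy_mm <- pixel_center_mm(center_idx[["y"]], dy)
    cx_mm <- pixel_center_mm(center_idx[["x"]], dx)
    outer(((py - cy_mm) / b)^2, ((px - cx_mm) / a)^2, "+") <= 1
  }

  labels <- array(0L, dim = c(nz, ny, nx))
  place <- function(z, mask, code, what) {
    sl <- labels[z, , ]
    if (any(sl[mask] != 0L))
      abort_ctpa(sprintf("phantom structures overlap (%s, slice %d)", what, z),
                 "phantom_generation_error")
    sl[mask] <- code
    labels[z, , ] <<- sl
  }
  lm <- canonical_label_map()
  lungs <- ellipse_mask(lungL_idx, lay$lung_a, lay$lung_b) |
           ellipse_mask(lungR_idx, lay$lung_a, lay$lung_b)
  for (z in seq_len(nz)) {
    place(z, lungs, lm[["LUNG"]], "lungs")
    fh <- z_profile(z, spec$z_heart, spec$heart_halfwidth)
    if (fh > 0) {
      place(z, ellipse_mask(lv_idx, spec$a_lv * fh, spec$b_lv * fh), lm[["LV"]], "LV")
      place(z, ellipse_mask(rv_idx, spec$a_rv * fh, spec$b_rv * fh), lm[["RV"]], "RV")
    }
    fp <- z_profile(z, spec$z_pa, spec$pa_halfwidth)
    if (fp > 0) {
      place(z, ellipse_mask(pa_idx, spec$r_pa * fp, spec$r_pa * fp), lm[["PA"]], "PA")
      place(z, ellipse_mask(aa_idx, spec$r_aa, spec$r_aa), lm[["AA"]], "AA")
    }
  }

  # ground truth from closed-form geometry (never from the measurement code)
  d_real <- c((rv_idx[["y"]] - lv_idx[["y"]]) * dy,
              (rv_idx[["x"]] - lv_idx[["x"]]) * dx)
  sa_real <- fold_acute(atan2(abs(d_real[2]), abs(d_real[1])) * 180 / pi)
  chord_px <- function(a, d) 2 * floor(a / d) * d     # center-to-center, mm
  truth <- structure(list(
    rv_lv = spec$a_rv / spec$a_lv,
    pa_aa = spec$r_pa / spec$r_aa,
    sa_deg = fold_acute(spec$theta_sep_deg),
    sa_deg_realized = sa_real,
    rv_lv_raster = chord_px(spec$a_rv, dx) / chord_px(spec$a_lv, dx),
    pa_aa_raster = chord_px(spec$r_pa, dx) / chord_px(spec$r_aa, dx),
    z_heart = spec$z_heart, z_pa = spec$z_pa
  ), class = "phantom_truth")
  list(volume = labeled_volume(labels, spec$spacing), truth = truth)
}

#' Default parameter ranges for phantom cohorts
#'
#' Uniform sampling ranges that keep every phantom within the fixed in-plane
#' layout (no structure collisions) while spanning clinically plausible
#' index values: RV/LV roughly 0.7-1.5, PA/AA 0.75-1.5, septal angles
#' 20-60 degrees.
#'
#' @return Named list of `c(lo, hi)` ranges (integers for slice positions).
#' @export
default_phantom_ranges <- function() {
  list(a_lv = c(16, 22), b_lv = c(13, 17),
       a_rv = c(15, 24), b_rv = c(12, 16),
       theta_sep_deg = c(20, 60), gap = c(4, 8),
       r_pa = c(12, 18), r_aa = c(12, 16),
       z_heart = c(12L, 16L), z_pa = c(4L, 8L))
}

#' Sample a reproducible cohort of phantoms
#'
#' Draws `n` phantom specifications with parameters uniform in `ranges`
#' (slice positions uniform over the integer range) and generates each one.
#' The whole cohort is reproducible from `seed`.
#'
#' @param n Number of phantoms.
#' @param ranges Named list of `c(lo, hi)` ranges as in
#'   [default_phantom_ranges()]; a zero-width range fixes the parameter.
#' @param seed Integer seed.
#' @param grid,spacing Passed to every [phantom_spec()].
#' @return List of `n` elements, each `list(volume, truth, spec)`; names are
#'   `subj_001`, `subj_002`, ...
#' @export
sample_phantom_cohort <- function(n, ranges = default_phantom_ranges(), seed = 1L,
                                  grid = c(nz = 24L, ny = 256L, nx = 256L),
                                  spacing = c(dz = 5, dy = 0.7, dx = 0.7)) {
  if (n < 1L) abort_ctpa("n must be >= 1", "ctpa_value_error")
  base <- default_phantom_ranges()
  bad <- setdiff(names(ranges), names(base))
  if (length(bad))
    abort_ctpa(sprintf("unknown range parameter(s): %s", paste(bad, collapse = ", ")),
               "phantom_spec_error")
  ranges <- utils::modifyList(base, ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[2] < r[1])
      abort_ctpa(sprintf("invalid range for %s", nm), "phantom_spec_error")
  }
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      runif_r <- function(r) stats::runif(1, r[1], r[2])
      int_r <- function(r) if (r[1] == r[2]) as.integer(r[1]) else
        sample(seq.int(r[1], r[2]), 1)
      list(a_lv = runif_r(ranges$a_lv), b_lv = runif_r(ranges$b_lv),
           a_rv = runif_r(ranges$a_rv), b_rv = runif_r(ranges$b_rv),
           theta_sep_deg = runif_r(ranges$theta_sep_deg),
           gap = runif_r(ranges$gap),
           r_pa = runif_r(ranges$r_pa), r_aa = runif_r(ranges$r_aa),
           z_heart = int_r(ranges$z_heart), z_pa = int_r(ranges$z_pa))
    })
  })
  out <- lapply(seq_len(n), function(i) {
    p <- draws[[i]]
    spec <- phantom_spec(grid = grid, spacing = spacing,
                         a_lv = p$a_lv, b_lv = p$b_lv, a_rv = p$a_rv, b_rv = p$b_rv,
                         theta_sep_deg = p$theta_sep_deg, gap = p$gap,
                         r_pa = p$r_pa, r_aa = p$r_aa,
                         z_heart = p$z_heart, z_pa = p$z_pa, seed = seed)
    c(generate_phantom(spec), list(spec = spec))
  })
  names(out) <- sprintf("subj_%03d", seq_len(n))
  out
}

#' Ground truths as measurement records
#'
#' @param truths Named list of `phantom_truth` objects (names become subject
#'   ids; unnamed lists get `subj_001`, ...).
#' @param source Source label for the records.
#' @return Measurement data frame with one row per (subject, index).
#' @export
truth_records <- function(truths, source = "manual") {
  ids <- names(truths) %||% sprintf("subj_%03d", seq_along(truths))
  if (is.null(names(truths))) names(truths) <- ids
  do.call(rbind, lapply(ids, function(id) {
    tr <- truths[[id]]
    measurement_records(
      subject_id = id, index_name = c("RV_LV", "PA_AA", "SA"),
      value = c(tr$rv_lv, tr$pa_aa, tr$sa_deg), source = source,
      slice_index = c(tr$z_heart, tr$z_pa, tr$z_heart))
  }))
}

#' Simulate manual rater measurements from ground truth
#'
#' Emulates human annotation noise: ratio indices get multiplicative Gaussian
#' noise `truth * (1 + e)`, `e ~ N(0, noise_cv^2)`; the septal angle gets
#' additive noise `N(0, (noise_cv * 45)^2)` degrees, clipped to \[0, 90\].
#' Independent per subject and index; reproducible from `seed`.
#'
#' @param truths Named list of `phantom_truth` objects.
#' @param noise_cv Coefficient of variation of the rater noise (>= 0).
#' @param seed Integer seed.
#' @return Measurement data frame with `source = "manual"`.
#' @export
simulate_manual_ratings <- function(truths, noise_cv = 0.05, seed = 1L) {
  if (noise_cv < 0) abort_ctpa("noise_cv must be >= 0", "ctpa_value_error")
  ids <- names(truths) %||% sprintf("subj_%03d", seq_along(truths))
  n <- length(truths)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      tr <- truths[[i]]
      rvlv <- max(tr$rv_lv * (1 + stats::rnorm(1, 0, noise_cv)), 1e-6)
      paaa <- max(tr$pa_aa * (1 + stats::rnorm(1, 0, noise_cv)), 1e-6)
      sa <- min(max(tr$sa_deg + stats::rnorm(1, 0, noise_cv * 45), 0), 90)
      measurement_records(
        subject_id = ids[i], index_name = c("RV_LV", "PA_AA", "SA"),
        value = c(rvlv, paaa, sa), source = "manual",
        slice_index = c(tr$z_heart, tr$z_pa, tr$z_heart))
    }))
  })
}

#' Render a pseudo-CT intensity volume from a labeled volume
#'
#' Assigns each structure (and the background) a constant HU-like intensity
#' and adds Gaussian noise — the training input for the toy segmentation
#' stage. Piecewise-constant by construction; not an anatomically realistic
#' CT simulation.
#'
#' @param vol A [labeled_volume()].
#' @param intensity_map Named numeric vector covering `background` and every
#'   structure name in the volume's label map.
#' @param noise_sd Gaussian noise standard deviation (same units).
#' @param seed Integer seed.
#' @return List of class `ct_volume`: `image` (numeric (z, y, x) array) and
#'   `spacing`.
#' @export
render_pseudo_ct <- function(vol,
                             intensity_map = c(background = 40, LV = 350, RV = 300,
                                               PA = 320, AA = 380, LUNG = -780),
                             noise_sd = 20, seed = 1L) {
  stopifnot(inherits(vol, "labeled_volume"))
  need <- c("background", names(vol$label_map)[unname(vol$label_map) %in%
                                                 unique(as.vector(vol$labels))])
  missing_int <- setdiff(need, names(intensity_map))
  if (length(missing_int))
    abort_ctpa(sprintf("intensity_map lacks entries for: %s",
                       paste(missing_int, collapse = ", ")), "ctpa_value_error")
  lut <- rep(intensity_map[["background"]], max(vol$label_map) + 1L)
  for (nm in names(vol$label_map))
    if (nm %in% names(intensity_map))
      lut[vol$label_map[[nm]] + 1L] <- intensity_map[[nm]]
  img <- array(lut[vol$labels + 1L], dim = dim(vol$labels))
  if (noise_sd > 0)
    img <- img + with_seed(seed, array(stats::rnorm(length(img), 0, noise_sd),
                                       dim = dim(img)))
  structure(list(image = img, spacing = vol$spacing), class = "ct_volume")
}
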