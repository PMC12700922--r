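test_that("maximal horizontal chord follows the center-to-center convention", {
  # filled rectangle spanning columns 10..49 at dx = 0.7 mm
  m <- matrix(FALSE, 30, 60); m[5:20, 10:49] <- TRUE
  ch <- max_horizontal_chord(m, dx = 0.7, slice_index = 3L)
  expect_equal(ch$length_mm, 39 * 0.7)
  expect_equal(ch$row, 5)                       # tie over rows -> lowest y
  expect_equal(c(ch$x_left, ch$x_right), c(10, 49))
  expect_equal(ch$slice_index, 3L)

  # digital disk of radius 20 px centered on a pixel: row through the center
  # spans -20..+20
  d2 <- outer((1:50 - 25)^2, (1:50 - 25)^2, "+")
  ch2 <- max_horizontal_chord(d2 <= 400, dx = 1)
  expect_equal(ch2$length_mm, 40)
  expect_equal(unname(chord_oracle(d2 <= 400, 1)$length_mm), 40)

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  ch3 <- max_horizontal_chord(single, dx = 1)
  expect_equal(ch3$length_mm, 0)
  expect_equal(ch3$x_left, ch3$x_right)

  expect_error(max_horizontal_chord(matrix(FALSE, 4, 4), 1),
               class = "structure_absent_error")
})

test_that("chord extraction matches the exhaustive per-row oracle on random masks", {
  set.seed(101)
  for (i in 1:50) {
    m <- random_mask()
    got <- max_horizontal_chord(m, dx = 0.8)
    ref <- chord_oracle(m, dx = 0.8)
    expect_identical(got[c("row", "x_left", "x_right")],
                     ref[c("row", "x_left", "x_right")])
    expect_equal(got$length_mm, ref$length_mm)
  }
})

test_that("slice selection maximizes union area with lowest-z tie-break", {
  mk <- function(areas) {
    lab <- array(0L, c(length(areas), 10, 10))
    for (z in seq_along(areas)) if (areas[z] > 0) {
      sl <- matrix(0L, 10, 10); sl[seq_len(areas[z])] <- 1L
      lab[z, , ] <- sl
    }
    labeled_volume(lab, c(1, 1, 1), c(LV = 1L))
  }
  expect_equal(largest_area_slice(mk(c(10, 50, 30)), 1L), 2)
  expect_equal(largest_area_slice(mk(c(7, 7, 3)), 1L), 1)
  expect_error(largest_area_slice(mk(c(5, 5, 5)), 2L),
               class = "structure_absent_error")
})

test_that("spine reference line connects lung extremes through their midpoint", {
  m <- matrix(FALSE, 500, 300)
  m[40, 100] <- TRUE; m[460, 100] <- TRUE; m[250, 90:110] <- TRUE
  ln <- spine_reference_line(m)
  expect_equal(ln$point, c(250, 100))
  expect_equal(ln$direction, c(1, 0))

  m2 <- matrix(FALSE, 500, 300)
  m2[40, 90] <- TRUE; m2[440, 190] <- TRUE
  ln2 <- spine_reference_line(m2)
  expect_equal(ln2$direction, c(400, 100) / sqrt(400^2 + 100^2))

  # ties among extreme pixels resolve to the lowest x
  m3 <- matrix(FALSE, 10, 10)
  m3[2, c(4, 7)] <- TRUE; m3[9, c(5, 7)] <- TRUE
  ln3 <- spine_reference_line(m3)
  expect_equal(ln3$point, c((2 + 9) / 2, (4 + 5) / 2))
  expect_error(spine_reference_line(matrix(FALSE, 5, 5)),
               class = "structure_absent_error")
})

test_that("septal line modes: centroid line and closest-point midline", {
  lv <- matrix(FALSE, 400, 500); lv[190:210, 140:160] <- TRUE  # centroid (200,150)
  rv <- matrix(FALSE, 400, 500); rv[190:210, 340:360] <- TRUE  # centroid (200,350)
  ln <- septal_line(lv, rv, mode = "centers")
  expect_equal(ln$point, c(200, 250))
  expect_equal(abs(ln$direction), c(0, 1))

  # two vertical-edged blocks separated by a vertical gap: the closest-point
  # midline runs down the gap center
  lv2 <- matrix(FALSE, 60, 60); lv2[10:50, 10:24] <- TRUE
  rv2 <- matrix(FALSE, 60, 60); rv2[10:50, 31:45] <- TRUE
  ln2 <- septal_line(lv2, rv2, mode = "closest_midline")
  expect_equal(abs(ln2$direction), c(1, 0))
  # the 1.5x-minimum rule admits slightly slanted near-corner pairs, so the
  # fitted line center sits within a fraction of a pixel of the gap center
  expect_lt(abs(ln2$point[2] - 27.5), 0.2)

  expect_error(septal_line(matrix(FALSE, 5, 5), rv2),
               class = "structure_absent_error")
  one <- matrix(FALSE, 9, 9); one[5, 2] <- TRUE
  other <- matrix(FALSE, 9, 9); other[5, 8] <- TRUE
  expect_error(septal_line(one, other, mode = "closest_midline"),
               class = "degenerate_septum_error")
})

test_that("septal angle is the acute angle, insensitive to direction signs", {
  rl <- function(d) structure(list(point = c(0, 0), direction = d / sqrt(sum(d^2))),
                              class = "reference_line")
  expect_equal(septal_angle(rl(c(1, 0)), rl(c(0, 1))), 90)
  expect_equal(septal_angle(rl(c(1, 0)), rl(c(1, 1))), 45)
  expect_equal(septal_angle(rl(c(1, 0)), rl(c(-1, 0))), 0)
  set.seed(5)
  for (i in 1:20) {
    a <- rl(stats::rnorm(2)); b <- rl(stats::rnorm(2))
    ang <- septal_angle(a, b)
    expect_gte(ang, 0); expect_lte(ang, 90)
    a_neg <- rl(-a$direction)
    expect_equal(septal_angle(a_neg, b), ang)
  }
})

test_that("RV/LV ratio recovers rasterized chords across an RV size sweep", {
  for (a_rv in c(15, 18, 20, 22)) {
    ph <- generate_phantom(phantom_spec(grid = small_grid, spacing = small_spacing,
                                        a_rv = a_rv, a_lv = 20))
    got <- compute_rv_lv(ph$volume)
    dx <- small_spacing[["dx"]]
    expect_equal(got$ratio, floor(a_rv / dx) / floor(20 / dx))
    expect_equal(got$heart_slice, ph$truth$z_heart)
  }
  # identical LV and RV shapes give exactly 1
  ph <- generate_phantom(phantom_spec(grid = small_grid, spacing = small_spacing,
                                      a_rv = 20, b_rv = 16, a_lv = 20, b_lv = 16))
  expect_equal(compute_rv_lv(ph$volume)$ratio, 1)
})

test_that("PA/AA ratio is measured on the PA-area-selected slice", {
  ph <- generate_phantom(phantom_spec(grid = small_grid, spacing = small_spacing,
                                      r_pa = 16, r_aa = 16))
  got <- compute_pa_aa(ph$volume)
  expect_equal(got$ratio, 1)
  expect_equal(got$pa_slice, ph$truth$z_pa)
  ph2 <- generate_phantom(phantom_spec(grid = small_grid, spacing = small_spacing,
                                       r_pa = 16, r_aa = 14, z_pa = 7))
  got2 <- compute_pa_aa(ph2$volume)
  expect_equal(got2$pa_slice, 7)
  expect_lt(abs(got2$ratio - 32 / 28), 0.08)   # within pixel quantization
})

test_that("septal angle recovers the constructed septum orientation", {
  ph <- generate_phantom(phantom_spec(grid = small_grid, spacing = small_spacing,
                                      theta_sep_deg = 35))
  got <- compute_septal_angle(ph$volume)
  # exact against the realized (pixel-snapped) septum; snapping itself can
  # shift the angle by ~atan(dx / separation) at this coarse 1.4 mm grid
  expect_lt(abs(got$angle_deg - ph$truth$sa_deg_realized), 0.5)
  expect_lt(abs(got$angle_deg - 35), 2.5)
  # ventricles side by side (septum horizontal w.r.t. the vertical lung axis)
  ph2 <- generate_phantom(phantom_spec(grid = small_grid, spacing = small_spacing,
                                       theta_sep_deg = 90))
  expect_lt(abs(compute_septal_angle(ph2$volume)$angle_deg - 90), 1)
})

test_that("rigid rotation of a slice leaves the septal angle unchanged", {
  base <- compute_septal_angle(strip_slice_volume(0, 35))$angle_deg
  expect_lt(abs(base - 35), 1)
  for (phi in c(10, -25, 60)) {
    rot <- compute_septal_angle(strip_slice_volume(phi, 35))$angle_deg
    expect_lt(abs(rot - base), 1)
  }
})

test_that("indices are deterministic, scale-equivariant and translation-invariant", {
  spec <- phantom_spec(grid = small_grid, spacing = small_spacing)
  ph <- generate_phantom(spec)
  i1 <- compute_indices(ph$volume)
  i2 <- compute_indices(ph$volume)
  expect_identical(i1, i2)

  # doubling in-plane spacing doubles chords, leaves indices unchanged
  scaled <- labeled_volume(ph$volume$labels,
                           ph$volume$spacing * c(1, 2, 2))
  i3 <- compute_indices(scaled)
  expect_equal(i3$rv_chord$length_mm, 2 * i1$rv_chord$length_mm)
  expect_equal(i3$rv_lv, i1$rv_lv)
  expect_equal(i3$pa_aa, i1$pa_aa)
  expect_equal(i3$septal_angle_deg, i1$septal_angle_deg)

  # integer (y, x) shift of every mask
  lab <- ph$volume$labels
  shifted <- array(0L, dim = dim(lab))
  shifted[, 4:dim(lab)[2], 3:dim(lab)[3]] <-
    lab[, 1:(dim(lab)[2] - 3), 1:(dim(lab)[3] - 2)]
  i4 <- compute_indices(labeled_volume(shifted, ph$volume$spacing))
  expect_equal(i4$rv_lv, i1$rv_lv)
  expect_equal(i4$pa_aa, i1$pa_aa)
  expect_equal(i4$septal_angle_deg, i1$septal_angle_deg)
})

test_that("missing structures fail loudly, naming the failing index", {
  ph <- generate_phantom(phantom_spec(grid = small_grid, spacing = small_spacing))
  lab <- ph$volume$labels
  lab[lab == canonical_label_map()[["AA"]]] <- 0L
  no_aa <- labeled_volume(lab, ph$volume$spacing)
  expect_error(compute_indices(no_aa), "PA_AA", class = "structure_absent_error")
  lab2 <- ph$volume$labels
  lab2[lab2 == canonical_label_map()[["LUNG"]]] <- 0L
  expect_error(compute_indices(labeled_volume(lab2, ph$volume$spacing)),
               "SA", class = "structure_absent_error")
})

test_that("chords are measured on the largest hole-filled component", {
  ph <- generate_phantom(phantom_spec(grid = small_grid, spacing = small_spacing))
  lab <- ph$volume$labels
  z <- ph$truth$z_heart
  lm <- canonical_label_map()
  sl <- lab[z, , ]
  # poke a hole in the RV and add a distant RV speck wider than the hole
  rv_idx <- which(sl == lm[["RV"]], arr.ind = TRUE)
  c_rv <- round(colMeans(rv_idx))
  sl[c_rv[1] + (-1:1), c_rv[2] + (-1:1)] <- 0L
  sl[2, 2:12] <- lm[["RV"]]
  lab[z, , ] <- sl
  messy <- labeled_volume(lab, ph$volume$spacing)
  expect_equal(compute_rv_lv(messy)$ratio, compute_rv_lv(ph$volume)$ratio)
})
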