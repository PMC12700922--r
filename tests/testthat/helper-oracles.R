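# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different code paths than the implementation.

# Exhaustive per-row scan: the reference for max_horizontal_chord. Plain
# loop, no vectorized shortcuts.
chord_oracle <- function(mask, dx) {
  best_w <- -1L; best <- NULL
  for (y in seq_len(nrow(mask))) {
    xs <- which(mask[y, ])
    if (!length(xs)) next
    w <- max(xs) - min(xs)
    if (w > best_w) {
      best_w <- w
      best <- list(row = y, x_left = min(xs), x_right = max(xs),
                   length_mm = w * dx)
    }
  }
  best
}

# Random blobby mask: union of a rectangle, a disk and speckle noise.
# Always non-empty. Uses the ambient RNG stream.
random_mask <- function(ny = 40L, nx = 40L) {
  m <- matrix(FALSE, ny, nx)
  y0 <- sample.int(ny - 4L, 1); x0 <- sample.int(nx - 4L, 1)
  m[y0:(y0 + sample.int(4, 1)), x0:(x0 + sample.int(4, 1))] <- TRUE
  cy <- runif(1, 5, ny - 5); cx <- runif(1, 5, nx - 5); r <- runif(1, 2, 8)
  d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+")
  m <- m | (d2 <= r^2)
  m | (matrix(runif(ny * nx), ny, nx) < 0.02)
}

# One-way ANOVA mean squares through stats::lm/anova — an independent route
# to ICC(1,1) compared with the implementation's direct mean-square formulas.
icc_oracle_anova <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(value = as.vector(tab),
                   subject = factor(rep(seq_len(n), times = k)))
  an <- stats::anova(stats::lm(value ~ subject, data = df))
  ms_r <- an["subject", "Mean Sq"]
  ms_w <- an["Residuals", "Mean Sq"]
  (ms_r - ms_w) / (ms_r + (k - 1) * ms_w)
}

# Single-slice volume for the rotation-robustness check: a thin "lung" strip
# through the center at global angle phi from vertical, and two ventricular
# disks whose center line makes theta degrees with the strip. Rotating phi
# co-rotates both lines, so the measured septal angle should stay ~theta.
strip_slice_volume <- function(phi_deg, theta_deg, n = 201L) {
  stopifnot(n %% 2L == 1L)
  c0 <- (n + 1) / 2
  yy <- matrix(seq_len(n) - c0, n, n)
  xx <- t(yy)
  phi <- phi_deg * pi / 180
  v <- c(cos(phi), sin(phi))            # strip direction (y, x)
  along <- yy * v[1] + xx * v[2]
  perp <- -yy * v[2] + xx * v[1]
  # thin ellipse, not a rectangle: its extreme points are sharp major-axis
  # tips that rotate rigidly (a rectangle's extreme corners do not)
  lung <- (along / 80)^2 + (perp / 6)^2 <= 1
  ang <- (phi_deg + theta_deg) * pi / 180
  u <- c(cos(ang), sin(ang))
  disk <- function(cy, cx, r) (yy - cy)^2 + (xx - cx)^2 <= r^2
  lv <- disk(36 * u[1], 36 * u[2], 12)
  rv <- disk(-36 * u[1], -36 * u[2], 12)
  stopifnot(!any(lung & (lv | rv)), !any(lv & rv))
  sl <- matrix(0L, n, n)
  sl[lung] <- 5L; sl[lv] <- 1L; sl[rv] <- 2L
  labeled_volume(array(sl, c(1L, n, n)), spacing = c(1, 1, 1))
}

# Small phantom settings used by fast tests (128 x 128 in-plane grid keeps
# the anatomy but quarters the rasterization work).
small_grid <- c(nz = 24L, ny = 128L, nx = 128L)
small_spacing <- c(dz = 5, dy = 1.4, dx = 1.4)

# Toy segmentation setup shared by the segmentation chain checks.
toy_seg_grid <- c(nz = 8L, ny = 64L, nx = 64L)
toy_seg_spacing <- c(dz = 5, dy = 2.8, dx = 2.8)
toy_seg_ranges <- function()
  utils::modifyList(default_phantom_ranges(),
                    list(z_heart = c(5L, 6L), z_pa = c(3L, 3L)))
toy_seg_config <- function(epochs = 20L)
  seg_train_config(input_size = c(64L, 64L, 3L), epochs = epochs,
                   learning_rate = 3e-3, depth = 2L, base_channels = 8L,
                   batch_size = 2L, seed = 3L, loss = "combined")
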