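#' Save a measurement overlay PNG
#'
#' Draws the selected heart and PA slices with the measured chords (RV/LV in
#' orange/green, PA/AA in orange/blue) and the septal and spine reference
#' lines, mirroring how the measurements are reported visually.
#'
#' @param vol The measured [labeled_volume()].
#' @param idx An `index_set` from [compute_indices()].
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
save_overlay <- function(vol, idx, path) {
  grDevices::png(path, width = 1200, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(2, 2, 3, 1))
  draw_slice <- function(z, title) {
    sl <- vol$labels[z, , ]
    ny <- nrow(sl); nx <- ncol(sl)
    # image(): x right, y flipped so row 1 is at the top as on a workstation
    graphics::image(seq_len(nx), seq_len(ny), t(sl[ny:1, ]),
                    col = c("black", "#00aa55", "#dd8800", "#cc4444",
                            "#4477cc", "#888888"),
                    zlim = c(0, 5), axes = FALSE, xlab = "", ylab = "",
                    main = title, asp = ny / nx)
    function(y, x0, x1, col) graphics::segments(x0, ny + 1 - y, x1, ny + 1 - y,
                                                col = col, lwd = 3)
  }
  seg1 <- draw_slice(idx$heart_slice,
                     sprintf("heart slice %d: RV/LV = %.3f, SA = %.1f deg",
                             idx$heart_slice, idx$rv_lv, idx$septal_angle_deg))
  seg1(idx$rv_chord$row, idx$rv_chord$x_left, idx$rv_chord$x_right, "white")
  seg1(idx$lv_chord$row, idx$lv_chord$x_left, idx$lv_chord$x_right, "yellow")
  ny <- dim(vol$labels)[2]
  draw_line <- function(line, col) {
    d <- line$direction; p <- line$point
    tt <- c(-ny, ny)
    graphics::lines(p[2] + tt * d[2], ny + 1 - (p[1] + tt * d[1]),
                    col = col, lwd = 2, lty = 2)
  }
  draw_line(idx$septal_line, "cyan")
  draw_line(idx$spine_line, "white")
  seg2 <- draw_slice(idx$pa_slice,
                     sprintf("PA slice %d: PA/AA = %.3f", idx$pa_slice, idx$pa_aa))
  seg2(idx$pa_chord$row, idx$pa_chord$x_left, idx$pa_chord$x_right, "white")
  seg2(idx$aa_chord$row, idx$aa_chord$x_left, idx$aa_chord$x_right, "yellow")
  invisible(path)
}
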