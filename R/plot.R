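format_bp_axis <- function(max_pos) {
  if (max_pos >= 2e6) list(div = 1e6, unit = "Mb")
  else if (max_pos >= 2e3) list(div = 1e3, unit = "kb")
  else list(div = 1, unit = "bp")
}

draw_panel <- function(samples, range = NULL, main = "") {
  s <- samples[!samples$masked & !is.na(samples$value), , drop = FALSE]
  if (!is.null(range)) {
    s <- s[s$pos >= range[1] & s$pos <= range[2], , drop = FALSE]
    if (nrow(s) == 0L) {
      warning("zoom range [", range[1], ", ", range[2],
              "] contains no samples; panel left empty")
      graphics::plot.new()
      return(invisible())
    }
  }
  ax <- format_bp_axis(max(s$pos))
  graphics::plot(s$pos / ax$div, s$value, type = "l", lwd = 0.6,
                 col = "#2c5f8a", xlab = sprintf("position (%s)", ax$unit),
                 ylab = "information (bits)", main = main)
}

#' Plot profile samples to an image file
#'
#' One whole-sequence panel plus one panel per zoom range, stacked
#' vertically. Zoom ranges outside the sequence are clipped with a
#' warning.
#'
#' @param samples samples `data.frame` (from [subsample_profile()] or a
#'   profile's `$samples`).
#' @param out_path output image path; `.png` or `.svg` decides the device.
#' @param zooms list of length-2 numeric vectors `c(from, to)` in bp.
#' @param title main title of the top panel.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return `out_path`, invisibly.
#' @export
plot_profile <- function(samples, out_path, zooms = list(),
                         title = samples$seq_id[1] %||% "profile",
                         width = 1400, height = 350 * (1 + length(zooms))) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0L)
  maxpos <- max(samples$pos)
  zooms <- lapply(zooms, function(z) {
    z <- sort(as.numeric(z[1:2]))
    if (z[1] < 1 || z[2] > maxpos) {
      warning("zoom range clipped to sequence bounds")
      z <- c(max(1, z[1]), min(maxpos, z[2]))
    }
    z
  })
  if (grepl("\\.svg$", out_path))
    grDevices::svg(out_path, width = width / 100, height = height / 100)
  else grDevices::png(out_path, width = width, height = height, res = 110)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1 + length(zooms), 1),
                mar = c(4, 4, 2.5, 1) + 0.1)
  draw_panel(samples, main = title)
  for (z in zooms)
    draw_panel(samples, range = z,
               main = sprintf("zoom %s-%s bp",
                              format(z[1], big.mark = ","),
                              format(z[2], big.mark = ",")))
  invisible(out_path)
}

#' @export
plot.information_profile <- function(x, step = x$config$sample_step, ...) {
  draw_panel(subsample_profile(x, step), main = x$seq_id)
  invisible(x)
}
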