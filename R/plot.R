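#' Rose plot of a circular sample
#'
#' Minimal base-graphics rose diagram with an optional von Mises kernel
#' density overlay, drawn in compass orientation (North up, clockwise).
#' Convenience surface for eyeballing simulated or read-in headings.
#'
#' @param sample an [angle_sample()] or numeric degrees.
#' @param bin_deg histogram bin width in degrees. Default 20.
#' @param kde optional [vonmises_kde()] result to overlay.
#' @param main plot title.
#' @return invisibly, the bin counts.
#' @export
rose_plot <- function(sample, bin_deg = 20, kde = NULL, main = "") {
  s <- as_angle_sample(sample)
  breaks <- seq(0, 360, by = bin_deg)
  counts <- graphics::hist(s$angles, breaks = breaks, plot = FALSE)$counts
  rel <- counts / max(counts)
  op <- graphics::par(pty = "s", mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), axes = FALSE,
                 xlab = "", ylab = "", main = main, asp = 1)
  tt <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(sin(tt), cos(tt), col = "grey60")
  for (i in seq_along(rel)) {
    a0 <- .deg2rad(breaks[i]); a1 <- .deg2rad(breaks[i + 1])
    aa <- seq(a0, a1, length.out = 8)
    graphics::polygon(c(0, rel[i] * sin(aa)), c(0, rel[i] * cos(aa)),
                      col = "grey80", border = "grey30")
  }
  if (!is.null(kde)) {
    d <- kde$density / max(kde$density)
    th <- .deg2rad(c(kde$grid_deg, kde$grid_deg[1]))
    dd <- c(d, d[1])
    graphics::lines(dd * sin(th), dd * cos(th), col = "firebrick", lwd = 2)
  }
  graphics::text(0, 1.12, "N"); graphics::text(1.12, 0, "E")
  graphics::text(0, -1.12, "S"); graphics::text(-1.12, 0, "W")
  invisible(counts)
}
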