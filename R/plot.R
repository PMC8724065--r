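#' Plot an ONEST result
#'
#' Draws OPA against the number of observers (k = 2..N; OPA is trivial at
#' k = 1). `style = "all_curves"` overlays every sampled OPA curve in grey
#' with the min/max/mean envelopes on top; `style = "envelope_only"` draws
#' just the minimum and maximum envelopes — the best- and worst-case
#' two-observer-onwards agreement.
#'
#' @param x an `onest_result`.
#' @param style `"all_curves"` or `"envelope_only"`.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.onest_result <- function(x, style = c("all_curves", "envelope_only"),
                              main = "ONEST plot", ...) {
  style <- match.arg(style)
  graphics::plot(NA, xlim = range(x$k), ylim = c(0, 1),
                 xlab = "Number of observers", ylab = "OPA",
                 main = main, xaxt = "n", ...)
  graphics::axis(1, at = x$k)
  if (style == "all_curves") {
    for (i in seq_len(nrow(x$curves))) {
      graphics::lines(x$k, x$curves[i, ], col = "grey70", lwd = 0.6)
    }
    graphics::lines(x$k, x$mean_curve, col = "black", lwd = 2)
  }
  graphics::lines(x$k, x$min_curve, col = "firebrick", lwd = 2)
  graphics::lines(x$k, x$max_curve, col = "steelblue", lwd = 2)
  graphics::abline(v = x$plateau_k, lty = 3)
  invisible(x)
}

#' Write an ONEST plot to an image file
#'
#' @param result an `onest_result`.
#' @param path output file; format chosen by extension (`.png` or `.svg`).
#' @param style passed to [plot.onest_result()].
#' @param width,height device size in inches.
#' @return invisibly, `path`.
#' @export
render_onest_plot <- function(result, path,
                              style = c("all_curves", "envelope_only"),
                              width = 6, height = 4.5) {
  style <- match.arg(style)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(path, width = width, height = height),
    stop("unsupported plot format: .", ext, call. = FALSE))
  on.exit(grDevices::dev.off())
  plot(result, style = style)
  invisible(path)
}
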