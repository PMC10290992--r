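# Base-graphics viewing helpers for frames, masks and MSE traces.

#' Display the magnitude of a frame
#'
#' @param cine a `cine_series`.
#' @param i frame index.
#' @param ... passed to [graphics::image()].
#' @export
plot_frame <- function(cine, i = 1L, ...) {
  m <- Mod(cine_frame(cine, i))
  graphics::image(t(m)[, nrow(m):1], col = grey.colors(256, 0, 1),
                  axes = FALSE, asp = 1,
                  main = sprintf("frame %d (phase %d)", i,
                                 cine$phase_labels[i]), ...)
  invisible(NULL)
}

#' Plot one or more MSE traces
#'
#' @param ... named numeric MSE traces.
#' @param cycle_length optional frames-per-cycle for vertical guides.
#' @param log use a log y-axis.
#' @export
plot_mse_trace <- function(..., cycle_length = NULL, log = TRUE) {
  traces <- list(...)
  if (is.null(names(traces)) || any(names(traces) == ""))
    names(traces) <- paste0("trace", seq_along(traces))
  ylim <- range(unlist(traces))
  graphics::plot(NULL, xlim = c(1, max(lengths(traces))), ylim = ylim,
                 log = if (log) "y" else "", xlab = "frame", ylab = "MSE")
  for (k in seq_along(traces))
    graphics::lines(traces[[k]], col = k, lwd = 1.5)
  if (!is.null(cycle_length))
    graphics::abline(v = seq(cycle_length, max(lengths(traces)),
                             by = cycle_length), lty = 3, col = "grey")
  graphics::legend("topright", names(traces), col = seq_along(traces),
                   lwd = 1.5, bty = "n")
  invisible(NULL)
}

#' Display a sampling pattern
#'
#' @param pattern a `sampling_pattern`.
#' @export
plot_pattern <- function(pattern) {
  if (!is.null(pattern$mask)) {
    graphics::image(t(pattern$mask)[, pattern$N:1], col = c("black", "white"),
                    axes = FALSE, asp = 1, main = pattern$kind)
  } else {
    graphics::plot(pattern$traj[, 2], -pattern$traj[, 1], pch = ".",
                   asp = 1, xlab = "k2", ylab = "k1", main = pattern$kind)
  }
  invisible(NULL)
}
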