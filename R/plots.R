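# Base-graphics views of trajectories and the phase plane.

#' @export
plot.ta_trajectory <- function(x, species = NULL, log = "y", ...) {
  df <- as.data.frame(x)
  if (is.null(species)) {
    species <- if ("x" %in% names(df)) "x" else "T"
  }
  v <- pmax(df[[species]], .Machine$double.xmin)
  graphics::plot(df$time, v, type = "l", log = log,
                 xlab = "time", ylab = species, ...)
  invisible(x)
}

#' @export
plot.ta_ssa_trajectory <- function(x, species = "T", ...) {
  df <- as.data.frame(x)
  graphics::plot(df$time, df[[species]], type = "s",
                 xlab = "time (s)", ylab = paste(species, "(molecules)"),
                 ...)
  invisible(x)
}

#' Phase-plane plot of the nullclines
#'
#' Log-log view of `NC(x)` (threshold branch dashed) and `NC(y)`, with
#' an optional overlaid trajectory.
#'
#' @param x A [nullclines()] result.
#' @param traj Optional trajectory with `x`, `y` columns.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ta_nullclines <- function(x, traj = NULL, ...) {
  df <- as.data.frame(x)
  pos <- df$nc_x > 0 & df$nc_y > 0
  rng_y <- range(c(df$nc_x[pos], df$nc_y[pos]))
  graphics::plot(range(df$x), rng_y, type = "n", log = "xy",
                 xlab = "x (toxin)", ylab = "y (complex)", ...)
  folds <- attr(x, "folds")
  if (length(folds) >= 2L) {
    mid <- df$x >= folds[1L] & df$x <= folds[2L]
    graphics::lines(df$x[!mid & df$nc_x > 0],
                    df$nc_x[!mid & df$nc_x > 0], col = "black")
    graphics::lines(df$x[mid & df$nc_x > 0], df$nc_x[mid & df$nc_x > 0],
                    col = "black", lty = 2)
  } else {
    graphics::lines(df$x[df$nc_x > 0], df$nc_x[df$nc_x > 0],
                    col = "black")
  }
  graphics::lines(df$x[df$nc_y > 0], df$nc_y[df$nc_y > 0], col = "grey50")
  if (!is.null(traj)) {
    graphics::lines(pmax(traj$x, 1e-12), pmax(traj$y, 1e-12),
                    col = "red")
  }
  invisible(x)
}

#' @export
plot.ta_branch <- function(x, ...) {
  graphics::plot(x$value, x$re_lambda, type = "l",
                 xlab = x$param[1L], ylab = "Re(leading eigenvalue)",
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
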