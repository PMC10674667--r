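# Base-graphics plot methods for the analysis result objects.

#' @export
plot.bilff_rdf <- function(x, ..., main = "radial distribution function") {
  plot(x$r, x$g, type = "l", xlab = "r / pm", ylab = "g(r)", main = main, ...)
  abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
plot.bilff_cdf <- function(x, ..., main = "distance-angle distribution") {
  image(x$r, x$angle, x$counts, col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "r / pm", ylab = "angle / deg", main = main, ...)
  invisible(x)
}

#' Plot a slice of a spatial distribution function
#'
#' @param x a `bilff_sdf`.
#' @param z z-position of the slice, pm (nearest grid plane is used).
#' @param ... passed to [graphics::image()].
#' @export
plot.bilff_sdf <- function(x, z = 0, ...) {
  k <- which.min(abs(x$axes - z))
  image(x$axes, x$axes, x$density[, , k],
        col = hcl.colors(64, "viridis"), xlab = "x / pm", ylab = "y / pm",
        main = sprintf("SDF slice at z = %.0f pm (nm^-3)", x$axes[k]), ...)
  invisible(x)
}

#' @export
plot.bilff_msd <- function(x, ...) {
  plot(x$msd$t_ps, x$msd$msd_pm2, type = "l", xlab = "lag / ps",
       ylab = expression(MSD / pm^2), main = "mean squared displacement", ...)
  abline(v = x$window_ps, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
plot.bilff_lifetime <- function(x, ...) {
  plot(x$curves$t_ps, x$curves$intermittent, type = "l", ylim = c(0, 1),
       xlab = "t / ps", ylab = "correlation",
       main = "hydrogen-bond correlation", ...)
  lines(x$curves$t_ps, x$curves$continuous, lty = 2)
  legend("topright", c("intermittent C(t)", "continuous S(t)"),
         lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Diagnostic plot of a trajectory (temperature, pressure, energies)
#'
#' @param x a `bilff_trajectory`.
#' @param ... unused.
#' @export
plot.bilff_trajectory <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  t_ps <- x$time / 1000
  plot(t_ps, x$temperature, type = "l", xlab = "t / ps", ylab = "T / K",
       main = "instantaneous temperature")
  plot(t_ps, x$epot, type = "l", xlab = "t / ps", ylab = "E_pot / kJ/mol",
       main = "potential energy")
  invisible(x)
}
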