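# Minimal base-graphics figures for the profile and curve classes.

#' @export
plot.overall_exchange_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    plot(x$time_min, x$mean_D, log = "x", xlab = "time [min]",
         ylab = "remaining deuterons", pch = 16, col = col, ...)
  } else {
    graphics::points(x$time_min, x$mean_D, pch = 16, col = col, ...)
  }
  if (any(is.finite(x$sem))) {
    graphics::arrows(x$time_min, x$mean_D - x$sem, x$time_min,
                     x$mean_D + x$sem, angle = 90, code = 3,
                     length = 0.02, col = col)
  }
  invisible(x)
}

#' @export
plot.delta_g_profile <- function(x, ...) {
  plot(x$residue_number, x$delta_g, xlab = "residue (C99 numbering)",
       ylab = expression(Delta * G ~ "[kcal/mol]"), pch = 16, ...)
  ok <- is.finite(x$ci_lo)
  graphics::arrows(x$residue_number[ok], x$ci_lo[ok],
                   x$residue_number[ok], x$ci_hi[ok],
                   angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' @export
plot.hbond_occupancy_profile <- function(x, ...) {
  plot(x$residue_number, x$occ_helix, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "residue (C99 numbering)", ylab = "H-bond occupancy", ...)
  graphics::lines(x$residue_number, x$occ_alpha, col = 2, lty = 2)
  graphics::lines(x$residue_number, x$occ_310, col = 4, lty = 3)
  graphics::legend("bottomright", c("helix", "alpha", "3-10"),
                   col = c(1, 2, 4), lty = c(1, 2, 3), bty = "n")
  invisible(x)
}

#' @export
plot.fluctuation_profile <- function(x, ...) {
  plot(x$residue_number, x$msf_norm, type = "b", pch = 16,
       xlab = "residue (C99 numbering)", ylab = "normalized MSF", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
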