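# Base-graphics displays for the comparison objects.

#' @export
plot.tte_port_effect <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$position, p$diff_pct, type = "l",
                 xlab = sprintf("position along %s (mm)", x$axis),
                 ylab = "dose difference (%)",
                 main = sprintf("%s vs %s", x$ref, x$test), ...)
  graphics::arrows(p$position, p$diff_pct - p$unc_pct,
                   p$position, p$diff_pct + p$unc_pct,
                   length = 0.02, angle = 90, code = 3,
                   col = "grey60")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
plot.tte_gamma <- function(x, ...) {
  if (is.null(x$position)) {
    graphics::hist(x$gamma[x$evaluated], breaks = 30,
                   xlab = "gamma", main = sprintf(
                     "gamma %g%%/%g mm, pass rate %.1f%%",
                     x$criteria[1], x$criteria[2], 100 * x$pass_rate), ...)
  } else {
    graphics::plot(x$position, x$gamma, type = "h",
                   xlab = "position (mm)", ylab = "gamma",
                   main = sprintf("gamma %g%%/%g mm, pass rate %.1f%%",
                                  x$criteria[1], x$criteria[2],
                                  100 * x$pass_rate), ...)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}
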