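#' Plot a hysteresis experiment
#'
#' Substrate stable-state concentrations against oxygen diffusivity for
#' both directions of environmental change, the standard
#' bifurcation-diagram view of the oxic/anoxic regime shift.  Oxygen is
#' drawn in red, sulfide in blue; solid lines trace the toward-oxic run
#' and dashed lines the toward-anoxic run.
#'
#' @param x A `symtip_hysteresis` object.
#' @param log_conc Plot concentrations on a log10 axis (default `TRUE`).
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.symtip_hysteresis <- function(x, log_conc = TRUE, ...) {
  up <- x$toward_oxic; dn <- x$toward_anoxic
  tr <- if (log_conc) function(v) log10(pmax(v, 1e-12)) else identity
  la <- log10(up$a_O)
  ylim <- range(tr(c(up$O, up$S, dn$O, dn$S)))
  graphics::plot(la, tr(up$O), type = "l", col = "red3",
                 xlab = expression(log[10] ~ alpha[O] ~ (h^-1)),
                 ylab = if (log_conc) "log10 concentration (uM)"
                        else "concentration (uM)",
                 ylim = ylim, ...)
  graphics::lines(la, tr(up$S), col = "steelblue3")
  graphics::lines(log10(dn$a_O), tr(dn$O), col = "red3", lty = 2)
  graphics::lines(log10(dn$a_O), tr(dn$S), col = "steelblue3", lty = 2)
  graphics::legend("right", bty = "n", lty = c(1, 1, 1, 2),
                   col = c("red3", "steelblue3", "grey30", "grey30"),
                   legend = c("oxygen", "sulfide", "toward oxic",
                              "toward anoxic"))
  invisible(x)
}
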