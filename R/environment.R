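#' Counter-varying diffusivity gradient
#'
#' Builds the paired oxygen/sulfide diffusivity sequence along which stable
#' states are collected.  Oxygen diffusivity always spans `1e-2` to `1e0`
#' 1/h on a log10-equispaced grid.  Sulfide diffusivity varies in the
#' opposite sense over a range whose log10 half-width about the midpoint
#' `1e-1` is scaled by the environmental asymmetry `factor`: factor 1 gives
#' the mirrored symmetric range `1e-2` to `1e0`, factor 0.8 the narrower
#' `10^-1.8` to `10^-0.2`, factor 2 the wider `10^-3` to `10^1`, and factor
#' 0 a constant `1e-1`.
#'
#' @param n_steps Number of gradient steps (>= 2).
#' @param factor Environmental asymmetry factor, a nonnegative scalar
#'   (values in `[0, 2]` are explored in practice).
#' @param direction `"toward_oxic"` (oxygen diffusivity increasing) or
#'   `"toward_anoxic"` (decreasing).
#' @return A data frame of class `driver_sequence` with columns
#'   `step`, `a_O`, `a_S`, and attributes `direction` and `factor`.
#' @export
#' @examples
#' head(driver_sequence(11, factor = 0.8))
driver_sequence <- function(n_steps = 101L, factor = 1,
                            direction = c("toward_oxic", "toward_anoxic")) {
  direction <- match.arg(direction)
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2 ||
      n_steps != round(n_steps))
    stop("n_steps must be an integer >= 2", call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 0)
    stop("environmental asymmetry factor must be a nonnegative number",
         call. = FALSE)
  la_O <- seq(-2, 0, length.out = n_steps)
  la_S <- -1 - factor * (la_O + 1)     # mirrored about log10 midpoint -1
  if (direction == "toward_anoxic") {
    la_O <- rev(la_O)
    la_S <- rev(la_S)
  }
  structure(
    data.frame(step = seq_len(n_steps), a_O = 10^la_O, a_S = 10^la_S),
    direction = direction, factor = factor,
    class = c("driver_sequence", "data.frame"))
}

#' Three-ramp temporal driver schedule
#'
#' A piecewise-constant schedule used to visualize the temporal dynamics:
#' an initial hold at the anoxic-favoring extreme (high sulfide, low oxygen
#' diffusivity) followed by three ramps -- toward the oxic extreme, back to
#' the anoxic extreme, and toward the oxic extreme again -- so that the
#' trajectory crosses a tipping point three times (anoxic-to-oxic,
#' oxic-to-anoxic, anoxic-to-oxic).  Each ramp is a staircase of
#' `n_steps_per_ramp` log10-equispaced driver values, each held for
#' `step_duration` hours.
#'
#' @param n_steps_per_ramp Driver steps per ramp.
#' @param step_duration Hold time per staircase step, h.
#' @param factor Environmental asymmetry factor (see [driver_sequence()]).
#' @param hold_duration Duration of the initial anoxic-favoring hold, h
#'   (default one staircase step).
#' @return A data frame of class `temporal_pattern` with columns
#'   `time_h` (start time of each constant-driver segment),
#'   `duration_h`, `a_O`, `a_S`.
#' @export
temporal_pattern <- function(n_steps_per_ramp = 50L, step_duration = 1e6,
                             factor = 1, hold_duration = step_duration) {
  if (n_steps_per_ramp < 2 || n_steps_per_ramp != round(n_steps_per_ramp))
    stop("n_steps_per_ramp must be an integer >= 2", call. = FALSE)
  if (step_duration <= 0 || hold_duration <= 0)
    stop("durations must be positive", call. = FALSE)
  up <- driver_sequence(n_steps_per_ramp, factor, "toward_oxic")
  dn <- driver_sequence(n_steps_per_ramp, factor, "toward_anoxic")
  # drop the duplicated endpoint where consecutive ramps meet
  seg <- rbind(up[, c("a_O", "a_S")],
               dn[-1L, c("a_O", "a_S")],
               up[-1L, c("a_O", "a_S")])
  dur <- c(hold_duration + step_duration,
           rep(step_duration, nrow(seg) - 1L))
  structure(
    data.frame(time_h = cumsum(c(0, dur[-length(dur)])),
               duration_h = dur, a_O = seg$a_O, a_S = seg$a_S,
               row.names = NULL),
    factor = factor, step_duration = step_duration,
    class = c("temporal_pattern", "data.frame"))
}

#' Export a driver schedule as CSV
#'
#' @param drivers A `driver_sequence` or `temporal_pattern`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drivers_csv <- function(drivers, path) {
  utils::write.csv(as.data.frame(drivers), path, row.names = FALSE)
  invisible(path)
}
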