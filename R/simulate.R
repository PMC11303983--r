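#' Simulation settings for the stable-state protocol
#'
#' @param step_duration Biological time simulated at each gradient step, h.
#'   Must be a positive multiple of `immigration_interval`.
#' @param immigration_interval Interval between immigration events, h.
#' @param immigration_amount Cells/L added to each bacterial group at every
#'   immigration event.  Immigration is a discrete impulse, preventing
#'   either group from being absorbed at zero density.
#' @param initial_state Starting state of every independent run (see
#'   [system_state()]).
#' @param rtol Relative tolerance of the stiff integrator.
#' @param atol Absolute tolerances, one per state variable (cells/L for the
#'   densities, uM for the concentrations).
#' @param steady_state_residual_tol Diagnostic threshold on the relative
#'   derivative norm at the end of a gradient step (1/h); exceedances are
#'   flagged with a warning, not an error.
#' @param early_exit If `TRUE`, a gradient step may end before
#'   `step_duration` once the residual norm has stayed below
#'   `steady_state_residual_tol` for 10 consecutive immigration intervals.
#'   Off by default: the default protocol always integrates the full step.
#' @return An object of class `symtip_settings`.
#' @export
sim_settings <- function(step_duration = 1e6,
                         immigration_interval = 1000,
                         immigration_amount = 1,
                         initial_state = system_state(1e5, 1e5, 20, 20, 10),
                         rtol = 1e-8,
                         atol = c(N_CB = 1e-3, N_SB = 1e-3,
                                  O = 1e-9, S = 1e-9, P = 1e-9),
                         steady_state_residual_tol = 1e-5,
                         early_exit = FALSE) {
  if (step_duration <= 0 || immigration_interval <= 0)
    stop("durations must be positive", call. = FALSE)
  n_chunk <- step_duration / immigration_interval
  if (abs(n_chunk - round(n_chunk)) > 1e-8)
    stop("step_duration must be a positive multiple of immigration_interval",
         call. = FALSE)
  if (immigration_amount < 0)
    stop("immigration_amount must be nonnegative", call. = FALSE)
  if (rtol <= 0 || any(atol <= 0))
    stop("integrator tolerances must be positive", call. = FALSE)
  if (length(atol) == 1L) atol <- rep(atol, 5L)
  stopifnot(length(atol) == 5L)
  structure(list(step_duration = step_duration,
                 immigration_interval = immigration_interval,
                 immigration_amount = immigration_amount,
                 initial_state = system_state(
                   unname(initial_state["N_CB"]),
                   unname(initial_state["N_SB"]),
                   unname(initial_state["O"]),
                   unname(initial_state["S"]),
                   unname(initial_state["P"])),
                 rtol = rtol, atol = unname(atol),
                 steady_state_residual_tol = steady_state_residual_tol,
                 early_exit = early_exit),
            class = "symtip_settings")
}

# parameter vector in the order expected by the compiled right-hand side
.ode_parms <- function(params, a_O, a_S) {
  c(unlist(params[.param_fields], use.names = FALSE), a_O, a_S)
}

# relative derivative norm used as the steady-state residual:
# max_i |dx_i/dt| / max(|x_i|, scale_i), in 1/h
.residual_norm <- function(state, params, a_O, a_S) {
  f <- model_derivatives(state, params, a_O, a_S)
  scale <- pmax(abs(state), c(1, 1, 1e-3, 1e-3, 1e-3))
  max(abs(f) / scale)
}

# one lsoda call over [0, duration] with immigration impulses at the given
# local times; returns the (floored) state matrix at `times`
.integrate_chunk <- function(state, parms, times, event_times, amount,
                             rtol, atol) {
  ev <- NULL
  all_times <- times
  if (length(event_times) && amount > 0) {
    ev <- list(data = data.frame(
      var = rep(1:2, times = length(event_times)),
      time = rep(event_times, each = 2L),
      value = amount, method = "add"))
    all_times <- sort(unique(c(times, event_times)))
  }
  out <- deSolve::ode(y = state, times = all_times, func = "symtip_derivs",
                      parms = parms, dllname = "symtip",
                      initfunc = "symtip_init", method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 10000,
                      events = ev)
  if (attr(out, "istate")[1L] < 0)
    stop("integrator failure at t = ", out[nrow(out), 1L], call. = FALSE)
  out[match(times, all_times), , drop = FALSE]
}

# floor sub-zero integrator excursions at zero; excursions beyond the
# absolute-tolerance scale are reported, sub-tolerance noise is not
.floor_state <- function(x, warn_below = -1e-2) {
  neg <- x < 0
  if (any(x < warn_below))
    warning("state floored at zero (most negative: ",
            signif(min(x), 3), ")", call. = FALSE)
  x[neg] <- 0
  x
}

#' Integrate one gradient step
#'
#' Integrates the model over `settings$step_duration` hours at constant
#' diffusivities, adding `immigration_amount` cells/L to both groups every
#' `immigration_interval` hours (at the interior interval boundaries, so the
#' returned state has relaxed for one full interval after the last impulse).
#'
#' Immigration impulses fall on the global interval clock, including the
#' final interval boundary; the steady-state residual is evaluated just
#' before that final impulse, so it measures the relaxed system state and
#' excludes the impulse itself.
#'
#' @param state Named starting state vector.
#' @param params A `symtip_params` object.
#' @param a_O,a_S Oxygen and sulfide diffusivities, 1/h.
#' @param settings A `symtip_settings` object.
#' @return A list with elements `state` (named end-of-step state vector,
#'   floored at zero, including the final immigration impulse) and
#'   `residual` (relative derivative norm at the end of the step, 1/h,
#'   pre-impulse).
#' @export
integrate_step <- function(state, params, a_O, a_S,
                           settings = sim_settings()) {
  stopifnot(inherits(params, "symtip_params"),
            inherits(settings, "symtip_settings"))
  if (a_O < 0 || a_S < 0)
    stop("diffusivities must be nonnegative", call. = FALSE)
  if (!all(is.finite(state)))
    stop("non-finite starting state", call. = FALSE)
  parms <- .ode_parms(params, a_O, a_S)
  dt <- settings$immigration_interval
  n_chunk <- round(settings$step_duration / dt)

  x <- state[.state_fields]
  if (!isTRUE(settings$early_exit)) {
    ev <- if (n_chunk > 1L) dt * seq_len(n_chunk - 1L) else numeric(0)
    out <- .integrate_chunk(x, parms, c(0, settings$step_duration), ev,
                            settings$immigration_amount,
                            settings$rtol, settings$atol)
    x <- .floor_state(out[nrow(out), 1L + seq_len(5L)])
    names(x) <- .state_fields
  } else {
    # blocks of 10 immigration intervals; stop once all 10 end-of-interval
    # residuals in a block are below tolerance
    block <- 10L
    done <- 0L
    repeat {
      k <- min(block, n_chunk - done)
      times <- dt * (0:k)
      ev <- dt * seq_len(k - 1L)
      out <- .integrate_chunk(x, parms, times, ev,
                              settings$immigration_amount,
                              settings$rtol, settings$atol)
      states <- out[-1L, 1L + seq_len(5L), drop = FALSE]
      x <- .floor_state(states[nrow(states), ])
      names(x) <- .state_fields
      done <- done + k
      if (done >= n_chunk) break
      if (k == block) {
        res <- apply(states, 1L, function(r) {
          r <- pmax(r, 0); names(r) <- .state_fields
          .residual_norm(r, params, a_O, a_S)
        })
        if (all(res < settings$steady_state_residual_tol)) break
      }
      # impulse at the block seam keeps the global immigration clock
      x[1:2] <- x[1:2] + settings$immigration_amount
    }
  }
  residual <- .residual_norm(x, params, a_O, a_S)
  x[1:2] <- x[1:2] + settings$immigration_amount  # final-boundary impulse
  list(state = x, residual = residual)
}

#' Run the stable-state protocol along one driver direction
#'
#' Starts from `settings$initial_state` and, for each gradient step, calls
#' [integrate_step()] carrying the end state forward, so that the state
#' recorded at every driver value reflects the system's history.
#'
#' @param params A `symtip_params` object.
#' @param drivers A [driver_sequence()].
#' @param settings A `symtip_settings` object.
#' @param quiet Suppress per-step progress messages (default `TRUE`).
#' @return A data frame of class `stable_states` with one row per gradient
#'   step: `step`, `a_O`, `a_S`, the five state variables, and `residual`.
#'   Steps whose residual exceeds `steady_state_residual_tol` are reported
#'   with a single warning.
#' @export
run_direction <- function(params, drivers, settings = sim_settings(),
                          quiet = TRUE) {
  stopifnot(inherits(drivers, "driver_sequence"))
  n <- nrow(drivers)
  states <- matrix(NA_real_, n, 5L,
                   dimnames = list(NULL, .state_fields))
  residuals <- numeric(n)
  x <- settings$initial_state
  for (i in seq_len(n)) {
    step <- tryCatch(
      integrate_step(x, params, drivers$a_O[i], drivers$a_S[i], settings),
      error = function(e) stop("simulation failed at gradient step ", i,
                               " (a_O = ", signif(drivers$a_O[i], 4), "): ",
                               conditionMessage(e), call. = FALSE))
    x <- step$state
    states[i, ] <- x
    residuals[i] <- step$residual
    if (!quiet)
      message(sprintf("step %d/%d a_O=%.4g a_S=%.4g residual=%.3g",
                      i, n, drivers$a_O[i], drivers$a_S[i], step$residual))
  }
  bad <- which(residuals > settings$steady_state_residual_tol)
  if (length(bad))
    warning("end-of-step residual above tolerance at step(s) ",
            paste(bad, collapse = ", "), call. = FALSE)
  structure(
    cbind(drivers[, c("step", "a_O", "a_S")], as.data.frame(states),
          residual = residuals),
    direction = attr(drivers, "direction"), factor = attr(drivers, "factor"),
    class = c("stable_states", "data.frame"))
}

#' Run the two-direction hysteresis experiment
#'
#' Builds the two opposite driver sequences for the given environmental
#' asymmetry factor and runs [run_direction()] independently for each, both
#' starting from the same initial state.  The long equilibration of the
#' first gradient step establishes the attractor appropriate to each
#' direction's starting extreme.
#'
#' @param params A `symtip_params` object.
#' @param factor Environmental asymmetry factor (see [driver_sequence()]).
#' @param settings A `symtip_settings` object.
#' @param n_steps Number of gradient steps per direction.
#' @param quiet Suppress progress messages.
#' @return An object of class `symtip_hysteresis`: a list with elements
#'   `toward_oxic` and `toward_anoxic` (both `stable_states` data frames),
#'   plus `factor`, `n_steps`, `params` and `settings`.
#' @export
run_hysteresis <- function(params, factor = 1, settings = sim_settings(),
                           n_steps = 101L, quiet = TRUE) {
  up <- run_direction(params, driver_sequence(n_steps, factor,
                                              "toward_oxic"),
                      settings, quiet = quiet)
  dn <- run_direction(params, driver_sequence(n_steps, factor,
                                              "toward_anoxic"),
                      settings, quiet = quiet)
  structure(list(toward_oxic = up, toward_anoxic = dn, factor = factor,
                 n_steps = as.integer(n_steps), params = params,
                 settings = settings),
            class = "symtip_hysteresis")
}

#' @export
print.symtip_hysteresis <- function(x, ...) {
  cat("Hysteresis experiment:", x$n_steps, "gradient steps per direction,",
      "environmental asymmetry factor", x$factor, "\n")
  invisible(x)
}

#' Integrate a temporal driver schedule
#'
#' Integrates continuously across a piecewise-constant driver schedule
#' (see [temporal_pattern()]), carrying state and the immigration clock
#' across segment boundaries, and records the state at a fixed output
#' cadence.
#'
#' @param params A `symtip_params` object.
#' @param pattern A `temporal_pattern` (or any data frame with columns
#'   `time_h`, `duration_h`, `a_O`, `a_S`).  A zero-row schedule yields an
#'   empty trajectory.
#' @param settings A `symtip_settings` object (`step_duration` is ignored;
#'   segment durations come from the schedule).
#' @param record_every Output cadence, h; must divide the immigration
#'   interval into or be a multiple of it such that segment durations are
#'   multiples of it.
#' @return A data frame of class `symtip_trajectory` with columns `time_h`,
#'   `a_O`, `a_S` and the five state variables.
#' @export
run_temporal <- function(params, pattern, settings = sim_settings(),
                         record_every = 1000) {
  stopifnot(inherits(params, "symtip_params"),
            inherits(settings, "symtip_settings"))
  empty <- data.frame(time_h = numeric(0), a_O = numeric(0),
                      a_S = numeric(0), N_CB = numeric(0),
                      N_SB = numeric(0), O = numeric(0), S = numeric(0),
                      P = numeric(0))
  if (nrow(pattern) == 0L)
    return(structure(empty, class = c("symtip_trajectory", "data.frame")))
  dt <- settings$immigration_interval
  x <- settings$initial_state
  rows <- vector("list", nrow(pattern))
  t0 <- 0
  for (i in seq_len(nrow(pattern))) {
    d <- pattern$duration_h[i]
    if (abs(d / record_every - round(d / record_every)) > 1e-8 ||
        abs(d / dt - round(d / dt)) > 1e-8)
      stop("segment durations must be multiples of record_every and of ",
           "the immigration interval", call. = FALSE)
    parms <- .ode_parms(params, pattern$a_O[i], pattern$a_S[i])
    times <- seq(0, d, by = record_every)
    ev <- dt * seq_len(round(d / dt) - 1L)  # interior immigration impulses
    out <- .integrate_chunk(x, parms, times, ev,
                            settings$immigration_amount,
                            settings$rtol, settings$atol)
    m <- out[, 1L + seq_len(5L), drop = FALSE]
    m[m < 0] <- 0
    keep <- if (i == 1L) seq_len(nrow(out)) else -1L  # drop duplicated t0
    rows[[i]] <- data.frame(time_h = t0 + out[keep, 1L],
                            a_O = pattern$a_O[i], a_S = pattern$a_S[i],
                            m[keep, , drop = FALSE])
    x <- m[nrow(m), ]
    names(x) <- .state_fields
    # segment-boundary impulse keeps the global immigration clock
    x[1:2] <- x[1:2] + settings$immigration_amount
    t0 <- t0 + d
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  structure(traj, class = c("symtip_trajectory", "data.frame"))
}
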