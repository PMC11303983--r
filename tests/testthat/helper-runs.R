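# Shared, lazily computed simulation runs.  The heavy stable-state
# experiments are reused across test files; each is computed at most once
# per test session.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache, inherits = FALSE))
    assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache, inherits = FALSE)
}

# full-resolution hysteresis experiments under the default protocol
hyst_sym <- function()
  cached_run("sym", run_hysteresis(symmetric_parameters(), factor = 1,
                                   settings = sim_settings(),
                                   n_steps = 101L))

hyst_factor <- function(f)
  cached_run(paste0("f", f),
             run_hysteresis(symmetric_parameters(), factor = f,
                            settings = sim_settings(), n_steps = 101L))

hyst_HO <- function(H_O)
  cached_run(paste0("HO", H_O),
             run_hysteresis(update_parameters(symmetric_parameters(),
                                              H_O = H_O),
                            factor = 1, settings = sim_settings(),
                            n_steps = 101L))

# symmetric three-ramp temporal simulation (50 staircase steps per ramp)
temporal_sym <- function()
  cached_run("temporal", {
    pattern <- temporal_pattern(n_steps_per_ramp = 50L,
                                step_duration = 1e6, factor = 1)
    run_temporal(symmetric_parameters(), pattern, sim_settings(),
                 record_every = 500)
  })

# end of the initial anoxic-favoring hold in temporal_sym()
temporal_burn_in <- function() {
  temporal_pattern(n_steps_per_ramp = 50L, step_duration = 1e6,
                   factor = 1)$time_h[2]
}

# brute-force reference for tipping detection: scan every consecutive pair
oracle_detect <- function(states, metric = "log10", floor = 0.5) {
  tr <- if (metric == "log10") function(x) log10(pmax(x, 1e-12)) else identity
  n <- nrow(states)
  best <- NULL; best_i <- NULL
  la <- log10(states$a_O)
  centre <- mean(range(la))
  closer <- function(a, b) {
    da <- abs((la[a] + la[a + 1L]) / 2 - centre)
    db <- abs((la[b] + la[b + 1L]) / 2 - centre)
    da < db - 1e-12
  }
  for (i in seq_len(n - 1L)) {
    ch <- max(abs(tr(states$O[i + 1L]) - tr(states$O[i])),
              abs(tr(states$S[i + 1L]) - tr(states$S[i])))
    if (is.null(best) || ch > best + 1e-12 * max(1, best)) {
      best <- ch; best_i <- i
    } else if (abs(ch - best) <= 1e-12 * max(1, best) &&
               closer(i, best_i)) {
      best_i <- i
    }
  }
  if (best < floor) return(NULL)
  list(index = best_i,
       magnitude_O = abs(tr(states$O[best_i + 1L]) - tr(states$O[best_i])),
       magnitude_S = abs(tr(states$S[best_i + 1L]) - tr(states$S[best_i])),
       location_log10_a_O = (la[best_i] + la[best_i + 1L]) / 2,
       transition = if (states$O[best_i + 1L] > states$O[best_i])
         "anoxic_to_oxic" else "oxic_to_anoxic")
}

# toy stable-state table with controlled substrate jumps (log10 units)
toy_states <- function(n, jump_at, jump_O, jump_S, la_range = c(-2, 0),
                       base_O = 0, base_S = 2, wiggle = 0.002) {
  la <- seq(la_range[1], la_range[2], length.out = n)
  lo <- base_O + cumsum(c(0, stats::runif(n - 1L, -wiggle, wiggle)))
  ls <- base_S + cumsum(c(0, stats::runif(n - 1L, -wiggle, wiggle)))
  lo[(jump_at + 1L):n] <- lo[(jump_at + 1L):n] + jump_O
  ls[(jump_at + 1L):n] <- ls[(jump_at + 1L):n] + jump_S
  data.frame(step = seq_len(n), a_O = 10^la, a_S = 10^rev(la),
             O = 10^lo, S = 10^ls)
}

fake_hysteresis <- function(up, dn, factor = 1) {
  structure(list(toward_oxic = up, toward_anoxic = dn, factor = factor,
                 n_steps = nrow(up), params = symmetric_parameters(),
                 settings = sim_settings()),
            class = "symtip_hysteresis")
}
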