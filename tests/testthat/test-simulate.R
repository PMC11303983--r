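test_that("bacteria-free, oxidation-free substrates relax to the closed form", {
  # with no organisms and c = 0, each substrate is an independent linear
  # relaxation toward its background: X(t) = X_b + (X_0 - X_b) exp(-a t)
  p <- update_parameters(symmetric_parameters(), c = 0)
  s <- sim_settings(step_duration = 2000, immigration_amount = 0,
                    initial_state = system_state(0, 0, 20, 20, 10))
  a_O <- 2e-4; a_S <- 5e-4
  r <- integrate_step(s$initial_state, p, a_O, a_S, s)
  expect_equal(unname(r$state["O"]), 100 + (20 - 100) * exp(-a_O * 2000),
               tolerance = 1e-6)
  expect_equal(unname(r$state["S"]), 100 + (20 - 100) * exp(-a_S * 2000),
               tolerance = 1e-6)
  expect_equal(unname(r$state["P"]), 10)   # starts at background
  expect_equal(unname(r$state[c("N_CB", "N_SB")]), c(0, 0))
})

test_that("the integrated flow commutes with the mirror swap", {
  p <- symmetric_parameters()
  x <- system_state(1e5, 2e6, 30, 5, 8)   # deliberately asymmetric state
  s <- sim_settings(step_duration = 5000)
  a <- integrate_step(x, p, 0.3, 0.02, s)$state
  b <- integrate_step(mirror_state(x), p, 0.02, 0.3, s)$state
  expect_equal(mirror_state(a), b, tolerance = 1e-10)
})

test_that("immigration keeps both groups strictly positive", {
  p <- symmetric_parameters()
  # strongly anoxic conditions: cyanobacteria are suppressed, yet the
  # recorded state retains at least the immigration stock
  s <- sim_settings(step_duration = 10000)
  r <- integrate_step(s$initial_state, p, 1e-2, 1e0, s)
  expect_gte(unname(r$state["N_CB"]), s$immigration_amount)
  expect_gte(unname(r$state["N_SB"]), s$immigration_amount)
})

test_that("doubling the step duration leaves the recorded stable state unchanged", {
  p <- symmetric_parameters()
  sA <- sim_settings(step_duration = 1e5)
  sB <- sim_settings(step_duration = 2e5)
  a <- integrate_step(sA$initial_state, p, 1e-2, 1e0, sA)$state
  b <- integrate_step(sB$initial_state, p, 1e-2, 1e0, sB)$state
  expect_equal(a[c("O", "S", "P")], b[c("O", "S", "P")], tolerance = 1e-8)
  expect_equal(a["N_SB"] / b["N_SB"], c(N_SB = 1), tolerance = 1e-8)
})

test_that("the optional early exit reproduces the full-step state", {
  p <- symmetric_parameters()
  full <- sim_settings(step_duration = 1e5)
  fast <- sim_settings(step_duration = 1e5, early_exit = TRUE)
  a <- integrate_step(full$initial_state, p, 1e-2, 1e0, full)$state
  b <- integrate_step(fast$initial_state, p, 1e-2, 1e0, fast)$state
  expect_equal(a[c("O", "S", "P")], b[c("O", "S", "P")], tolerance = 1e-6)
})

test_that("settings are validated", {
  expect_error(sim_settings(step_duration = 1500,
                            immigration_interval = 1000),
               "multiple")
  expect_error(sim_settings(rtol = 0), "positive")
  expect_error(sim_settings(immigration_amount = -1), "nonnegative")
})

test_that("run_direction carries state forward and records residuals", {
  p <- symmetric_parameters()
  s <- sim_settings(step_duration = 20000)
  d <- driver_sequence(5, factor = 1, direction = "toward_oxic")
  out <- run_direction(p, d, s)
  expect_s3_class(out, "stable_states")
  expect_equal(nrow(out), 5L)
  expect_equal(out$a_O, d$a_O)
  expect_true(all(is.finite(out$residual)))
  expect_true(all(as.matrix(out[, c("N_CB", "N_SB", "O", "S", "P")]) >= 0))
  # history dependence inside the bistable region: the carried run stays
  # on the anoxic branch at mid-gradient, a fresh symmetric start does not
  fresh <- integrate_step(s$initial_state, p, d$a_O[3], d$a_S[3], s)$state
  expect_false(isTRUE(all.equal(unname(fresh["S"]), out$S[3],
                                tolerance = 1e-3)))
})

test_that("a one-segment schedule agrees with integrate_step", {
  p <- symmetric_parameters()
  s <- sim_settings(step_duration = 10000)
  pat <- data.frame(time_h = 0, duration_h = 10000, a_O = 0.05, a_S = 0.2)
  traj <- run_temporal(p, pat, s, record_every = 1000)
  expect_equal(nrow(traj), 11L)
  ref <- integrate_step(s$initial_state, p, 0.05, 0.2, s)$state
  last <- unlist(traj[nrow(traj), c("O", "S", "P")])
  expect_equal(last, ref[c("O", "S", "P")], tolerance = 1e-10)
})

test_that("a zero-length schedule yields an empty trajectory", {
  traj <- run_temporal(symmetric_parameters(),
                       data.frame(time_h = numeric(0),
                                  duration_h = numeric(0),
                                  a_O = numeric(0), a_S = numeric(0)),
                       sim_settings())
  expect_s3_class(traj, "symtip_trajectory")
  expect_equal(nrow(traj), 0L)
})
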