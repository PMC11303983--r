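test_that("tipping detection matches the brute-force scan on randomized sequences", {
  set.seed(7)
  for (k in 1:30) {
    n <- sample(10:60, 1)
    i <- sample(2:(n - 2L), 1)
    jO <- stats::runif(1, 0.6, 2.5) * sample(c(-1, 1), 1)
    jS <- stats::runif(1, 0.6, 2.5) * -sign(jO)
    toy <- toy_states(n, i, jO, jS)
    tp <- detect_tipping(toy)
    ref <- oracle_detect(toy)
    expect_equal(tp$index, ref$index)
    expect_equal(tp$magnitude_O, ref$magnitude_O)
    expect_equal(tp$magnitude_S, ref$magnitude_S)
    expect_equal(tp$location_log10_a_O, ref$location_log10_a_O)
    expect_identical(tp$transition, ref$transition)
  }
})

test_that("a lone oxygen jump is located and sized exactly", {
  set.seed(1)
  # oxygen jumps from 1 to 100 uM between steps 5 and 6, <1% drift elsewhere
  toy <- toy_states(12, 5, jump_O = 2, jump_S = -1.3, wiggle = 0.001)
  tp <- detect_tipping(toy)
  expect_true(tp$detected)
  expect_identical(tp$index, 5L)
  expect_equal(tp$magnitude_O, 2, tolerance = 1e-3)
  expect_identical(tp$transition, "anoxic_to_oxic")
  expect_equal(total_shift_magnitude(tp), 3.3, tolerance = 1e-3)
})

test_that("gentle monotone drift yields an explicit no-tipping result", {
  la <- seq(-2, 0, length.out = 20)
  gentle <- data.frame(a_O = 10^la, O = 10^seq(0, 0.4, length.out = 20),
                       S = 10^seq(2, 1.7, length.out = 20))
  tp <- detect_tipping(gentle)
  expect_false(tp$detected)
  expect_true(is.na(tp$total_magnitude))
  expect_error(post_shift_plateau(gentle, tp), "no tipping")
  expect_error(detect_tipping(gentle[1, ]), "two stable states")
})

test_that("the total shift magnitude is the sum of the two substrate magnitudes", {
  set.seed(2)
  toy <- toy_states(15, 7, jump_O = 1.2, jump_S = -0.8, wiggle = 0)
  tp <- detect_tipping(toy)
  expect_equal(tp$magnitude_O, 1.2)
  expect_equal(tp$magnitude_S, 0.8)
  expect_equal(total_shift_magnitude(tp), 2)
  expect_equal(tp$total_magnitude, tp$magnitude_O + tp$magnitude_S)
})

test_that("tied maxima break toward the gradient midpoint, deterministically", {
  la <- seq(-2, 0, length.out = 9)
  O <- rep(1, 9); S <- rep(100, 9)
  # two identical jumps: between steps 2-3 (off-centre) and 4-5 (central)
  O[3:9] <- 10; O[5:9] <- 100
  toy <- data.frame(a_O = 10^la, O = O, S = S)
  tp <- detect_tipping(toy)
  expect_true(tp$tie)
  expect_identical(tp$index, 4L)          # the central pair wins
  # mirroring the sequence picks the mirrored pair, equally central
  toy2 <- data.frame(a_O = 10^la, O = rev(100 / O), S = S)
  tp2 <- detect_tipping(toy2)
  expect_identical(tp2$index, 5L)
  expect_equal(abs(tp2$location_log10_a_O + 1), abs(tp$location_log10_a_O + 1))
})

test_that("raw-concentration mode measures magnitudes in uM", {
  set.seed(3)
  toy <- toy_states(15, 7, jump_O = 2, jump_S = -2, wiggle = 0)
  tp <- detect_tipping(toy, metric = "raw")
  expect_true(tp$detected)
  expect_equal(tp$magnitude_O, 100 - 1)    # 1 -> 100 uM
  expect_equal(tp$magnitude_S, 100 - 1)    # 100 -> 1 uM
})

test_that("self-comparison gives zero location shifts and zero asymmetry", {
  set.seed(4)
  up <- toy_states(21, 10, 2, -2, wiggle = 0)
  dn <- toy_states(21, 8, -2, 2, wiggle = 0)
  h <- fake_hysteresis(up, dn)
  rep <- analyze_hysteresis(h)
  rep <- compare_to_symmetric(rep, analyze_hysteresis(h))
  expect_equal(rep$location_shift_up, 0)
  expect_equal(rep$location_shift_down, 0)
  expect_equal(rep$magnitude_asymmetry, 0)
  expect_gte(rep$bistability_width, 0)
})

test_that("post-shift plateau reads the branch beyond the tipping step", {
  set.seed(5)
  up <- toy_states(21, 10, 2, -2, wiggle = 0)
  tp <- detect_tipping(up)
  expect_equal(post_shift_plateau(up, tp, "O"), max(up$O[11:21]))
})

test_that("missing tipping points propagate as flags, not errors", {
  la <- seq(-2, 0, length.out = 10)
  flat <- data.frame(a_O = 10^la, O = rep(1, 10), S = rep(100, 10))
  set.seed(6)
  up <- toy_states(10, 5, 2, -2, wiggle = 0)
  h <- fake_hysteresis(up, flat)
  rep <- analyze_hysteresis(h)
  expect_false(rep$tp_oxic_to_anoxic$detected)
  expect_true(is.na(rep$magnitude_asymmetry))
  expect_true(is.na(rep$bistability_width))
  rep <- compare_to_symmetric(rep, rep)
  expect_true(is.na(rep$location_shift_down))
  expect_equal(rep$location_shift_up, 0)
})
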