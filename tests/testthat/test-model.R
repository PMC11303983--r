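test_that("Monod growth follows the saturating form and its contract", {
  # half-saturation and no-nutrient anchors
  expect_identical(monod_growth(0.1, 0.5, 0.5), 0.05)
  expect_identical(monod_growth(0.1, 0.5, 0), 0)
  # direct evaluation away from the anchors
  expect_equal(monod_growth(0.1, 0.5, 10), 0.1 * 10 / (0.5 + 10))
  # monotone nondecreasing in P, bounded by g_max
  P <- seq(0, 50, by = 0.5)
  g <- monod_growth(0.1, 0.5, P)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g < 0.1))
  expect_error(monod_growth(0.1, 0, 1), "k_P")
  expect_error(monod_growth(0.1, 0.5, -1), "P >= 0")
})

test_that("Haldane inhibition halves growth at the half-inhibition constant", {
  expect_identical(haldane_inhibition(100, 100), 0.5)
  expect_identical(haldane_inhibition(100, 0), 1)
  expect_equal(haldane_inhibition(100, 300), 0.25)
  X <- seq(0, 500, by = 5)
  h <- haldane_inhibition(100, X)
  expect_true(all(h > 0 & h <= 1))
  expect_true(all(diff(h) <= 0))
  expect_error(haldane_inhibition(0, 10), "H > 0")
})

test_that("diffusion-only conditions are a fixed point of the derivatives", {
  p <- update_parameters(symmetric_parameters(), c = 0)
  x <- system_state(0, 0, p$O_b, p$S_b, p$P_b)
  expect_equal(unname(model_derivatives(x, p, 0.3, 0.7)),
               rep(0, 5))
})

test_that("derivatives match a hand evaluation of the rate terms", {
  p <- symmetric_parameters()
  x <- system_state(1e5, 1e5, 20, 20, 10)
  d <- model_derivatives(x, p, 0.1, 0.1)
  g <- 0.1 * 10 / 10.5
  h <- 1 / 1.2
  expect_equal(unname(d["N_CB"]), g * h * 1e5 - 0.04 * 1e5)
  expect_equal(unname(d["N_SB"]), g * h * 1e5 - 0.04 * 1e5)
  expect_equal(unname(d["O"]), 3e-8 * g * h * 1e5 - 0.1 * 400 + 0.1 * 80)
  expect_equal(unname(d["S"]), 3e-8 * g * h * 1e5 - 0.1 * 400 + 0.1 * 80)
  expect_equal(unname(d["P"]), -2 * g * h * 1e5 / 1.67e8 + 0.1 * 0)
})

test_that("derivatives commute with the species/substrate mirror", {
  p <- symmetric_parameters()
  set.seed(42)
  for (k in 1:25) {
    x <- system_state(10^stats::runif(1, 0, 10), 10^stats::runif(1, 0, 10),
                      stats::runif(1, 0, 150), stats::runif(1, 0, 150),
                      stats::runif(1, 0, 10))
    a <- 10^stats::runif(2, -2, 0)
    lhs <- mirror_state(model_derivatives(x, p, a[1], a[2]))
    rhs <- model_derivatives(mirror_state(x), p, a[2], a[1])
    expect_equal(lhs, rhs, tolerance = 1e-14)
  }
})

test_that("the symmetric default parameterization is as documented", {
  p <- symmetric_parameters()
  expect_identical(p$H_S, p$H_O)
  expect_identical(p$H_S, 100)
  expect_identical(p$p_O, p$p_S)
  expect_identical(p$p_O, 3.00e-8)
  expect_true(is_system_symmetric(p))
  expect_false(is_system_symmetric(update_parameters(p, H_O = 60)))
})

test_that("parameter sets validate and copy-with-override leaves the original intact", {
  p <- symmetric_parameters()
  q <- update_parameters(p, H_O = 60, p_S = 4e-8)
  expect_identical(p$H_O, 100)   # immutability of the source
  expect_identical(q$H_O, 60)
  expect_identical(q$p_S, 4e-8)
  expect_error(update_parameters(p, nonsense = 1), "unknown parameter")
  expect_error(update_parameters(p, g_max = -1), "nonnegative")
  expect_error(update_parameters(p, m = 0), "strictly positive")
  expect_error(model_parameters(g_max = 0.1, k_P = 0.5, H_S = 100,
                                H_O = NA, y_P = 1, p_O = 1, p_S = 1,
                                m = 0.1, alpha_P = 1, O_b = 1, S_b = 1,
                                P_b = 1, c = 1),
               "finite")
})

test_that("parameter files round-trip losslessly", {
  p <- update_parameters(symmetric_parameters(), H_O = 61.237,
                         p_S = 2.9999999e-8)
  f <- withr::local_tempfile(fileext = ".txt")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_identical(unclass(q), unclass(p))
  # a missing key is reported by name
  lines <- readLines(f)
  writeLines(lines[!startsWith(lines, "H_O")], f)
  expect_error(read_parameters(f), "H_O")
})

test_that("system states are validated and the mirror is an involution", {
  expect_error(system_state(1, 1, -0.1, 0, 1), "nonnegative")
  expect_error(system_state(1, 1, Inf, 0, 1), "finite")
  x <- system_state(3, 7, 11, 13, 17)
  expect_identical(mirror_state(mirror_state(x)), x)
  expect_identical(unname(mirror_state(x)), c(7, 3, 13, 11, 17))
})
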