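f0 <- autoreg_cubic()

test_that("autoregulation function and drift evaluate correctly", {
  expect_equal(eval_autoregulation(2, f0), 0)   # odd about x = 2
  expect_equal(eval_autoregulation(3, f0), 1)   # -1 + 2
  expect_equal(eval_autoregulation(1, f0), -1)  # 1 - 2
  expect_equal(drift(1, 2, f0), 0)
  expect_equal(drift(3, 2, f0), 0)
  expect_equal(drift(2, 0, f0), -2)
  # vectorized: all three fixed points at lambda = 2 at once
  expect_equal(drift(c(1, 2, 3), 2, f0), c(0, 0, 0))
})

test_that("constructor rejects non-bistable-capable polynomials", {
  expect_error(autoreg_cubic(c(1, 2, 3, 1)), "negative")
  expect_error(autoreg_cubic(c(1, 2, 3)), "4 finite")
})

test_that("potential obeys its defining conventions", {
  expect_equal(potential(0, 2, f0), 0)
  expect_equal(potential(0, -3, f0), 0)
  # -dU/dx equals the drift (central difference)
  h <- 1e-6
  num <- -(potential(1.7 + h, 2, f0) - potential(1.7 - h, 2, f0)) / (2 * h)
  expect_equal(num, drift(1.7, 2, f0), tolerance = 1e-8)
  # at lambda = 2: minima at 1 and 3, maximum at 2
  for (x0 in c(1, 3)) {
    expect_lt(potential(x0, 2, f0), potential(x0 - 0.05, 2, f0))
    expect_lt(potential(x0, 2, f0), potential(x0 + 0.05, 2, f0))
  }
  expect_gt(potential(2, 2, f0), potential(1.95, 2, f0))
  expect_gt(potential(2, 2, f0), potential(2.05, 2, f0))
})

test_that("fixed points at reference production rates", {
  fp <- find_fixed_points(2, f0)
  expect_equal(fp$x, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fp$stability, c("stable", "unstable", "stable"))

  fp3 <- find_fixed_points(3, f0)
  expect_equal(nrow(fp3), 1L)
  expect_equal(fp3$stability, "stable")
  expect_equal(fp3$x, bisect_root(function(x) drift(x, 3, f0), 3, 4),
               tolerance = 1e-8)
  expect_equal(round(fp3$x, 1), 3.3)

  fp0 <- find_fixed_points(0, f0)
  expect_equal(nrow(fp0), 1L)
  expect_equal(fp0$x, bisect_root(function(x) drift(x, 0, f0), 0, 1),
               tolerance = 1e-8)
  expect_equal(round(fp0$x, 2), 0.48)
})

test_that("every reported fixed point has drift residual below 1e-9", {
  for (l in seq(0, 4, by = 0.13)) {
    fp <- find_fixed_points(l, f0)
    expect_true(all(abs(drift(fp$x, l, f0)) < 1e-9))
  }
})

test_that("saddle-node thresholds match the closed form", {
  th <- saddle_node_thresholds(f0)
  expect_equal(th$lambda_low, 2 - 2 / (3 * sqrt(3)), tolerance = 1e-14)
  expect_equal(th$lambda_high, 2 + 2 / (3 * sqrt(3)), tolerance = 1e-14)
  expect_lt(th$lambda_low, th$lambda_high)
  # monostable cubic: f = -x^3 has no pair of critical points in g
  expect_error(saddle_node_thresholds(autoreg_cubic(c(0, 0, 0, -1))),
               "no bistable window")
})

test_that("root count is 3 strictly inside the window and 1 outside", {
  th <- saddle_node_thresholds(f0)
  for (l in seq(0.1, 3.9, by = 0.07)) {
    k <- nrow(find_fixed_points(l, f0))
    if (l > th$lambda_low + 1e-6 && l < th$lambda_high - 1e-6) {
      expect_identical(k, 3L)
    } else if (l < th$lambda_low - 1e-6 || l > th$lambda_high + 1e-6) {
      expect_identical(k, 1L)
    }
  }
  expect_identical(nrow(find_fixed_points(th$lambda_low + 1e-6, f0)), 3L)
  expect_identical(nrow(find_fixed_points(th$lambda_low - 1e-6, f0)), 1L)
  expect_identical(nrow(find_fixed_points(th$lambda_high - 1e-6, f0)), 3L)
  expect_identical(nrow(find_fixed_points(th$lambda_high + 1e-6, f0)), 1L)
})

test_that("bifurcation diagram tabulates both branches", {
  bd <- bifurcation_diagram(0, 4, 0.1, f0)
  expect_named(bd, c("lambda", "x_star", "stability"))
  expect_true(all(abs(mapply(function(x, l) drift(x, l, f0),
                             bd$x_star, bd$lambda)) < 1e-9))
  k <- table(bd$lambda)
  expect_true(all(k %in% c(1L, 3L)))
})
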