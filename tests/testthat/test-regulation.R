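f0 <- autoreg_cubic()

test_that("mutation indicators and production rates", {
  expect_equal(has_jak2(c("O", "J", "T", "JT", "TJ")), c(0L, 1L, 0L, 1L, 1L))
  expect_equal(has_tet2(c("O", "J", "T", "JT", "TJ")), c(0L, 0L, 1L, 1L, 1L))
  expect_equal(production_rate(regulation_spec(0.5, 1, 1), "JT"), 2.5)
  expect_equal(production_rate(regulation_spec(3.5, -1, -1), "O"), 3.5)
  expect_equal(production_rate(regulation_spec(7, 2, -3), "O"), 7)
  s <- regulation_spec(2, 1, -1)
  expect_equal(production_rate(s, "JT"), production_rate(s, "TJ"))
})

test_that("branch following is hysteretic", {
  expect_equal(follow_branch(c(2, 3, 2), 1, f0), 3, tolerance = 1e-9)
  expect_equal(follow_branch(c(2, 1, 2), 1, f0), 1, tolerance = 1e-9)
  expect_equal(follow_branch(2, 1, f0), 1, tolerance = 1e-9)
})

test_that("branch following agrees with direct time integration", {
  set.seed(101)
  th <- saddle_node_thresholds(f0)
  for (i in 1:15) {
    path <- runif(4, 0, 4)
    # avoid starting or stepping too close to a threshold, where relaxation
    # times diverge and the fixed-step integrator would need a huge horizon
    path <- path[abs(path - th$lambda_low) > 0.05 &
                 abs(path - th$lambda_high) > 0.05]
    if (!length(path)) next
    x0 <- if (runif(1) < 0.5) 0 else 4
    expect_equal(follow_branch(path, x0, f0), rk4_follow(path, x0, f0),
                 tolerance = 1e-6)
  }
})

test_that("a path inside the bistable window never changes branch", {
  set.seed(7)
  th <- saddle_node_thresholds(f0)
  for (i in 1:10) {
    path <- runif(6, th$lambda_low + 1e-3, th$lambda_high - 1e-3)
    for (x0 in c(0, 4)) {
      x <- follow_branch(path[1], x0, f0)
      low_branch <- x < find_fixed_points(path[1], f0)$x[2]
      for (k in 2:length(path)) {
        x <- follow_branch(path[1:k], x0, f0)
        expect_identical(x < find_fixed_points(path[k], f0)$x[2], low_branch)
      }
    }
  }
})

test_that("exactly-at-threshold rates keep the marginal branch", {
  th <- saddle_node_thresholds(f0)
  # low branch survives (as the degenerate root) exactly at lambda_high
  x_at <- follow_branch(c(2, th$lambda_high), 1, f0)
  expect_equal(x_at, th$x_at_high, tolerance = 1e-6)
  # but jumps once strictly beyond
  expect_gt(follow_branch(c(2, th$lambda_high + 1e-6), 1, f0), 3)
})

test_that("mutation-history steady states reproduce the preset tables", {
  t4a <- mutation_trajectory_steady_states(scenario_preset("fig4a"), f0)
  expect_equal(unclass(t4a)[c("J", "JT", "T", "TJ")],
               c(J = 3.3247, JT = 3, T = 0.6753, TJ = 1), tolerance = 1e-4)
  t2a <- mutation_trajectory_steady_states(scenario_preset("fig2a"), f0)
  expect_equal(round(c(unclass(t2a)), 1),
               c(O = 0.6, J = 0.8, T = 0.8, JT = 3.2, TJ = 3.2))
  t2b <- mutation_trajectory_steady_states(scenario_preset("fig2b"), f0)
  expect_equal(round(c(unclass(t2b)), 1),
               c(O = 3.4, J = 3.2, T = 3.2, JT = 0.8, TJ = 0.8))
  expect_true(all(unclass(t2a) > 0) && all(unclass(t2b) > 0))
})

test_that("coupled model: Y bistable, X affine in Y", {
  ss <- coupled_steady_states(coupled_model_spec())
  expect_equal(round(c(unclass(ss$y)), 1),
               c(O = 0.8, J = 3.2, T = 0.6, JT = 0.8, TJ = 0.8))
  expect_equal(round(c(unclass(ss$x)), 1),
               c(O = 1.8, J = 3.2, T = 1.6, JT = 0.8, TJ = 0.8))
  # affine identity
  m <- coupled_model_spec(coupling = 2.5, direct = -0.3)
  ss2 <- coupled_steady_states(m)
  expect_equal(ss2$x[["J"]] - ss2$x[["TJ"]],
               2.5 * (ss2$y[["J"]] - ss2$y[["TJ"]]))
  # decoupled linear gene is flat
  ss0 <- coupled_steady_states(coupled_model_spec(coupling = 0, direct = 0,
                                                  basal = 1.7))
  expect_equal(unname(c(unclass(ss0$x))), rep(1.7, 5))
})

test_that("observation classifier labels the published patterns", {
  t2a <- mutation_trajectory_steady_states(scenario_preset("fig2a"), f0)
  cl <- classify_observation(t2a)
  expect_true(cl$non_additive)
  expect_false(cl$non_commutative)
  expect_identical(cl$observation, "2")

  x3 <- coupled_steady_states(scenario_preset("fig3"))$x
  expect_identical(classify_observation(x3)$observation, "3")

  t2c <- mutation_trajectory_steady_states(scenario_preset("fig2c"), f0)
  expect_identical(classify_observation(t2c)$observation, "1")

  t4a <- mutation_trajectory_steady_states(scenario_preset("fig4a"), f0)
  cl4 <- classify_observation(t4a)
  expect_true(cl4$non_commutative)
  expect_identical(cl4$observation, "4")

  additive <- c(O = 1, J = 1.5, T = 2, JT = 2.5, TJ = 2.5)
  cla <- classify_observation(additive)
  expect_false(cla$non_additive)
  expect_false(cla$non_commutative)
})

test_that("additivity within tol implies commutativity within 2*tol", {
  set.seed(11)
  tol <- 0.05
  for (i in 1:200) {
    spec <- regulation_spec(runif(1, 0, 4), runif(1, -2, 2), runif(1, -2, 2))
    tab <- unclass(mutation_trajectory_steady_states(spec, f0))
    addJ <- abs((tab["J"] - tab["O"]) - (tab["TJ"] - tab["T"]))
    addT <- abs((tab["T"] - tab["O"]) - (tab["JT"] - tab["J"]))
    if (addJ <= tol && addT <= tol)
      expect_lte(abs(tab["JT"] - tab["TJ"]), 2 * tol)
  }
})
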