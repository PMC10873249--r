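test_that("exact propagation matches the exhaustive-trajectory oracle (n <= 4)", {
  for (sc in c("A", "B", "C")) {
    for (n in c(3, 4)) {
      params <- make_scenario(sc, n = n)
      dist <- propagate_exact(params, survival_tol = 1e-13, min_steps = 0)
      st <- absorption_statistics(dist)
      orc <- oracle_propagate(params)
      for (cl in c("JAK2_first_pure", "TET2_first_pure")) {
        row <- st[st$class == cl, ]
        o <- orc$stats[[cl]]
        expect_equal(row$probability, o[["mass"]], tolerance = 1e-8)
        expect_equal(row$mean_count, o[["mean_count"]], tolerance = 1e-8)
        expect_equal(row$sd_count, o[["sd_count"]], tolerance = 1e-8)
        expect_equal(row$mean_T, o[["mean_T"]], tolerance = 1e-8)
        expect_equal(row$sd_T, o[["sd_T"]], tolerance = 1e-8)
      }
      expect_equal(unname(dist$class_mass[["ambiguous"]]), orc$ambiguous,
                   tolerance = 1e-8)
    }
  }
})

test_that("oracle agreement also holds for the independent-draw semantics", {
  params <- make_scenario("B", n = 4)
  dist <- propagate_exact(params, survival_tol = 1e-13, min_steps = 0,
                          birth_exclusive = FALSE)
  st <- absorption_statistics(dist)
  orc <- oracle_propagate(params, birth_exclusive = FALSE)
  expect_equal(st$mean_count[1], orc$stats$JAK2_first_pure[["mean_count"]],
               tolerance = 1e-8)
  expect_equal(st$mean_T[2], orc$stats$TET2_first_pure[["mean_T"]],
               tolerance = 1e-8)
})

test_that("mass is conserved at every step and survival is monotone", {
  dist <- propagate_exact(make_scenario("B", n = 15))
  absorbed <- cumsum(dist$time_dist$JAK2_first_pure +
                     dist$time_dist$TET2_first_pure +
                     dist$time_dist$ambiguous)
  expect_true(all(abs(absorbed + dist$survival - 1) < 1e-10))
  expect_true(all(diff(dist$survival) <= 1e-15))
  expect_equal(sum(dist$class_mass) + dist$residual_survival, 1,
               tolerance = 1e-10)
})

test_that("label-swap symmetric parameters give identical class statistics", {
  params <- moran_parameters(c(1, 2, 2, 3, 3),
                             mutation = c(0.15, 0.15, 0.2, 0.2), n = 15)
  st <- absorption_statistics(propagate_exact(params))
  expect_equal(st[1, -1], st[2, -1], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("stopping rule and guards behave as documented", {
  params <- make_scenario("B", n = 10)
  d1 <- propagate_exact(params, survival_tol = 1e-4, min_steps = 50)
  expect_gt(d1$steps, 50)
  expect_lt(d1$residual_survival, 1e-4)
  # min_steps dominates when survival collapses early
  expect_gte(propagate_exact(params, survival_tol = 0.5, min_steps = 30)$steps,
             30)
  expect_error(propagate_exact(params, survival_tol = 1e-12, max_steps = 5),
               "did not converge")
  # an initial state with double mutants is rejected
  expect_error(propagate_exact(params,
                               initial = population_state(9, n_JT = 1)),
               "double-mutant")
})

test_that("propagation accepts a custom single-mutant initial state", {
  params <- make_scenario("C", n = 10)
  d <- propagate_exact(params, initial = population_state(5, n_J = 5),
                       survival_tol = 1e-10, min_steps = 0)
  # JAK2 head start: pure JAK2-first is the dominant outcome
  expect_gt(d$class_mass[["JAK2_first_pure"]], d$class_mass[["TET2_first_pure"]])
})
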