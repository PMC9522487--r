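test_that("the vector field matches direct substitution and vanishes at E", {
  p <- stage_scenario("early")
  eq <- coexistence_equilibrium(p)
  expect_lt(max(abs(leslie_rhs(p, c(eq$x_star, eq$y_star)))), 1e-12)

  v <- leslie_rhs(p, c(i = 1, l = 1))
  expect_equal(unname(v), c(0.5 - 1.42e-6 - 0.1, 0.6 - 0.5), tolerance = 1e-12)

  expect_equal(unname(leslie_rhs(p, c(5, 0))[2]), 0)  # predator-free axis
  expect_equal(unname(leslie_rhs(p, c(0, 0))), c(0, 0))
  expect_error(leslie_rhs(p, c(0, 1)), "Gower")
  expect_error(leslie_rhs(p, c(-1, 1)), "non-negative")
})

test_that("fitness forms reduce correctly at reference states", {
  p <- leslie_params(r1 = 0.5, r2 = 0.6, c1 = 0, c2 = 0.5, b = 0.1,
                     k = 100, c = 1)
  expect_equal(unname(leslie_fitness(p, c(100, 0))[1]), 0)  # at capacity
  expect_equal(unname(leslie_fitness(p, c(37, 0))[2]), 0.6) # predator-free
  q <- leslie_params(r1 = 0.5, r2 = 0.6, c1 = 0, c2 = 0.5, b = 0.1, k = 100)
  expect_equal(unname(leslie_fitness(q, c(50, 1))[1]), 0.5 * 0.5 - 0.1)
  expect_error(leslie_fitness(p, c(0, 1)), "positive")
})

test_that("the difference map scales by one plus fitness and absorbs extinction", {
  p <- leslie_params(r1 = 0.5, r2 = 0.6, c1 = 0, c2 = 0.5, b = 0.1,
                     k = 100, c = 1)
  nxt <- leslie_map_step(p, c(i = 50, l = 1))
  expect_equal(unname(nxt[1]), 50 * 1.15)
  expect_equal(unname(leslie_map_step(p, c(0, 0))), c(0, 0))

  # vanishing fitnesses give a map fixed point
  H <- leslie_fitness(p, c(50, 1))
  state <- c(i = 50, l = 1)
  manual <- state * (1 + H)
  expect_equal(unname(leslie_map_step(p, state)), unname(manual))

  harsh <- leslie_params(r1 = 0.5, r2 = 0.6, c1 = 0, c2 = 0.5, b = 2,
                         k = 100, c = 1)
  expect_warning(res <- leslie_map_step(harsh, c(i = 1, l = 10)), "floored")
  expect_true(all(res >= 0))
})

test_that("coexistence equilibrium reproduces the three disease stages", {
  eq_e <- coexistence_equilibrium(stage_scenario("early"))
  expect_equal(truncate_decimals(eq_e$x_star), 4.99)
  expect_equal(truncate_decimals(eq_e$y_star), 5.99)

  eq_c <- coexistence_equilibrium(stage_scenario("chronic"))
  expect_equal(eq_c$x_star, 0.5)
  expect_equal(eq_c$y_star, 0.5)

  eq_a <- coexistence_equilibrium(stage_scenario("acute"))
  expect_equal(eq_a$x_star, 0.28 / 0.625)
  expect_equal(eq_a$y_star, 0.525 / 0.625)
})

test_that("Jacobian closed form matches entrywise substitution", {
  J <- leslie_jacobian(stage_scenario("early"))
  D <- 0.1 * 0.5 + 1.42e-6 * 0.6
  expect_equal(unname(J),
               matrix(c(-0.5 * 0.1 * 0.5 / D, -0.5 * 1.42e-6 * 0.5 / D,
                        0.6^2 / 0.5, -0.6), 2, byrow = TRUE))
  expect_equal(J[1, 2], -7.0999e-6, tolerance = 1e-4)

  Jc <- leslie_jacobian(stage_scenario("chronic"))
  expect_equal(Jc[1, 1], -0.3)
  expect_equal(Jc[2, 2], -0.6)
})

test_that("det(J at E) = r1*r2 identically over random parameter sets", {
  for (p in random_leslie_set(1000)) {
    expect_equal(numeric_det(leslie_jacobian(p)), p$r1 * p$r2,
                 tolerance = 1e-10)
  }
})

test_that("eigenvalues solve the characteristic polynomial", {
  for (p in random_leslie_set(200, seed = 911)) {
    co <- characteristic_coefficients(p)
    ev <- eigen(leslie_jacobian(p), only.values = TRUE)$values
    resid <- ev^2 + co[["linear"]] * ev + co[["constant"]]
    expect_lt(max(Mod(resid)), 1e-9)
  }
  co_e <- characteristic_coefficients(stage_scenario("early"))
  expect_equal(unname(co_e["linear"]), 1.09999, tolerance = 1e-5)
  expect_equal(unname(co_e["constant"]), 0.3)
  expect_equal(unname(characteristic_coefficients(
    stage_scenario("acute"))["constant"]), 0.525)
  expect_equal(unname(characteristic_coefficients(
    stage_scenario("chronic"))["constant"]), 0.36)
})

test_that("the node/focus criterion is exactly the discriminant sign test", {
  for (p in random_leslie_set(1000, seed = 515)) {
    crit <- node_focus_criterion(p)
    J <- leslie_jacobian(p)
    disc <- (J[1, 1] + J[2, 2])^2 - 4 * numeric_det(J)
    expect_identical(crit$label == "node", disc >= 0)
  }
})

test_that("stage criterion values and labels match the printed analysis", {
  crit_e <- node_focus_criterion(stage_scenario("early"))
  expect_equal(crit_e$lhs, 4.5548e-3, tolerance = 1e-3)
  expect_equal(crit_e$rhs, 8.519876e-6, tolerance = 1e-3)
  expect_equal(crit_e$label, "node")

  crit_a <- node_focus_criterion(stage_scenario("acute"))
  expect_equal(crit_a$lhs, 8.623253e-4, tolerance = 1e-3)
  expect_equal(crit_a$rhs, 0.588)
  expect_equal(crit_a$label, "focus")

  # equal growth rates with any conversion force a focus
  p_eq <- leslie_params(r1 = 0.5, r2 = 0.5, c1 = 0.3, c2 = 0.5, b = 0.1)
  expect_equal(node_focus_criterion(p_eq)$label, "focus")
})

test_that("the reported eigenvalue-sum quantity reproduces the stage summaries", {
  expect_equal(reported_trace_quantity(stage_scenario("acute")), 0.638)
  expect_equal(reported_trace_quantity(stage_scenario("chronic")), 0.3)
  expect_equal(reported_trace_quantity(stage_scenario("early")), 0.100008,
               tolerance = 1e-5)
})

test_that("the full Leslie report carries criterion and classification together", {
  rep <- leslie_stability_report(stage_scenario("early"))
  expect_s3_class(rep, "stability_report")
  expect_equal(rep$label, "stable node")
  expect_equal(rep$criterion_label, "node")
  expect_equal(rep$det, 0.3)
  expect_equal(truncate_decimals(unname(rep$point)), c(4.99, 5.99))

  rep_a <- leslie_stability_report(stage_scenario("acute"))
  expect_equal(rep_a$label, "stable focus")
  expect_equal(rep_a$reported_trace_quantity, 0.638)
})

test_that("parameter validation rejects degenerate rate constants", {
  expect_error(leslie_params(r1 = 0, r2 = 1, c1 = 0, c2 = 1, b = 1),
               "invalid")
  expect_error(leslie_params(r1 = 1, r2 = 1, c1 = -0.1, c2 = 1, b = 1),
               "invalid")
})
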