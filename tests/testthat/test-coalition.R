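test_that("coalition velocities match hand arithmetic and vanish at corners", {
  p <- coalition_payoffs(1, 1, 1, 1)
  expect_equal(unname(coalition_rhs(p, c(0.5, 0.5))), c(0, 0))

  q <- coalition_payoffs(2, 1, 1, 3)
  expect_equal(unname(coalition_rhs(q, c(0.5, 0.5))), c(0.125, -0.25))

  set.seed(5)
  for (rep in 1:20) {
    r <- coalition_payoffs(rnorm(1), rnorm(1), rnorm(1), rnorm(1))
    for (corner in list(c(0, 0), c(1, 1), c(1, 0), c(0, 1))) {
      expect_identical(unname(coalition_rhs(r, corner)), c(0, 0))
    }
  }
  expect_error(coalition_rhs(p, c(1.2, 0.5)), "unit square")
})

test_that("fixed points are the four corners plus the admissible mixed point", {
  fp <- coalition_fixed_points(coalition_payoffs(1, 1, 1, 1))
  expect_equal(nrow(fp), 5)
  expect_equal(fp[fp$kind == "interior", c("x1", "x2")],
               data.frame(x1 = 0.5, x2 = 0.5, row.names = 5L))

  fp2 <- coalition_fixed_points(coalition_payoffs(2, 1, 1, 3))
  int2 <- fp2[fp2$kind == "interior", ]
  expect_equal(int2$x1, 1 / 4)   # b1 / n
  expect_equal(int2$x2, 2 / 3)   # a1 / m

  # negative payoffs can still place the mixed point inside the square
  fp3 <- coalition_fixed_points(coalition_payoffs(-1, -1, 1, 1))
  expect_equal(nrow(fp3), 5)
  expect_equal(unlist(fp3[fp3$kind == "interior", c("x1", "x2")]),
               c(x1 = 0.5, x2 = 0.5))

  # a1/m = 2 falls outside (0,1): corners only
  fp4 <- coalition_fixed_points(coalition_payoffs(2, -1, 1, 3))
  expect_equal(nrow(fp4), 4)

  expect_warning(fp5 <- coalition_fixed_points(coalition_payoffs(1, -1, 1, 1)),
                 "degenerate")
  expect_equal(nrow(fp5), 4)
})

test_that("interior velocity vanishes and the grid scan finds no extra roots", {
  cases <- list(coalition_payoffs(1, 1, 1, 1),
                coalition_payoffs(2, 1, 1, 3),
                coalition_payoffs(-1, -1, 1, 1))
  for (p in cases) {
    fp <- coalition_fixed_points(p)
    int <- fp[fp$kind == "interior", ]
    expect_lt(max(abs(coalition_rhs(p, c(int$x1, int$x2)))), 1e-12)

    # brute-force scan of the unit square for simultaneous zeros
    g <- seq(0, 1, length.out = 200)
    grid <- expand.grid(x1 = g, x2 = g)
    v1 <- grid$x1 * (1 - grid$x1) * (p$a1 - p$m * grid$x2)
    v2 <- grid$x2 * (1 - grid$x2) * (p$b1 - p$n * grid$x1)
    roots <- grid[abs(v1) < 1e-9 & abs(v2) < 1e-9, ]
    d <- apply(roots, 1, function(pt) {
      min(sqrt((pt[1] - fp$x1)^2 + (pt[2] - fp$x2)^2))
    })
    expect_true(all(d <= 1.5 / 199))  # within one grid cell of a known root
  }
})

test_that("the interior Jacobian is antidiagonal with closed-form eigenvalues", {
  p <- coalition_payoffs(1, 1, 1, 1)
  J <- coalition_jacobian(p)
  expect_equal(J, matrix(c(0, -0.5, -0.5, 0), 2, byrow = TRUE))
  expect_equal(sort(eigen(J, only.values = TRUE)$values), c(-0.5, 0.5))

  set.seed(9)
  for (rep in 1:30) {
    q <- coalition_payoffs(runif(1, -2, 2), runif(1, -2, 2),
                           runif(1, -2, 2), runif(1, -2, 2))
    fp <- suppressWarnings(coalition_fixed_points(q))
    if (!any(fp$kind == "interior")) next
    Jq <- coalition_jacobian(q)
    expect_identical(c(Jq[1, 1], Jq[2, 2]), c(0, 0))
    ev <- eigenvalues_2x2(Jq)
    prod_off <- Jq[1, 2] * Jq[2, 1]
    if (prod_off > 0) {
      expect_equal(sort(Re(ev)), c(-1, 1) * sqrt(prod_off),
                   tolerance = 1e-9)
    } else {
      expect_equal(sort(Im(ev)), c(-1, 1) * sqrt(abs(prod_off)),
                   tolerance = 1e-9)
    }
    # cross-check against the dense numeric eigensolver
    expect_equal(sort(Re(ev)), sort(Re(eigen(Jq)$values)), tolerance = 1e-9)
  }
})

test_that("interior classification follows the sign structure of the payoffs", {
  expect_equal(classify_interior(coalition_payoffs(1, 1, 1, 1)), "saddle")
  expect_equal(classify_interior(coalition_payoffs(1, 1, -1, -3)), "center")
  expect_error(classify_interior(coalition_payoffs(2, -1, 1, 3)),
               "no interior")
})

test_that("transplant payoff fixtures are stored verbatim and are saddles", {
  M1 <- transplant_payoff_fixture("leu_vs_hsc_cleu")
  expect_equal(M1, matrix(c(0, 5e8, 9.2247e6, 0), 2, byrow = TRUE))
  M2 <- transplant_payoff_fixture("hsc_leu_vs_cleu")
  expect_equal(M2, matrix(c(0, 1009224700, 0.431001, 0), 2, byrow = TRUE))
  expect_error(transplant_payoff_fixture("bogus"))

  r1 <- saddle_report(M1)
  expect_equal(r1$det, -4.61235e15)
  expect_equal(r1$label, "saddle")
  expect_equal(r1$trace, 0)

  r2 <- saddle_report(M2)
  expect_equal(r2$det, -434976854.9, tolerance = 1e-9)
  expect_equal(r2$label, "saddle")
  expect_gt(r2$discriminant, 0)

  r3 <- saddle_report(matrix(c(0, 1, 1, 0), 2))
  expect_equal(r3$det, -1)
  expect_equal(sort(Re(r3$eigenvalues)), c(-1, 1))
})

test_that("edges of the unit square are invariant under the flow", {
  p <- coalition_payoffs(2, 1, 1, 3)
  cfg <- integrator_config(dt = 0.5, t_end = 20)
  for (x1_0 in c(0, 1)) {
    tr <- integrate_model(coalition_field(p), c(x1 = x1_0, x2 = 0.3), cfg)
    expect_lt(max(abs(tr$x1 - x1_0)), 1e-12)
  }
})
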