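test_that("pro-inflammatory subsystem solve matches the hand linear solve", {
  p <- cytokine_params()
  sub <- solve_pro_subsystem(p, 0.005 / 0.35)
  expect_equal(sub$D, 1.9832584, tolerance = 1e-7)
  expect_equal(sub$C_T, 0.0143790, tolerance = 1e-5)
  expect_equal(sub$C_6, 0.0131170, tolerance = 1e-5)
  expect_true(sub$physical)

  # decoupled limit: no IL-6 production at all
  p2 <- update_params(p, alpha_6 = 0, k_6T = 0)
  sub2 <- solve_pro_subsystem(p2, 0.2)
  expect_equal(sub2$C_6, 0)
  expect_equal(sub2$C_T, p2$alpha_T / (p2$beta_T + p2$gamma_T10 * 0.2))

  # singular subsystem: cross-activation product equals decay product
  p3 <- update_params(p, k_T6 = 1.8, k_6T = 1.2, gamma_T10 = 0,
                      gamma_610 = 0)
  expect_error(solve_pro_subsystem(p3, 0), "singular")
})

test_that("steady-state CT and C6 decrease with IL-10 under defaults", {
  sub <- solve_pro_subsystem(cytokine_params(), seq(0, 1, length.out = 101))
  expect_true(all(diff(sub$C_T) < 0))
  expect_true(all(diff(sub$C_6) < 0))
})

test_that("default parameters admit exactly one, stable, equilibrium", {
  eq <- enumerate_equilibria(cytokine_params(), regime = "post_delay")
  expect_equal(nrow(eq), 1)
  expect_equal(eq$C_T, 0.014379, tolerance = 1e-4)
  expect_equal(eq$C_6, 0.013117, tolerance = 1e-4)
  expect_equal(eq$C_10, 0.014286, tolerance = 1e-4)
  expect_equal(eq$stability, "stable")
  expect_true(all(Re(c(eq$lambda1, eq$lambda2, eq$lambda3)) < 0))
  expect_lte(eq$residual_norm, 1e-10)

  # with the gate off the IL-10 root is exactly alpha_10 / beta_10
  pre <- enumerate_equilibria(cytokine_params(), regime = "pre_delay")
  expect_equal(nrow(pre), 1)
  expect_equal(pre$C_10, 0.005 / 0.35, tolerance = 1e-9)
  expect_equal(eq$C_10, pre$C_10, tolerance = 1e-6)

  # fully dead network: origin only
  p0 <- cytokine_params(alpha_T = 0, alpha_6 = 0, alpha_10 = 0, k_T6 = 0,
                        k_6T = 0, k_10T = 0, k_106 = 0, gamma_T10 = 0,
                        gamma_610 = 0)
  eq0 <- enumerate_equilibria(p0)
  expect_equal(nrow(eq0), 1)
  expect_equal(c(eq0$C_T, eq0$C_6, eq0$C_10), c(0, 0, 0), tolerance = 1e-11)
})

test_that("scan-and-bisect agrees with a dense brute-force oracle", {
  draws <- c(list(cytokine_params()), draw_params(10, seed = 21))
  for (p in draws) {
    eq <- enumerate_equilibria(p, regime = "post_delay")
    oracle <- brute_force_roots(p, "post_delay", n = 1e5,
                                C10_max = attr(eq, "C10_max"))
    expect_equal(nrow(eq), length(oracle))
    if (length(oracle) > 0) {
      expect_lt(max(abs(sort(eq$C_10) - oracle)), 1e-8)
      expect_true(all(eq$residual_norm <= 1e-10))
    }
  }
})

test_that("paper-mode Jacobian reproduces the published stability analysis", {
  p <- cytokine_params()
  st <- c(C_T = 0.623, C_6 = 0.512, C_10 = 1.837)
  J <- cytokine_jacobian(p, st, mode = "paper")
  expect_equal(J$matrix,
               matrix(c(-1.98370, 0.45, -0.06230,
                        0.40, -1.31022, -0.03072,
                        0.08317, -0.08317, -0.35), 3, 3, byrow = TRUE),
               tolerance = 5e-4)
  lam <- Re(J$eigenvalues)
  expect_equal(lam, c(-2.1886, -1.1052, -0.3502), tolerance = 5e-3)
  expect_equal(sum(diag(J$matrix)), -3.64392, tolerance = 1e-9)
  expect_equal(sum(J$eigenvalues), sum(diag(J$matrix)) + 0i, tolerance = 1e-9)
})

test_that("exact-mode Jacobian keeps the product-rule terms", {
  p <- cytokine_params()
  st <- c(C_T = 0.623, C_6 = 0.512, C_10 = 1.837)
  J <- cytokine_jacobian(p, st, mode = "exact")
  expect_equal(J$matrix[3, 1], 0.04875, tolerance = 1e-4)
  expect_equal(J$matrix[3, 2], -0.04689, tolerance = 1e-4)
  Jp <- cytokine_jacobian(p, st, mode = "paper")
  expect_equal(Re(J$eigenvalues), Re(Jp$eigenvalues), tolerance = 5e-3)
  # paper mode is undefined without pro-inflammatory dominance
  expect_error(cytokine_jacobian(p, c(C_T = 0.1, C_6 = 0.5, C_10 = 0.1),
                                 mode = "paper"), "C_T > C_6")
})

test_that("decoupling renders the Jacobian block-triangular", {
  p <- update_params(cytokine_params(), gamma_T10 = 0, gamma_610 = 0,
                     k_10T = 0, k_106 = 0)
  J <- cytokine_jacobian(p, c(C_T = 0.5, C_6 = 0.2, C_10 = 0.1))
  A <- matrix(c(-1.8, 0.45, 0.4, -1.2), 2, 2, byrow = TRUE)
  expected <- sort(c(eigen(A, only.values = TRUE)$values, -0.35))
  expect_equal(Re(J$eigenvalues), expected, tolerance = 1e-12)
})

test_that("eigenvalue sum equals the trace across random states and modes", {
  draws <- draw_params(40, seed = 31)
  states <- draw_states(40, seed = 32)
  for (i in seq_along(draws)) {
    s <- states[[i]][c("C_T", "C_6", "C_10")]
    for (mode in c("exact", "paper")) {
      if (mode == "paper" && s[["C_T"]] <= s[["C_6"]]) next
      J <- cytokine_jacobian(draws[[i]], s, mode = mode)
      expect_lt(abs(sum(J$eigenvalues) - sum(diag(J$matrix))), 1e-9)
      # analytic trace identity shared by both modes
      p <- draws[[i]]
      tr_analytic <- -(p$beta_T + p$gamma_T10 * s[["C_10"]]) -
        (p$beta_6 + p$gamma_610 * s[["C_10"]]) - p$beta_10
      expect_lt(abs(sum(diag(J$matrix)) - tr_analytic), 1e-12)
    }
  }
})

test_that("stability classification thresholds on eigenvalue real parts", {
  expect_equal(classify_stability(c(-2.19, -1.11, -0.35)), "stable")
  expect_equal(classify_stability(c(-1, 0, -1)), "marginal")
  expect_equal(classify_stability(c(0.2, -1, -1)), "unstable")
  expect_equal(classify_stability(complex(real = c(-1, -1), imaginary = c(2, -2))),
               "stable")
})

test_that("closed-form linear solution handles the analytic special cases", {
  # diagonal, homogeneous: plain exponentials
  sub <- linear_subsystem(A = diag(c(-1.8, -1.2)), alpha_vec = c(0, 0),
                         C0 = c(1, 1))
  got <- solve_linear_subsystem(sub, c(0, 0.5, 2))
  expect_equal(got$C_T, exp(-1.8 * c(0, 0.5, 2)), tolerance = 1e-12)
  expect_equal(got$C_6, exp(-1.2 * c(0, 0.5, 2)), tolerance = 1e-12)

  # t = 0 returns the initial condition exactly
  sub2 <- linear_subsystem(cytokine_params(), C0 = c(0.1, 0.05))
  expect_equal(unlist(solve_linear_subsystem(sub2, 0)[1, c("C_T", "C_6")]),
               c(C_T = 0.1, C_6 = 0.05))

  # singular A is refused
  sub3 <- linear_subsystem(A = matrix(c(-1, 1, 1, -1), 2), alpha_vec = c(0, 0),
                          C0 = c(1, 1))
  expect_error(solve_linear_subsystem(sub3, 1), "singular")
})

test_that("closed form and RK4 agree on the decoupled pre-delay system", {
  p <- update_params(cytokine_params(), gamma_T10 = 0, gamma_610 = 0)
  tr <- simulate_cytokines(p, t_end = 10, dt = 1e-3)
  cf <- solve_linear_subsystem(linear_subsystem(p, C0 = c(0.1, 0.05)),
                               c(2, 5, 10))
  for (k in seq_len(nrow(cf))) {
    i <- which(abs(tr$time - cf$t[k]) < 1e-9)
    expect_lt(abs(tr$C_T[i] - cf$C_T[k]), 1e-8)
    expect_lt(abs(tr$C_6[i] - cf$C_6[k]), 1e-8)
  }
})
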