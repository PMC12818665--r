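test_that("parameter validation accepts defaults and names the violated field", {
  expect_s3_class(cytokine_params(), "cytokine_params")
  expect_error(cytokine_params(beta_T = 0), "beta_T must be > 0")
  expect_error(cytokine_params(hill_K = -0.3), "hill_K")
  expect_error(cytokine_params(hill_n = 0.5), "hill_n")
  expect_error(cytokine_params(t_delay = -1), "t_delay")
  expect_error(update_params(cytokine_params(), gamma_t10 = 0.1), "unknown")
})

test_that("default parameters carry the calibrated post-stroke values", {
  p <- cytokine_params()
  expect_equal(unclass(p)[param_names()],
               list(alpha_T = 0.02, alpha_6 = 0.01, alpha_10 = 0.005,
                    k_T6 = 0.45, k_6T = 0.40, k_10T = 0.15, k_106 = 0.12,
                    gamma_T10 = 0.10, gamma_610 = 0.06,
                    beta_T = 1.8, beta_6 = 1.2, beta_10 = 0.35,
                    hill_n = 5, hill_K = 0.3, t_delay = 18))
})

test_that("heaviside is the right-continuous unit step", {
  expect_equal(heaviside(c(-1, 0, 6)), c(0, 1, 1))
  expect_error(heaviside(NaN))
})

test_that("hill gate hits half-max at d = K, clamps at C_T <= C_6, matches arithmetic", {
  expect_equal(hill_activation(0.4, 0.1, K = 0.3, n = 5), 0.5)
  expect_equal(hill_activation(0.2, 0.2, K = 0.3, n = 5), 0)
  expect_equal(hill_activation(0.1, 0.5, K = 0.3, n = 5), 0)
  # frozen from direct arithmetic: 0.111^5 / (0.3^5 + 0.111^5)
  expect_equal(hill_activation(0.623, 0.512, K = 0.3, n = 5),
               0.111^5 / (0.3^5 + 0.111^5))
  expect_equal(hill_activation(0.623, 0.512, K = 0.3, n = 5), 6.887e-3,
               tolerance = 1e-4)
})

test_that("hill gate is monotone in each argument and bounded in [0, 1)", {
  withr::with_seed(42, {
    for (i in 1:200) {
      K <- runif(1, 0.1, 0.5); n <- runif(1, 1, 8)
      ct <- sort(runif(2, 0, 3)); c6 <- sort(runif(2, 0, 3))
      expect_gte(hill_activation(ct[2], c6[1], K, n),
                 hill_activation(ct[1], c6[1], K, n))
      expect_lte(hill_activation(ct[1], c6[2], K, n),
                 hill_activation(ct[1], c6[1], K, n))
      h <- hill_activation(ct[2], c6[1], K, n)
      expect_true(h >= 0 && h < 1)
    }
  })
})

test_that("rhs reproduces hand-evaluated derivatives", {
  p <- cytokine_params()
  # pre-delay: induction inactive
  expect_equal(cytokine_rhs(cytokine_state(0, 0.1, 0.05, 0.01), p),
               c(dC_T = -0.13760, dC_6 = -0.01003, dC_10 = 0.00150),
               tolerance = 1e-12)
  # pure decay
  p0 <- cytokine_params(alpha_T = 0, alpha_6 = 0, alpha_10 = 0, k_T6 = 0,
                        k_6T = 0, k_10T = 0, k_106 = 0, gamma_T10 = 0,
                        gamma_610 = 0)
  expect_equal(cytokine_rhs(c(t = 0, C_T = 1, C_6 = 1, C_10 = 1), p0),
               c(dC_T = -1.8, dC_6 = -1.2, dC_10 = -0.35))
  # post-delay with the gate active
  d10 <- cytokine_rhs(c(t = 20, C_T = 0.623, C_6 = 0.512, C_10 = 1.837), p)
  hill <- 0.111^5 / (0.3^5 + 0.111^5)
  expect_equal(unname(d10["dC_10"]),
               0.005 + (0.15 * 0.623 + 0.12 * 0.512) * hill - 0.35 * 1.837)
  expect_equal(unname(d10["dC_10"]), -0.63688, tolerance = 1e-4)
})

test_that("time enters the rhs only through the delay gate", {
  p <- cytokine_params()
  s <- function(t) c(t = t, C_T = 0.7, C_6 = 0.3, C_10 = 0.2)
  expect_identical(cytokine_rhs(s(1), p), cytokine_rhs(s(5), p))
  expect_identical(cytokine_rhs(s(19), p), cytokine_rhs(s(50), p))
  expect_false(isTRUE(all.equal(cytokine_rhs(s(5), p), cytokine_rhs(s(19), p))))
})

test_that("derivatives point inward on the boundary of the positive octant", {
  draws <- draw_params(50, seed = 11)
  states <- draw_states(1000, seed = 12, t = 30)
  for (i in seq_along(states)) {
    p <- draws[[((i - 1) %% length(draws)) + 1]]
    s <- states[[i]]
    j <- (i %% 3) + 1                 # zero out one coordinate in turn
    s[c("C_T", "C_6", "C_10")[j]] <- 0
    dv <- cytokine_rhs(s, p)
    expect_gte(dv[[j]], 0)
  }
})

test_that("nondimensional ratios match the defining arithmetic", {
  nd <- nondimensionalize(cytokine_params())
  expect_equal(unlist(nd),
               c(ratio_activation_T = 0.25, ratio_activation_6 = 1 / 3,
                 ratio_suppression = 0.6, ratio_delay = 0.35 / 1.8))
  # unit point: state (K, K, K / gamma_T10) at t = 0 maps to (1, 1, 1, 0)
  p <- cytokine_params()
  nd2 <- nondimensionalize(p, c(t = 0, C_T = p$hill_K, C_6 = p$hill_K,
                                C_10 = p$hill_K / p$gamma_T10))
  expect_equal(c(nd2$C_tilde_T, nd2$C_tilde_6, nd2$C_tilde_10, nd2$tau),
               c(1, 1, 1, 0))
  nd3 <- nondimensionalize(p, c(t = 1 / p$beta_T, C_T = 0, C_6 = 0, C_10 = 0))
  expect_equal(nd3$tau, 1)
  expect_true(is.na(nondimensionalize(update_params(p, gamma_T10 = 0))$ratio_suppression))
})

test_that("parameter sets round-trip through YAML and JSON with typo guarding", {
  p <- update_params(cytokine_params(), gamma_T10 = 0.0731, hill_n = 4.25)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_params(p, f)
    expect_equal(unclass(read_params(f)), unclass(p))
  }
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(gamma_t10 = 0.1), f)
  expect_error(read_params(f), "unknown parameter field")
})
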