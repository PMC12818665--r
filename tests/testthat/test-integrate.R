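test_that("time grid honors breakpoints and the step bound", {
  g <- build_time_grid(72, 0.01, c(18, 24))
  expect_true(all(c(0, 18, 24, 72) %in% g))
  expect_true(all(diff(g) <= 0.01 + 1e-12))
  expect_true(!is.unsorted(g, strictly = TRUE))

  g2 <- build_time_grid(1, 0.3)
  expect_equal(g2, seq(0, 1, by = 0.25))

  expect_error(build_time_grid(72, 0.01, 80), "within")
  expect_error(build_time_grid(72, 0.01, -1), "within")
})

test_that("integrator's inlined derivative agrees with the model rhs", {
  # one RK4 step recomputed in-test from cytokine_rhs is the oracle
  draws <- draw_params(10, seed = 3)
  states <- draw_states(10, seed = 4, t = 30)
  h <- 0.05
  for (i in seq_along(draws)) {
    p <- draws[[i]]; y0 <- states[[i]][c("C_T", "C_6", "C_10")]
    f <- function(y) unname(cytokine_rhs(c(t = 30, y), p))
    k1 <- f(y0); k2 <- f(y0 + h / 2 * k1); k3 <- f(y0 + h / 2 * k2)
    k4 <- f(y0 + h * k3)
    expected <- y0 + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    p30 <- update_params(p, t_delay = 0)   # gate on, as at t = 30
    tr <- simulate_cytokines(p30, init = y0, t_end = h, dt = h)
    expect_equal(unlist(tr[2, c("C_T", "C_6", "C_10")]), expected,
                 tolerance = 1e-14)
  }
})

test_that("uncoupled exponential decay is integrated to near machine accuracy", {
  fx <- generate_fixture("pure_decay")
  tr <- simulate_cytokines(fx$params, init = c(C_T = 1, C_6 = 1, C_10 = 1),
                           t_end = 1, dt = 0.001)
  final <- unlist(tr[nrow(tr), c("C_T", "C_6", "C_10")])
  expect_equal(unname(final), exp(-c(1.8, 1.2, 0.35)), tolerance = 1e-9)
  expect_true(max(abs(final - exp(-c(1.8, 1.2, 0.35)))) < 1e-9)
})

test_that("halving the step shrinks the error like a fourth-order method", {
  ref <- simulate_cytokines(cytokine_params(), t_end = 10, dt = 1e-4)
  err <- vapply(c(0.02, 0.01), function(h) {
    s <- simulate_cytokines(cytokine_params(), t_end = 10, dt = h)
    idx <- match(round(s$time, 9), round(ref$time, 9))
    max(abs(as.matrix(s[, c("C_T", "C_6", "C_10")]) -
              as.matrix(ref[idx, c("C_T", "C_6", "C_10")])))
  }, numeric(1))
  expect_gte(err[1] / err[2], 12)
  expect_lte(err[1] / err[2], 20)
})

test_that("redundant breakpoints leave the trajectory unchanged", {
  base <- simulate_cytokines(cytokine_params(), t_end = 20, dt = 0.01)
  with_bp <- simulate_cytokines(
    cytokine_params(), t_end = 20, dt = 0.01,
    schedule = intervention_schedule(boluses = bolus_event(10, "C_T", 0)))
  idx <- match(round(base$time, 9), round(with_bp$time, 9))
  expect_true(all(!is.na(idx)))
  expect_lt(max(abs(as.matrix(base[, 2:4]) - as.matrix(with_bp[idx, 2:4]))),
            1e-10)
})

test_that("a zero-amount bolus is exactly a no-op", {
  sch <- intervention_schedule(boluses = bolus_event(5, "C_10", 0))
  a <- simulate_cytokines(cytokine_params(), t_end = 10, dt = 0.02)
  b <- simulate_cytokines(cytokine_params(), t_end = 10, dt = 0.02,
                          schedule = sch)
  idx <- match(round(a$time, 9), round(b$time, 9))
  expect_equal(as.matrix(a[, 2:4]), as.matrix(b[idx, 2:4]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("bolus is recorded pre-jump at its node and applied after", {
  tr <- run_scenario("il10_bolus", t_end = 30, dt = 0.01)
  i24 <- which(abs(tr$time - 24) < 1e-9)
  expect_length(i24, 1)
  base <- run_scenario("baseline", t_end = 30, dt = 0.01)
  b24 <- which(abs(base$time - 24) < 1e-9)
  # identical up to and including the bolus node
  expect_equal(tr$C_10[i24], base$C_10[b24], tolerance = 1e-12)
  # the next node reflects the +0.05 jump (minus a little decay)
  expect_gt(tr$C_10[i24 + 1], tr$C_10[i24] + 0.045)
})

test_that("scenario presets implement their advertised interventions", {
  p <- cytokine_params()
  ko <- run_scenario("il10_knockout", t_end = 10, dt = 0.01)
  expect_equal(ko$C_10, 0.01 * exp(-0.35 * ko$time), tolerance = 1e-10)

  inh <- run_scenario("tnf_inhibition", t_end = 1, dt = 0.001)
  manual <- simulate_cytokines(update_params(p, alpha_T = 0.01),
                               t_end = 1, dt = 0.001)
  expect_equal(as.matrix(inh[, 2:4]), as.matrix(manual[, 2:4]),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(run_scenario("unknown_thing"), "arg")
})

test_that("trajectory summaries find peaks and resolution times", {
  tr <- simulate_cytokines(cytokine_params(), t_end = 24, dt = 0.02)
  s <- summarize_trajectory(tr)
  expect_equal(s$species, c("C_T", "C_6", "C_10"))
  expect_equal(s$peak_time[s$species == "C_T"], 0)  # monotone decay from t=0

  # constant trajectory: resolution at once
  fx <- generate_fixture("pure_decay")
  flat <- simulate_cytokines(fx$params, init = c(C_T = 0, C_6 = 0, C_10 = 0),
                             t_end = 5, dt = 0.1)
  expect_equal(attr(summarize_trajectory(flat), "resolution_time"), 0)

  # pure decay: resolution time matches the analytic band crossing
  dec <- simulate_cytokines(fx$params, init = c(C_T = 1, C_6 = 1, C_10 = 1),
                            t_end = 72, dt = 0.01)
  s2 <- summarize_trajectory(dec, resolution_fraction = 0.05)
  t_analytic <- -log(1.05 * exp(-1.8 * 72)) / 1.8
  got <- attr(s2, "resolution_time")
  expect_lt(abs(got - t_analytic), 0.011)  # earliest grid node past crossing
})
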