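#' Analytic test fixtures
#'
#' Generators for small problems with known answers, used by the test suite
#' and available to users for validating the numerical machinery:
#' \describe{
#'   \item{`pure_decay`}{parameter set with every production and coupling
#'     zeroed, so each species decays exponentially; returns the closed-form
#'     solution as a callable.}
#'   \item{`linear_2d`}{a randomized stable 2x2 linear system (eigenvalue
#'     real parts < 0) with its matrix-exponential solution.}
#'   \item{`cubic_fold`}{the scalar root family `g(x; q) = q + x - x^3`,
#'     whose real-root count drops from 3 to 1 across folds at
#'     `q = +/- 2/(3 sqrt(3))`; returns a numerical root-count function
#'     (independent of the analytic fold location) for exercising fold
#'     detection.}
#'   \item{`ishigami`}{the three-input Ishigami function
#'     `sin(x1) + a sin(x2)^2 + b x3^4 sin(x1)` on `[-pi, pi]^3` with its
#'     analytic Sobol indices, the standard benchmark for variance-based
#'     sensitivity estimators.}
#' }
#'
#' @param kind One of `"pure_decay"`, `"linear_2d"`, `"cubic_fold"`,
#'   `"ishigami"`.
#' @param seed Integer seed for the randomized fixtures.
#' @param a,b Ishigami coefficients.
#' @return A list whose contents depend on `kind`; see Details and the
#'   examples in the test suite.
#' @examples
#' fx <- generate_fixture("pure_decay")
#' fx$solution(c(1, 1, 1), t = 2)
#' @export
generate_fixture <- function(kind = c("pure_decay", "linear_2d", "cubic_fold",
                                      "ishigami"),
                             seed = 1, a = 7, b = 0.1) {
  kind <- match.arg(kind)
  switch(kind,
    pure_decay = {
      p <- cytokine_params(alpha_T = 0, alpha_6 = 0, alpha_10 = 0,
                           k_T6 = 0, k_6T = 0, k_10T = 0, k_106 = 0,
                           gamma_T10 = 0, gamma_610 = 0)
      betas <- c(p$beta_T, p$beta_6, p$beta_10)
      list(kind = kind, params = p,
           solution = function(state0, t) {
             vapply(t, function(ti) state0 * exp(-betas * ti), numeric(3))
           })
    },
    linear_2d = {
      A <- withr::with_seed(as.integer(seed), {
        repeat {
          M <- matrix(rnorm(4), 2, 2)
          diag(M) <- -abs(diag(M)) - 0.5  # push toward stability
          if (all(Re(eigen(M, only.values = TRUE)$values) < -1e-6)) break
        }
        M
      })
      alpha_vec <- withr::with_seed(as.integer(seed) + 1L, abs(rnorm(2)) / 10)
      C0 <- withr::with_seed(as.integer(seed) + 2L, abs(rnorm(2)))
      sub <- linear_subsystem(A = A, alpha_vec = alpha_vec, C0 = C0)
      list(kind = kind, subsystem = sub,
           solution = function(t) solve_linear_subsystem(sub, t))
    },
    cubic_fold = {
      count_fn <- function(q) {
        x <- seq(-3, 3, length.out = 6001)
        g <- q + x - x^3
        sum(g[-length(g)] * g[-1] < 0) + sum(g == 0)
      }
      list(kind = kind, count_fn = count_fn,
           grid = seq(-1, 1, length.out = 41),
           folds_analytic = c(-2 / (3 * sqrt(3)), 2 / (3 * sqrt(3))))
    },
    ishigami = {
      fn <- function(m) {
        sin(m[, 1]) + a * sin(m[, 2])^2 + b * m[, 3]^4 * sin(m[, 1])
      }
      V1 <- 0.5 * (1 + b * pi^4 / 5)^2
      V2 <- a^2 / 8
      V13 <- b^2 * pi^8 * 8 / 225
      V <- V1 + V2 + V13
      list(kind = kind, fn = fn,
           ranges = tibble::tibble(name = c("x1", "x2", "x3"),
                                   low = -pi, high = pi),
           analytic = list(
             S1 = c(V1 / V, V2 / V, 0),
             ST = c((V1 + V13) / V, V2 / V, V13 / V),
             variance = V))
    })
}

#' Fold detection over a root-count function
#'
#' Scans a parameter grid with a user-supplied root/equilibrium count
#' function and refines every interval where the count changes by bisection
#' on the parameter, to width at most `tol`.  This is the engine behind
#' [sweep_equilibria()]'s fold locations, exposed for use with arbitrary
#' scalar families (see the `cubic_fold` fixture).
#'
#' @param count_fn Function mapping a parameter value to a root count.
#' @param grid Ascending parameter values to scan.
#' @param tol Maximal width of each refined fold interval.
#' @return A tibble with columns `lower`, `upper`, `count_lower`,
#'   `count_upper`, one row per count change.
#' @examples
#' fx <- generate_fixture("cubic_fold")
#' find_fold_intervals(fx$count_fn, fx$grid)
#' @export
find_fold_intervals <- function(count_fn, grid, tol = 1e-4) {
  detect_folds(count_fn, grid, tol)
}
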