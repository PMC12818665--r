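#' Pro-inflammatory subsystem at fixed IL-10
#'
#' For a fixed IL-10 level the TNF-alpha / IL-6 steady-state conditions are
#' linear, with unique solution
#' \deqn{C_T = \frac{\alpha_T(\beta_6 + \gamma_{610} C_{10}) + k_{T6}\alpha_6}{D},
#'       \qquad
#'       C_6 = \frac{\alpha_6(\beta_T + \gamma_{T10} C_{10}) + k_{6T}\alpha_T}{D}}
#' where \eqn{D(C_{10}) = (\beta_T + \gamma_{T10} C_{10})
#' (\beta_6 + \gamma_{610} C_{10}) - k_{T6} k_{6T}}.  A negative component
#' (possible when `D < 0`) is flagged, not an error.
#'
#' @param params A [cytokine_params()] object.
#' @param C_10 IL-10 level(s) (nM); vectorized.
#' @return A tibble with columns `C_10`, `C_T`, `C_6`, `D`, `physical`
#'   (both components nonnegative).
#' @examples
#' solve_pro_subsystem(cytokine_params(), 0.005 / 0.35)
#' @export
solve_pro_subsystem <- function(params, C_10) {
  p <- unclass(validate_params(params))
  a <- p$beta_T + p$gamma_T10 * C_10
  b <- p$beta_6 + p$gamma_610 * C_10
  D <- a * b - p$k_T6 * p$k_6T
  if (any(abs(D) < 1e-12)) {
    abort("pro-inflammatory subsystem is singular (|D| < 1e-12)")
  }
  CT <- (p$alpha_T * b + p$k_T6 * p$alpha_6) / D
  C6 <- (p$alpha_6 * a + p$k_6T * p$alpha_T) / D
  tibble::tibble(C_10 = C_10, C_T = CT, C_6 = C6, D = D,
                 physical = CT >= 0 & C6 >= 0)
}

# Scalar steady-state residual in C_10: substituting the subsystem solution
# into the IL-10 balance. Vectorized; NA where the subsystem is singular.
equilibrium_residual <- function(params, C_10, regime = "post_delay") {
  p <- unclass(params)
  a <- p$beta_T + p$gamma_T10 * C_10
  b <- p$beta_6 + p$gamma_610 * C_10
  D <- a * b - p$k_T6 * p$k_6T
  CT <- (p$alpha_T * b + p$k_T6 * p$alpha_6) / D
  C6 <- (p$alpha_6 * a + p$k_6T * p$alpha_T) / D
  drive <- if (regime == "post_delay") {
    (p$k_10T * CT + p$k_106 * C6) * hill_activation(CT, C6, p$hill_K, p$hill_n)
  } else 0
  res <- p$alpha_10 + drive - p$beta_10 * C_10
  res[abs(D) < 1e-12] <- NA_real_
  res
}

#' Enumerate steady states of the cytokine network
#'
#' Exploits the model structure: the TNF-alpha / IL-6 equations are linear
#' for fixed IL-10, so every equilibrium is a root of one scalar residual in
#' `C_10`.  Roots are located by a sign-change scan on a uniform grid over
#' `[0, C10_max]` and refined by bisection to an interval width of 1e-12,
#' then expanded to full states, equipped with the exact-mode Jacobian
#' eigenvalues and classified for stability.  This scan-and-bisect engine is
#' exhaustive on the scan resolution (tangent roots that do not change sign
#' are not detectable; see the methods vignette).
#'
#' @param params A [cytokine_params()] object.
#' @param regime `"post_delay"` (IL-10 induction active, `t >= t_delay`) or
#'   `"pre_delay"` (gate off).
#' @param C10_max Upper end of the scan (nM).  Default: twice the maximal
#'   attainable IL-10 production over the subsystem solution at `C_10 = 0`,
#'   i.e. `2 (alpha_10 + k_10T C_T(0) + k_106 C_6(0)) / beta_10`, or 10 if
#'   the subsystem at zero is nonphysical.
#' @param scan_points Number of scan nodes (>= 100).
#' @return An `equilibria_tbl`: a tibble with one row per equilibrium and
#'   columns `regime`, `C_T`, `C_6`, `C_10`, `residual_norm` (sup-norm of the
#'   full RHS at the root), `lambda1`..`lambda3` (complex eigenvalues, real
#'   part ascending), `stability`.  Scan subintervals excluded because the
#'   subsystem was singular are reported in the `excluded` attribute.
#' @examples
#' enumerate_equilibria(cytokine_params())
#' @export
enumerate_equilibria <- function(params, regime = c("post_delay", "pre_delay"),
                                 C10_max = NULL, scan_points = 10001) {
  params <- validate_params(params)
  regime <- match.arg(regime)
  if (scan_points < 100) abort("scan_points must be >= 100")
  p <- unclass(params)

  if (is.null(C10_max)) {
    base <- solve_pro_subsystem(params, 0)
    C10_max <- if (base$physical && base$D > 0) {
      2 * (p$alpha_10 + p$k_10T * base$C_T + p$k_106 * base$C_6) / p$beta_10
    } else 10
    C10_max <- max(C10_max, 2 * p$alpha_10 / p$beta_10, 1e-3)
  }

  grid <- seq(0, C10_max, length.out = scan_points)
  f <- equilibrium_residual(params, grid, regime)
  ok <- is.finite(f)
  excluded <- tibble::tibble(lower = grid[-length(grid)][!ok[-length(ok)] | !ok[-1]],
                             upper = grid[-1][!ok[-length(ok)] | !ok[-1]])

  roots <- numeric()
  # exact zeros on the grid
  hit <- which(ok & f == 0)
  roots <- c(roots, grid[hit])
  # sign changes between adjacent finite values
  sgn <- sign(f)
  ch <- which(ok[-length(ok)] & ok[-1] & sgn[-length(sgn)] * sgn[-1] < 0)
  for (i in ch) {
    lo <- grid[i]; hi <- grid[i + 1]
    flo <- f[i]
    while (hi - lo > 1e-12) {
      mid <- (lo + hi) / 2
      fm <- equilibrium_residual(params, mid, regime)
      if (!is.finite(fm)) break
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(unique(roots))

  rows <- purrr::map(roots, function(r) {
    sub <- solve_pro_subsystem(params, r)
    if (!sub$physical) return(NULL)
    st <- c(t = if (regime == "post_delay") p$t_delay else 0,
            C_T = sub$C_T, C_6 = sub$C_6, C_10 = r)
    res <- max(abs(cytokine_rhs(st, params)))
    J <- cytokine_jacobian(params, st, mode = "exact", regime = regime)
    tibble::tibble(regime = regime, C_T = sub$C_T, C_6 = sub$C_6, C_10 = r,
                   residual_norm = res,
                   lambda1 = J$eigenvalues[1], lambda2 = J$eigenvalues[2],
                   lambda3 = J$eigenvalues[3],
                   stability = classify_stability(J$eigenvalues))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(regime = character(), C_T = numeric(),
                          C_6 = numeric(), C_10 = numeric(),
                          residual_norm = numeric(),
                          lambda1 = complex(), lambda2 = complex(),
                          lambda3 = complex(), stability = character())
  }
  structure(out, class = c("equilibria_tbl", class(out)),
            params = params, excluded = excluded, C10_max = C10_max)
}

#' Jacobian of the cytokine network at a state
#'
#' Assembles the 3x3 Jacobian of the model RHS.  The first two rows are
#' exact in both modes:
#' `(-beta_T - gamma_T10 C_10, k_T6, -gamma_T10 C_T)` and
#' `(k_6T, -beta_6 - gamma_610 C_10, -gamma_610 C_6)`.  The IL-10 row
#' depends on `mode`:
#' \describe{
#'   \item{`"exact"` (default)}{full product rule,
#'     `J31 = k_10T h(d) + (k_10T C_T + k_106 C_6) h'(d)`,
#'     `J32 = k_106 h(d) - (k_10T C_T + k_106 C_6) h'(d)`, valid for any
#'     state (on the clamped branch `d <= 0` the induction row is zero).}
#'   \item{`"paper"`}{the commonly quoted simplification that keeps only the
#'     gate-derivative term with a pooled rate,
#'     `J31 = (k_10T + k_106) h'(d)` and `J32 = -J31`; requires `d > 0`.}
#' }
#' with `h'` the derivative of the Hill gate, and `J33 = -beta_10`.
#'
#' @param params A [cytokine_params()] object.
#' @param state State (as in [cytokine_rhs()]; `t` may be omitted).
#' @param mode `"exact"` or `"paper"`.
#' @param regime `"post_delay"` (induction active) or `"pre_delay"`
#'   (IL-10 row is `(0, 0, -beta_10)`).
#' @return A `jacobian_result`: list with `matrix` (3x3), `eigenvalues`
#'   (complex, sorted by ascending real part, ties by imaginary part),
#'   `mode`, `regime`, `state`.
#' @examples
#' J <- cytokine_jacobian(cytokine_params(),
#'                        c(C_T = 0.623, C_6 = 0.512, C_10 = 1.837),
#'                        mode = "paper")
#' J$eigenvalues
#' @export
cytokine_jacobian <- function(params, state, mode = c("exact", "paper"),
                              regime = "post_delay") {
  params <- validate_params(params)
  mode <- match.arg(mode)
  regime <- match.arg(regime, c("post_delay", "pre_delay"))
  if (is.data.frame(state)) state <- unlist(state[1, intersect(c("C_T", "C_6", "C_10"), names(state))])
  CT <- state[["C_T"]]; C6 <- state[["C_6"]]; C10 <- state[["C_10"]]
  p <- unclass(params)
  J <- matrix(0, 3, 3)
  J[1, ] <- c(-p$beta_T - p$gamma_T10 * C10, p$k_T6, -p$gamma_T10 * CT)
  J[2, ] <- c(p$k_6T, -p$beta_6 - p$gamma_610 * C10, -p$gamma_610 * C6)
  J[3, 3] <- -p$beta_10
  if (regime == "post_delay") {
    d <- CT - C6
    if (mode == "paper") {
      if (d <= 0) abort("paper-mode Jacobian requires C_T > C_6")
      hp <- hill_derivative(d, p$hill_K, p$hill_n)
      J[3, 1] <- (p$k_10T + p$k_106) * hp
      J[3, 2] <- -J[3, 1]
    } else {
      h <- hill_activation(CT, C6, p$hill_K, p$hill_n)
      hp <- hill_derivative(max(d, 0), p$hill_K, p$hill_n)
      drive <- p$k_10T * CT + p$k_106 * C6
      J[3, 1] <- p$k_10T * h + drive * hp
      J[3, 2] <- p$k_106 * h - drive * hp
    }
  }
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  ev <- ev[order(Re(ev), Im(ev))]
  structure(list(matrix = J, eigenvalues = ev, mode = mode, regime = regime,
                 state = c(C_T = CT, C_6 = C6, C_10 = C10)),
            class = "jacobian_result")
}

#' @export
print.jacobian_result <- function(x, ...) {
  cat("<jacobian_result> mode =", x$mode, ", regime =", x$regime, "\n")
  print(round(x$matrix, 6))
  cat("eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' @method tidy jacobian_result
#' @export
tidy.jacobian_result <- function(x, ...) {
  tibble::tibble(eigenvalue = seq_along(x$eigenvalues),
                 real = Re(x$eigenvalues), imaginary = Im(x$eigenvalues))
}

#' @method glance jacobian_result
#' @export
glance.jacobian_result <- function(x, ...) {
  tibble::tibble(trace = sum(diag(x$matrix)),
                 determinant = det(x$matrix),
                 stability = classify_stability(x$eigenvalues),
                 mode = x$mode)
}

#' Stability class from Jacobian eigenvalues
#'
#' Thresholded on the eigenvalue real parts at +/- 1e-9: all below -1e-9 is
#' `"stable"`, any above +1e-9 is `"unstable"`, otherwise `"marginal"`.
#'
#' @param eigenvalues Complex (or numeric) eigenvalues, or a
#'   `jacobian_result`.
#' @return One of `"stable"`, `"unstable"`, `"marginal"`.
#' @examples
#' classify_stability(c(-2.19, -1.11, -0.35))
#' @export
classify_stability <- function(eigenvalues) {
  if (inherits(eigenvalues, "jacobian_result")) {
    eigenvalues <- eigenvalues$eigenvalues
  }
  re <- Re(eigenvalues)
  if (all(re < -1e-9)) "stable"
  else if (any(re > 1e-9)) "unstable"
  else "marginal"
}

#' Pre-delay linear subsystem and its closed-form solution
#'
#' Before IL-10 induction switches on, and with IL-10 suppression decoupled,
#' the TNF-alpha / IL-6 pair evolves linearly,
#' \eqn{dC/dt = A C + \alpha} with
#' \eqn{A = \begin{pmatrix} -\beta_T & k_{T6} \\ k_{6T} & -\beta_6 \end{pmatrix}},
#' whose solution is \eqn{C(t) = e^{At} C_0 + A^{-1}(e^{At} - I)\alpha}.
#'
#' @param params A [cytokine_params()] object (used for `A` and `alpha`), or
#'   `NULL` if `A` and `alpha_vec` are given directly.
#' @param C0 Length-2 initial condition `(C_T, C_6)`.
#' @param A Optional 2x2 coefficient matrix overriding the one built from
#'   `params`.
#' @param alpha_vec Optional length-2 basal production vector.
#' @return A `linear_subsystem` object (list with `A`, `alpha_vec`, `C0`).
#' @examples
#' sub <- linear_subsystem(cytokine_params(), C0 = c(0.1, 0.05))
#' solve_linear_subsystem(sub, t = c(0, 1, 10))
#' @export
linear_subsystem <- function(params = NULL, C0 = c(0.1, 0.05), A = NULL,
                             alpha_vec = NULL) {
  if (is.null(A)) {
    p <- unclass(validate_params(params))
    A <- matrix(c(-p$beta_T, p$k_T6, p$k_6T, -p$beta_6), 2, 2, byrow = TRUE)
    if (is.null(alpha_vec)) alpha_vec <- c(p$alpha_T, p$alpha_6)
  }
  if (is.null(alpha_vec)) alpha_vec <- c(0, 0)
  stopifnot(all(dim(A) == c(2, 2)), length(alpha_vec) == 2, length(C0) == 2,
            all(is.finite(A)), all(is.finite(alpha_vec)), all(is.finite(C0)))
  structure(list(A = A, alpha_vec = as.numeric(alpha_vec),
                 C0 = as.numeric(C0)),
            class = "linear_subsystem")
}

#' @rdname linear_subsystem
#' @param sub A `linear_subsystem`.
#' @param t Time(s) (hr, >= 0); vectorized.
#' @return `solve_linear_subsystem()`: a tibble with columns `t`, `C_T`,
#'   `C_6` evaluated by matrix exponential.
#' @export
solve_linear_subsystem <- function(sub, t) {
  stopifnot(inherits(sub, "linear_subsystem"), all(t >= 0))
  if (abs(det(sub$A)) < 1e-12) abort("coefficient matrix A is singular")
  Ainv_alpha <- solve(sub$A, sub$alpha_vec)
  states <- vapply(t, function(ti) {
    E <- as.matrix(Matrix::expm(sub$A * ti))
    as.numeric(E %*% sub$C0 + (E %*% Ainv_alpha - Ainv_alpha))
  }, numeric(2))
  tibble::tibble(t = t, C_T = states[1, ], C_6 = states[2, ])
}
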