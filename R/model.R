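#' Heaviside step function
#'
#' Unit step with the right-continuous convention `H(0) = 1`, used to gate
#' delayed IL-10 induction on at exactly `t = t_delay`.
#'
#' @param x Numeric vector (finite).
#' @return 0/1 numeric vector of the same length.
#' @examples
#' heaviside(c(-1, 0, 6))
#' @export
heaviside <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  as.numeric(x >= 0)
}

#' Hill gate on the pro-inflammatory excess
#'
#' Cooperative activation fraction \eqn{d^n / (K^n + d^n)} evaluated on the
#' clamped pro-inflammatory excess \eqn{d = \max(C_T - C_6, 0)}.  The clamp
#' makes the gate well defined for all states and all cooperativities: the
#' drive is zero whenever IL-6 matches or exceeds TNF-alpha, reflecting that
#' IL-10 induction responds to pro-inflammatory *dominance*.
#'
#' @param C_T,C_6 TNF-alpha and IL-6 concentrations (nM); vectorized.
#' @param K Half-maximal excess (nM, > 0).
#' @param n Cooperativity (>= 1).
#' @return Activation fraction in `[0, 1)`; 0.5 exactly when `C_T - C_6 == K`.
#' @examples
#' hill_activation(0.4, 0.1, K = 0.3, n = 5)  # half-max
#' @export
hill_activation <- function(C_T, C_6, K = 0.3, n = 5) {
  stopifnot(K > 0, n >= 1)
  d <- pmax(C_T - C_6, 0)
  dn <- d^n
  dn / (K^n + dn)
}

# Derivative of the clamped Hill gate with respect to the excess d;
# zero on the clamped branch (d <= 0, using n > 1 smoothness at 0).
hill_derivative <- function(d, K, n) {
  ifelse(d > 0, n * K^n * d^(n - 1) / (K^n + d^n)^2, 0)
}

#' Cytokine state constructor
#'
#' A single time point of the network: time plus the three concentrations.
#'
#' @param t Time (hr, >= 0).
#' @param C_T,C_6,C_10 Concentrations (nM, >= 0, finite).
#' @return A one-row tibble with columns `t`, `C_T`, `C_6`, `C_10`.
#' @export
cytokine_state <- function(t = 0, C_T = 0.1, C_6 = 0.05, C_10 = 0.01) {
  vals <- c(t = t, C_T = C_T, C_6 = C_6, C_10 = C_10)
  if (!all(is.finite(vals))) abort("state values must be finite")
  if (any(vals < 0)) abort("state values must be nonnegative")
  tibble::tibble(t = t, C_T = C_T, C_6 = C_6, C_10 = C_10)
}

#' Right-hand side of the cytokine network ODEs
#'
#' Evaluates the time derivatives of TNF-alpha, IL-6 and IL-10 at a state.
#' Time enters only through the Heaviside delay gate on IL-10 induction.
#'
#' @param state A one-row data frame with columns `t`, `C_T`, `C_6`, `C_10`
#'   (e.g. from [cytokine_state()]), or a named numeric vector with those
#'   elements.
#' @param params A [cytokine_params()] object.
#' @return Named numeric vector `c(dC_T, dC_6, dC_10)` in nM/hr.
#' @examples
#' cytokine_rhs(cytokine_state(0, 0.1, 0.05, 0.01), cytokine_params())
#' @export
cytokine_rhs <- function(state, params) {
  params <- validate_params(params)
  if (is.data.frame(state)) state <- unlist(state[1, c("t", "C_T", "C_6", "C_10")])
  t <- state[["t"]]; CT <- state[["C_T"]]; C6 <- state[["C_6"]]; C10 <- state[["C_10"]]
  p <- unclass(params)
  gate <- heaviside(t - p$t_delay)
  hill <- hill_activation(CT, C6, p$hill_K, p$hill_n)
  c(dC_T = p$alpha_T + p$k_T6 * C6 - p$beta_T * CT - p$gamma_T10 * C10 * CT,
    dC_6 = p$alpha_6 + p$k_6T * CT - p$beta_6 * C6 - p$gamma_610 * C10 * C6,
    dC_10 = p$alpha_10 + (p$k_10T * CT + p$k_106 * C6) * hill * gate -
      p$beta_10 * C10)
}

#' Dimensionless rescaling of the model
#'
#' Rescales concentrations by the Hill threshold `K`, IL-10 additionally by
#' the TNF-alpha suppression strength, and time by the TNF-alpha decay rate:
#' \eqn{\tilde C_T = C_T/K}, \eqn{\tilde C_6 = C_6/K},
#' \eqn{\tilde C_{10} = \gamma_{T10} C_{10}/K}, \eqn{\tau = \beta_T t}.
#' The surviving dimensionless groups are the activation-to-degradation
#' ratios \eqn{k_{T6}/\beta_T} and \eqn{k_{6T}/\beta_6}, the suppression
#' strength ratio \eqn{\gamma_{610}/\gamma_{T10}} and the delay (time-scale)
#' ratio \eqn{\beta_{10}/\beta_T}.
#'
#' @param params A [cytokine_params()] object.
#' @param state Optional state (as in [cytokine_rhs()]) to rescale.
#' @return A one-row tibble with the four ratio columns and, when `state` is
#'   given, the rescaled state columns `C_tilde_T`, `C_tilde_6`, `C_tilde_10`,
#'   `tau`.  The suppression ratio is `NA` when `gamma_T10 == 0`.
#' @examples
#' nondimensionalize(cytokine_params())
#' @export
nondimensionalize <- function(params, state = NULL) {
  p <- unclass(validate_params(params))
  out <- tibble::tibble(
    ratio_activation_T = p$k_T6 / p$beta_T,
    ratio_activation_6 = p$k_6T / p$beta_6,
    ratio_suppression = if (p$gamma_T10 > 0) p$gamma_610 / p$gamma_T10 else NA_real_,
    ratio_delay = p$beta_10 / p$beta_T)
  if (!is.null(state)) {
    if (is.data.frame(state)) state <- unlist(state[1, c("t", "C_T", "C_6", "C_10")])
    out <- dplyr::mutate(out,
      C_tilde_T = state[["C_T"]] / p$hill_K,
      C_tilde_6 = state[["C_6"]] / p$hill_K,
      C_tilde_10 = p$gamma_T10 * state[["C_10"]] / p$hill_K,
      tau = p$beta_T * state[["t"]])
  }
  out
}
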