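#' Default parameter ranges for global sensitivity analysis
#'
#' The tested ranges for the eleven parameters screened in the global
#' sensitivity analysis: suppression and induction rates, Hill gate shape,
#' basal productions and decay rates.  Cross-activation rates (`k_T6`,
#' `k_6T`) and the IL-6 suppression rate are held at their defaults.
#'
#' @return A tibble with columns `name`, `low`, `high` (units as in
#'   [cytokine_params()]).
#' @export
default_param_ranges <- function() {
  tibble::tribble(
    ~name,        ~low,   ~high,
    "gamma_T10",  0.02,   0.15,
    "k_10T",      0.05,   0.25,
    "k_106",      0.04,   0.20,
    "hill_n",     2,      8,
    "hill_K",     0.1,    0.5,
    "alpha_T",    0.005,  0.05,
    "alpha_6",    0.005,  0.03,
    "alpha_10",   0.001,  0.01,
    "beta_T",     1.0,    2.5,
    "beta_6",     0.8,    1.8,
    "beta_10",    0.2,    0.6)
}

check_ranges <- function(ranges) {
  ranges <- tibble::as_tibble(ranges)
  stopifnot(all(c("name", "low", "high") %in% names(ranges)), nrow(ranges) > 0)
  if (any(ranges$low >= ranges$high)) abort("each range needs low < high")
  model_rows <- ranges$name %in% param_names()
  if (any(ranges$low[model_rows] < 0)) {
    abort("model parameter ranges must be nonnegative")
  }
  ranges
}

#' Latin hypercube sample over parameter ranges
#'
#' Stratified uniform sampling: each column has exactly one draw in each of
#' the `n_base` equiprobable strata of its range, with strata paired by an
#' independent random permutation per column.  Deterministic for a fixed
#' seed.
#'
#' @param ranges Tibble of `name`, `low`, `high` rows
#'   (default [default_param_ranges()]).
#' @param n_base Number of samples (>= 2).
#' @param seed Integer seed (required; recorded on the result).
#' @return A `sample_design` tibble (`n_base` rows, one column per
#'   parameter) with attributes `scheme = "lhs"`, `ranges`, `seed`.
#' @examples
#' lhs_sample(n_base = 4, seed = 1)
#' @export
lhs_sample <- function(ranges = default_param_ranges(), n_base, seed) {
  ranges <- check_ranges(ranges)
  stopifnot(n_base >= 2, is.finite(seed))
  k <- nrow(ranges)
  u <- withr::with_seed(as.integer(seed), lhs::randomLHS(n_base, k))
  m <- sweep(u, 2, ranges$high - ranges$low, "*")
  m <- sweep(m, 2, ranges$low, "+")
  colnames(m) <- ranges$name
  out <- tibble::as_tibble(m)
  structure(out, class = c("sample_design", class(out)),
            scheme = "lhs", ranges = ranges, seed = as.integer(seed))
}

#' Scalar quantities of interest for sensitivity analysis
#'
#' Maps a parameter set to a scalar model output:
#' \describe{
#'   \item{`steady_state_CT`}{TNF-alpha at the post-delay equilibrium with
#'     the largest `C_T` among stable roots (via [enumerate_equilibria()]).}
#'   \item{`final_CT_72h`}{TNF-alpha at the end of a baseline 72-hr run.}
#'   \item{`peak_C10`}{Peak IL-10 over a baseline 72-hr run.}
#'   \item{`auc_CT_0_72`}{Trapezoidal area under the TNF-alpha curve.}
#'   \item{`resolution_time`}{TNF-alpha resolution time of
#'     [summarize_trajectory()]; coded as 72 when not reached.}
#' }
#' Simulation-based QOIs use `dt = 0.02` hr.
#'
#' @param params A [cytokine_params()] object.
#' @param qoi_name One of the names above.
#' @return A single numeric value.
#' @examples
#' evaluate_qoi(cytokine_params(), "steady_state_CT")
#' @export
evaluate_qoi <- function(params, qoi_name) {
  qoi_name <- match.arg(qoi_name, c("steady_state_CT", "final_CT_72h",
                                    "peak_C10", "auc_CT_0_72",
                                    "resolution_time"))
  params <- validate_params(params)
  if (qoi_name == "steady_state_CT") {
    eq <- enumerate_equilibria(params, regime = "post_delay",
                               scan_points = 4001)
    st <- eq[eq$stability == "stable", ]
    if (nrow(st) == 0) st <- eq
    if (nrow(st) == 0) return(NA_real_)
    return(max(st$C_T))
  }
  tr <- simulate_cytokines(params, t_end = 72, dt = 0.02)
  switch(qoi_name,
    final_CT_72h = tr$C_T[nrow(tr)],
    peak_C10 = max(tr$C_10),
    auc_CT_0_72 = sum(diff(tr$time) * (head(tr$C_T, -1) + tail(tr$C_T, -1)) / 2),
    resolution_time = {
      rt <- attr(summarize_trajectory(tr), "resolution_time")
      if (is.na(rt)) 72 else rt
    })
}

# Evaluate a QOI over the rows of a design matrix (columns = sampled
# parameters, other fields at their defaults).
qoi_over_matrix <- function(m, qoi_name, base_params) {
  vapply(seq_len(nrow(m)), function(i) {
    q <- do.call(update_params, c(list(base_params), as.list(m[i, ])))
    evaluate_qoi(q, qoi_name)
  }, numeric(1))
}

#' Sobol sensitivity indices by Saltelli sampling
#'
#' Variance-based global sensitivity analysis.  Two base matrices `A` and
#' `B` are drawn as halves of one Latin-hypercube sample of dimension `2k`,
#' and the Saltelli cross matrices `AB_i` (A with column i from B) complete
#' the design (`n_base * (k + 2)` model runs).  First-order indices use the
#' Saltelli estimator \eqn{S_i = \mathrm{mean}(f_B (f_{AB_i} - f_A)) / V},
#' total-order indices the Jansen estimator
#' \eqn{S_{Ti} = \mathrm{mean}((f_A - f_{AB_i})^2) / (2V)}, with `V` the
#' variance of the pooled `A`/`B` evaluations.  Bootstrap confidence
#' half-widths resample design rows.  Deterministic for a fixed seed.
#'
#' @param ranges Tibble of `name`, `low`, `high` rows.
#' @param qoi_name Quantity of interest (see [evaluate_qoi()]); ignored when
#'   `fn` is supplied.
#' @param n_base Base sample size (a power of 2 is recommended).
#' @param seed Integer seed.
#' @param n_bootstrap Bootstrap replicates for the confidence half-widths.
#' @param fn Optional function `f(matrix) -> numeric` replacing the model
#'   QOI (used for analytic test functions); receives a numeric matrix with
#'   one column per range row.
#' @param params Base parameter set for QOI evaluation.
#' @return A `sensitivity_result` tibble with columns `parameter`,
#'   `first_order`, `total_order`, `first_order_ci`, `total_order_ci`, and
#'   attributes `qoi_name`, `n_base`, `seed`, `ranges`.
#' @examples
#' sobol_indices(qoi_name = "steady_state_CT", n_base = 16, seed = 1,
#'               n_bootstrap = 20)
#' @export
sobol_indices <- function(ranges = default_param_ranges(),
                          qoi_name = "steady_state_CT",
                          n_base = 1024, seed = 1, n_bootstrap = 200,
                          fn = NULL, params = cytokine_params()) {
  ranges <- check_ranges(ranges)
  k <- nrow(ranges)
  stopifnot(n_base >= 2)

  wide <- tibble::tibble(name = c(paste0(ranges$name, "_A"),
                                  paste0(ranges$name, "_B")),
                         low = rep(ranges$low, 2), high = rep(ranges$high, 2))
  ab <- lhs_sample(wide, n_base, seed)
  A <- as.matrix(ab[, seq_len(k), drop = FALSE])
  B <- as.matrix(ab[, k + seq_len(k), drop = FALSE])
  colnames(A) <- colnames(B) <- ranges$name

  evalf <- if (is.null(fn)) {
    function(m) qoi_over_matrix(m, qoi_name, params)
  } else fn

  fA <- evalf(A)
  fB <- evalf(B)
  fAB <- matrix(NA_real_, n_base, k)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fAB[, i] <- evalf(ABi)
  }

  est <- function(idx) {
    a <- fA[idx]; b <- fB[idx]; ab_ <- fAB[idx, , drop = FALSE]
    V <- var(c(a, b))
    if (V < 1e-30) abort("QOI constant over range")
    S1 <- vapply(seq_len(k), function(i) mean(b * (ab_[, i] - a)) / V,
                 numeric(1))
    ST <- vapply(seq_len(k), function(i) mean((a - ab_[, i])^2) / (2 * V),
                 numeric(1))
    list(S1 = S1, ST = ST)
  }
  full <- est(seq_len(n_base))

  boots <- withr::with_seed(as.integer(seed) + 1L, {
    purrr::map(seq_len(n_bootstrap), function(b) {
      est(sample.int(n_base, n_base, replace = TRUE))
    })
  })
  bs_S1 <- do.call(rbind, purrr::map(boots, "S1"))
  bs_ST <- do.call(rbind, purrr::map(boots, "ST"))
  ci <- function(m) apply(m, 2, function(col) {
    diff(quantile(col, c(0.025, 0.975), names = FALSE)) / 2
  })

  out <- tibble::tibble(parameter = ranges$name,
                        first_order = full$S1, total_order = full$ST,
                        first_order_ci = ci(bs_S1),
                        total_order_ci = ci(bs_ST))
  structure(out, class = c("sensitivity_result", class(out)),
            qoi_name = if (is.null(fn)) qoi_name else "custom",
            n_base = n_base, seed = as.integer(seed), ranges = ranges,
            params = params)
}

#' @method glance sensitivity_result
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(qoi_name = attr(x, "qoi_name"), n_base = attr(x, "n_base"),
                 seed = attr(x, "seed"), n_parameters = nrow(x),
                 sum_first_order = sum(x$first_order))
}

#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("first_order", "total_order"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(stats::reorder(.data$parameter,
                                                    .data$value),
                                     .data$value, fill = .data$index)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Sobol index", fill = NULL)
}

#' @export
plot.sensitivity_result <- function(x, ...) print(autoplot.sensitivity_result(x, ...))
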