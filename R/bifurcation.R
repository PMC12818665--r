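# Generic fold (count-change) detector: `count_fn(v)` returns the number of
# equilibria/roots at parameter value v. Count changes between adjacent grid
# values are refined by bisection on the parameter to width <= tol.
detect_folds <- function(count_fn, grid, tol = 1e-4) {
  counts <- vapply(grid, count_fn, numeric(1))
  out <- tibble::tibble(lower = numeric(), upper = numeric(),
                        count_lower = numeric(), count_upper = numeric())
  for (i in seq_len(length(grid) - 1)) {
    if (counts[i] == counts[i + 1]) next
    lo <- grid[i]; hi <- grid[i + 1]
    clo <- counts[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      cm <- count_fn(mid)
      if (cm == clo) lo <- mid else hi <- mid
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      lower = lo, upper = hi,
      count_lower = counts[i], count_upper = counts[i + 1]))
  }
  out
}

#' Equilibrium structure across a parameter sweep
#'
#' Runs [enumerate_equilibria()] (post-delay regime) at every value of a
#' parameter grid and records all equilibrium branches.  Saddle-node (fold)
#' bifurcations are detected as changes in the equilibrium count between
#' adjacent grid values and refined by bisection on the parameter to an
#' interval width of 1e-4.
#'
#' @param params Base [cytokine_params()].
#' @param parameter Name of the swept field (default `"gamma_T10"`, the
#'   IL-10 suppression efficacy on TNF-alpha).
#' @param grid Ascending numeric vector of parameter values (default: the
#'   physiologically plausible suppression range 0.02-0.15 in 27 points).
#' @param scan_points Passed to [enumerate_equilibria()].
#' @return A `bifurcation_diagram`: a tibble with columns `param_value`,
#'   `branch_index`, `C_T`, `C_6`, `C_10`, `stability`, `residual_norm`,
#'   plus attributes `parameter` and `fold_locations` (a tibble of refined
#'   parameter intervals where the count changes).
#' @examples
#' sweep_equilibria(cytokine_params(),
#'                  grid = seq(0.02, 0.15, length.out = 5),
#'                  scan_points = 2001)
#' @export
sweep_equilibria <- function(params, parameter = "gamma_T10",
                             grid = seq(0.02, 0.15, length.out = 27),
                             scan_points = 10001) {
  params <- validate_params(params)
  if (!parameter %in% param_names()) abort(paste0("unknown parameter: ", parameter))
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be strictly increasing")

  at_value <- function(v) {
    q <- tryCatch(do.call(update_params, c(list(params), setNames(list(v), parameter))),
                  error = function(e) abort(paste0("invalid grid value ", v, ": ",
                                                   conditionMessage(e))))
    enumerate_equilibria(q, regime = "post_delay", scan_points = scan_points)
  }

  pts <- purrr::map(grid, at_value)
  rows <- purrr::imap(pts, function(eq, i) {
    if (nrow(eq) == 0) return(NULL)
    dplyr::mutate(tibble::as_tibble(eq), param_value = grid[i],
                  branch_index = dplyr::row_number(), .before = 1)
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  out <- dplyr::select(out, "param_value", "branch_index", "C_T", "C_6",
                       "C_10", "stability", "residual_norm")

  counts <- vapply(pts, nrow, integer(1))
  folds <- if (length(grid) >= 2 && any(diff(counts) != 0)) {
    detect_folds(function(v) nrow(at_value(v)), grid)
  } else {
    tibble::tibble(lower = numeric(), upper = numeric(),
                   count_lower = numeric(), count_upper = numeric())
  }

  structure(out, class = c("bifurcation_diagram", class(out)),
            parameter = parameter, params = params, grid = grid,
            fold_locations = folds)
}

#' Fold locations of a bifurcation diagram
#' @param diagram A `bifurcation_diagram`.
#' @return The tibble of refined parameter intervals where the equilibrium
#'   count changes (empty if the branch structure never changes).
#' @export
fold_locations <- function(diagram) attr(diagram, "fold_locations")

#' @method autoplot bifurcation_diagram
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$param_value, .data$C_T,
                               colour = .data$stability,
                               group = .data$branch_index)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = "steady-state TNF-α (nM)", colour = NULL)
}

#' @export
plot.bifurcation_diagram <- function(x, ...) print(autoplot.bifurcation_diagram(x, ...))

#' Hysteresis protocol: ascending/descending parameter sweeps
#'
#' Sweeps a parameter across a grid twice — ascending from the standard
#' initial state, then descending — integrating to `t_settle` at each value
#' and inheriting the previous attained state, which is the dynamical probe
#' for bistability: on a bistable branch the two passes settle on different
#' attractors.  Settling is checked as a sup-norm RHS residual at `t_settle`
#' (<= 1e-9); an unsettled point is re-integrated once for four times as
#' long and flagged if still unsettled.
#'
#' @param params Base [cytokine_params()].
#' @param parameter Swept field name.
#' @param grid Ascending parameter values.
#' @param t_settle Integration horizon per grid value (hr).
#' @param dt RK4 step (hr).
#' @return A `hysteresis_result`: tibble with columns `param_value`,
#'   `direction` (`"up"`/`"down"`), `C_T`, `C_6`, `C_10`, `residual_norm`,
#'   `settled`; attribute `max_gap` = max over the grid of `|C_T(up) -
#'   C_T(down)|`, also available via [glance()].
#' @examples
#' h <- hysteresis_sweep(cytokine_params(),
#'                       grid = seq(0.02, 0.15, length.out = 5),
#'                       t_settle = 200, dt = 0.1)
#' glance(h)$max_gap
#' @export
hysteresis_sweep <- function(params, parameter = "gamma_T10",
                             grid = seq(0.02, 0.15, length.out = 27),
                             t_settle = 500, dt = 0.05) {
  params <- validate_params(params)
  if (!parameter %in% param_names()) abort(paste0("unknown parameter: ", parameter))
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be strictly increasing")

  settle_one <- function(v, init) {
    q <- do.call(update_params, c(list(params), setNames(list(v), parameter)))
    run <- function(horizon) {
      tr <- simulate_cytokines(q, init = init, t_end = horizon, dt = dt)
      unlist(tr[nrow(tr), c("C_T", "C_6", "C_10")])
    }
    st <- run(t_settle)
    res <- max(abs(cytokine_rhs(c(t = t_settle, st), q)))
    settled <- res <= 1e-9
    if (!settled) {
      st <- run(4 * t_settle)
      res <- max(abs(cytokine_rhs(c(t = 4 * t_settle, st), q)))
      settled <- res <= 1e-9
      if (!settled) warn(paste0("point did not settle at ", parameter, " = ", v))
    }
    list(state = st, residual = res, settled = settled)
  }

  pass <- function(values, direction) {
    init <- unlist(cytokine_state()[1, c("C_T", "C_6", "C_10")])
    purrr::map(values, function(v) {
      r <- settle_one(v, init)
      init <<- r$state
      tibble::tibble(param_value = v, direction = direction,
                     C_T = r$state[["C_T"]], C_6 = r$state[["C_6"]],
                     C_10 = r$state[["C_10"]],
                     residual_norm = r$residual, settled = r$settled)
    }) |> dplyr::bind_rows()
  }

  up <- pass(grid, "up")
  down <- pass(rev(grid), "down")
  out <- dplyr::arrange(dplyr::bind_rows(up, down), .data$param_value,
                        .data$direction)
  gap <- dplyr::left_join(up, down, by = "param_value",
                          suffix = c("_up", "_down"))
  max_gap <- max(abs(gap$C_T_up - gap$C_T_down))
  structure(out, class = c("hysteresis_result", class(out)),
            parameter = parameter, params = params, max_gap = max_gap)
}

#' @method glance hysteresis_result
#' @export
glance.hysteresis_result <- function(x, ...) {
  tibble::tibble(parameter = attr(x, "parameter"),
                 max_gap = attr(x, "max_gap"),
                 n_grid = length(unique(x$param_value)),
                 all_settled = all(x$settled))
}

#' @method autoplot hysteresis_result
#' @export
autoplot.hysteresis_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$param_value, .data$C_T,
                               colour = .data$direction)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$direction)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = "attained TNF-α (nM)", colour = "sweep")
}

#' @export
plot.hysteresis_result <- function(x, ...) print(autoplot.hysteresis_result(x, ...))

#' Linear regression along an equilibrium branch
#'
#' Ordinary least squares of steady-state TNF-alpha against the swept
#' parameter over a selected branch of a bifurcation diagram, summarising
#' how strongly suppression efficacy tracks the steady inflammatory tone.
#'
#' @param diagram A `bifurcation_diagram`.
#' @param stability Branch selector: keep points with this stability class
#'   (default `"stable"`); `NULL` keeps all points.
#' @param response Response column (default `"C_T"`).
#' @return A `branch_regression` object wrapping the `lm` fit, with
#'   [tidy()] / [glance()] methods; `glance()` reports `slope`, `intercept`,
#'   `r_squared` and `n_points`.
#' @export
branch_regression <- function(diagram, stability = "stable", response = "C_T") {
  df <- tibble::as_tibble(diagram)
  if (!is.null(stability)) df <- df[df$stability %in% stability, ]
  if (nrow(df) < 3) abort("branch regression needs at least 3 points")
  y <- df[[response]]
  x <- df$param_value
  if (var(y) < 1e-30) {
    fit <- lm(y ~ x)
    if (max(abs(stats::residuals(fit))) > 1e-12) {
      abort("response variance is zero but residuals are not")
    }
    r2 <- 1
  } else {
    fit <- lm(y ~ x)
    # suppressed: lm's "essentially perfect fit" note on collinear branches
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  structure(list(fit = fit, r_squared = r2, n_points = nrow(df),
                 parameter = attr(diagram, "parameter"),
                 response = response, stability = stability),
            class = "branch_regression")
}

#' @export
print.branch_regression <- function(x, ...) {
  g <- glance.branch_regression(x)
  cat("<branch_regression>", x$response, "~", x$parameter,
      "on", x$n_points, "points\n")
  cat(sprintf("  slope = %.6g, intercept = %.6g, R^2 = %.4f\n",
              g$slope, g$intercept, g$r_squared))
  invisible(x)
}

#' @method tidy branch_regression
#' @export
tidy.branch_regression <- function(x, ...) {
  co <- coef(summary(x$fit))
  tibble::tibble(term = c("intercept", x$parameter),
                 estimate = co[, 1], std_error = co[, 2])
}

#' @method glance branch_regression
#' @export
glance.branch_regression <- function(x, ...) {
  co <- coef(x$fit)
  tibble::tibble(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = x$r_squared, n_points = x$n_points)
}
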