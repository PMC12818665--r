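#' Breakpoint-aligned time grid
#'
#' Builds the union of per-segment uniform grids between consecutive sorted
#' unique breakpoints (with 0 and `t_end` appended).  Each segment is divided
#' into `ceil(length/dt)` equal steps, so the actual step never exceeds `dt`
#' and every breakpoint falls exactly on a node.  Aligning the grid with the
#' IL-10 delay time, bolus times and modulation boundaries keeps each
#' integration segment smooth, which is what preserves the Runge-Kutta
#' order of accuracy across the model's discontinuities.
#'
#' @param t_end End time (hr, > 0).
#' @param dt Maximal step (hr, > 0).
#' @param breakpoints Numeric vector of times in `[0, t_end]`.
#' @return Strictly increasing numeric vector starting at 0, ending at `t_end`.
#' @examples
#' build_time_grid(1, 0.3)  # 4 equal steps of 0.25
#' @export
build_time_grid <- function(t_end, dt, breakpoints = numeric()) {
  stopifnot(is.finite(t_end), t_end > 0, is.finite(dt), dt > 0)
  if (length(breakpoints) > 0 &&
      (any(!is.finite(breakpoints)) || any(breakpoints < 0) ||
       any(breakpoints > t_end))) {
    abort("breakpoints must lie within [0, t_end]")
  }
  bp <- sort(unique(c(0, breakpoints, t_end)))
  # collapse breakpoints closer than 1e-12 to avoid degenerate segments
  bp <- bp[c(TRUE, diff(bp) > 1e-12)]
  if (bp[length(bp)] < t_end) bp[length(bp)] <- t_end
  grid <- unlist(lapply(seq_len(length(bp) - 1), function(i) {
    len <- bp[i + 1] - bp[i]
    m <- ceiling(len / dt - 1e-12)
    seq(bp[i], bp[i + 1], length.out = m + 1)[-1]
  }))
  c(0, grid)
}

# RK4 over one smooth segment with fixed parameters and a fixed delay gate.
# The RHS arithmetic is inlined for speed; test-integrate.R asserts it agrees
# with cytokine_rhs() on random states.
rk4_segment <- function(y, ts, p, gate) {
  aT <- p$alpha_T; a6 <- p$alpha_6; a10 <- p$alpha_10
  kT6 <- p$k_T6; k6T <- p$k_6T; k10T <- p$k_10T; k106 <- p$k_106
  gT10 <- p$gamma_T10; g610 <- p$gamma_610
  bT <- p$beta_T; b6 <- p$beta_6; b10 <- p$beta_10
  n <- p$hill_n; Kn <- p$hill_K^p$hill_n
  f <- function(y) {
    d <- y[1] - y[2]
    hill <- if (gate && d > 0) {
      dn <- d^n
      dn / (Kn + dn)
    } else 0
    c(aT + kT6 * y[2] - bT * y[1] - gT10 * y[3] * y[1],
      a6 + k6T * y[1] - b6 * y[2] - g610 * y[3] * y[2],
      a10 + (k10T * y[1] + k106 * y[2]) * hill - b10 * y[3])
  }
  m <- length(ts)
  out <- matrix(NA_real_, m, 3)
  out[1, ] <- y
  for (i in seq_len(m - 1)) {
    h <- ts[i + 1] - ts[i]
    k1 <- f(y)
    k2 <- f(y + 0.5 * h * k1)
    k3 <- f(y + 0.5 * h * k2)
    k4 <- f(y + h * k3)
    y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(y < -1e-9)) abort("negative state encountered (reduce dt)")
    y[y < 0] <- 0
    out[i + 1, ] <- y
  }
  out
}

#' Simulate the cytokine network by fixed-step RK4
#'
#' Integrates the model with the classical fourth-order Runge-Kutta scheme on
#' a breakpoint-aligned grid ([build_time_grid()] with breakpoints at the
#' IL-10 delay time, all bolus times and all modulation window boundaries).
#' Within each segment the effective parameter set is the base set with all
#' active modulations applied multiplicatively, and the delay gate is fixed
#' by the segment's left endpoint (on from `t = t_delay`, matching the
#' right-continuous Heaviside convention).  A bolus amount is added to its
#' species *after* the state at that node is recorded, so the pre/post jump
#' is explicit in the output.
#'
#' @param params A [cytokine_params()] object.
#' @param init Initial state: a one-row data frame or named vector with
#'   `C_T`, `C_6`, `C_10` (default: the standard post-stroke initial
#'   concentrations 0.1 / 0.05 / 0.01 nM).
#' @param t_end Simulation horizon (hr); the default 72 hr covers the acute
#'   post-stroke window.
#' @param dt Maximal RK4 step (hr).
#' @param schedule An [intervention_schedule()] (default: none).
#' @return A `cytokine_trajectory`: a tibble with columns `time`, `C_T`,
#'   `C_6`, `C_10`, carrying the parameter set and schedule as attributes.
#'   States are nonnegative at every node (roundoff-scale negatives are
#'   snapped to zero; a genuine negative excursion raises an error).
#' @examples
#' tr <- simulate_cytokines(cytokine_params(), t_end = 24, dt = 0.1)
#' dplyr::slice_tail(tr, n = 1)
#' @export
simulate_cytokines <- function(params, init = cytokine_state(),
                               t_end = 72, dt = 0.01,
                               schedule = intervention_schedule()) {
  params <- validate_params(params)
  if (!inherits(schedule, "intervention_schedule")) {
    abort("schedule must be an intervention_schedule")
  }
  if (is.data.frame(init)) init <- unlist(init[1, c("C_T", "C_6", "C_10")])
  y <- as.numeric(init[c("C_T", "C_6", "C_10")])
  if (any(!is.finite(y)) || any(y < 0)) abort("initial state must be nonnegative and finite")

  bps <- c(params$t_delay,
           schedule$boluses$time,
           schedule$modulations$start, schedule$modulations$end)
  bps <- bps[bps > 0 & bps < t_end]
  grid <- build_time_grid(t_end, dt, bps)

  seg_bounds <- sort(unique(c(0, bps, t_end)))
  out <- matrix(NA_real_, length(grid), 3)
  out[1, ] <- y
  pos <- 1
  for (i in seq_len(length(seg_bounds) - 1)) {
    t0 <- seg_bounds[i]; t1 <- seg_bounds[i + 1]
    idx <- which(grid >= t0 - 1e-12 & grid <= t1 + 1e-12)
    ts <- grid[idx]
    p_eff <- unclass(effective_params(params, schedule, t0))
    gate <- t0 >= params$t_delay
    # bolus at the segment's left endpoint: state already recorded, add now
    b <- schedule$boluses
    hit <- which(abs(b$time - t0) < 1e-9)
    for (j in hit) {
      k <- match(b$species[j], c("C_T", "C_6", "C_10"))
      y[k] <- y[k] + b$amount[j]
    }
    seg <- rk4_segment(y, ts, p_eff, gate)
    out[idx[-1], ] <- seg[-1, , drop = FALSE]
    y <- seg[nrow(seg), ]
    pos <- idx[length(idx)]
  }

  new_trajectory(grid, out, params, schedule)
}

new_trajectory <- function(times, states, params, schedule) {
  tr <- tibble::tibble(time = times,
                       C_T = states[, 1], C_6 = states[, 2], C_10 = states[, 3])
  structure(tr, class = c("cytokine_trajectory", class(tr)),
            params = params, schedule = schedule)
}

#' Therapeutic scenario presets
#'
#' Canonical 72-hour simulations of the post-stroke network:
#' \describe{
#'   \item{`baseline`}{no intervention, standard initial concentrations.}
#'   \item{`il10_bolus`}{baseline plus a 0.05 nM IL-10 bolus at 24 hr
#'     (anti-inflammatory augmentation).}
#'   \item{`tnf_inhibition`}{basal TNF-alpha production halved over the whole
#'     run (sustained anti-TNF blockade; only `alpha_T` is attenuated).}
#'   \item{`il10_knockout`}{all IL-10 production (`alpha_10`, `k_10T`,
#'     `k_106`) set to zero.}
#' }
#'
#' @param name Scenario name (see above; `-` and `_` are interchangeable).
#' @param params Base parameter set.
#' @param t_end,dt Passed to [simulate_cytokines()].
#' @return A `cytokine_trajectory` with a `scenario` attribute.
#' @examples
#' run_scenario("il10_bolus", t_end = 48, dt = 0.1)
#' @export
run_scenario <- function(name, params = cytokine_params(), t_end = 72,
                         dt = 0.01) {
  name <- gsub("-", "_", name)
  name <- match.arg(name, c("baseline", "il10_bolus", "tnf_inhibition",
                            "il10_knockout"))
  schedule <- intervention_schedule()
  if (name == "il10_bolus") {
    schedule <- intervention_schedule(boluses = bolus_event(24, "C_10", 0.05))
  } else if (name == "tnf_inhibition") {
    schedule <- intervention_schedule(
      modulations = param_modulation("alpha_T", 0.5, 0, t_end))
  } else if (name == "il10_knockout") {
    params <- update_params(params, alpha_10 = 0, k_10T = 0, k_106 = 0)
  }
  tr <- simulate_cytokines(params, t_end = t_end, dt = dt, schedule = schedule)
  attr(tr, "scenario") <- name
  tr
}

#' Summary statistics of a trajectory
#'
#' Per-species peak value and time (global maximum over grid nodes, earliest
#' node on ties) and final value, plus the TNF-alpha resolution time: the
#' earliest node from which `C_T` stays within a fractional band above its
#' final value for the rest of the run.
#'
#' @param trajectory A `cytokine_trajectory`.
#' @param resolution_fraction Band half-width as a fraction of the final
#'   TNF-alpha value (default 0.05).
#' @return A tibble with one row per species (`species`, `peak_value`,
#'   `peak_time`, `final_value`) and the resolution time attached both as the
#'   `resolution_time` attribute and via [glance()]; `NA` if the band is
#'   never entered before the end.
#' @export
summarize_trajectory <- function(trajectory, resolution_fraction = 0.05) {
  stopifnot(nrow(trajectory) > 0)
  long <- tidyr::pivot_longer(tibble::as_tibble(trajectory),
                              c("C_T", "C_6", "C_10"),
                              names_to = "species", values_to = "conc")
  summ <- long |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      peak_value = max(.data$conc),
      peak_time = .data$time[which.max(.data$conc)],
      final_value = .data$conc[dplyr::n()],
      .groups = "drop") |>
    dplyr::arrange(match(.data$species, c("C_T", "C_6", "C_10")))
  ct <- trajectory$C_T
  band <- (1 + resolution_fraction) * ct[length(ct)]
  ok <- rev(cumprod(rev(ct <= band))) == 1  # suffix-wise within band
  res_t <- if (any(ok)) trajectory$time[which(ok)[1]] else NA_real_
  structure(summ, resolution_time = res_t)
}

#' @method glance cytokine_trajectory
#' @export
glance.cytokine_trajectory <- function(x, ...) {
  s <- summarize_trajectory(x, ...)
  wide <- tidyr::pivot_wider(s, names_from = "species",
                             values_from = c("peak_value", "peak_time",
                                             "final_value"))
  dplyr::mutate(wide, resolution_time = attr(s, "resolution_time"),
                t_end = max(x$time), n_nodes = nrow(x))
}

#' Plot a cytokine trajectory
#'
#' @param object A `cytokine_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the three concentration time courses, with the IL-10
#'   delay marked.
#' @method autoplot cytokine_trajectory
#' @export
autoplot.cytokine_trajectory <- function(object, ...) {
  params <- attr(object, "params")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("C_T", "C_6", "C_10"),
                              names_to = "species", values_to = "conc")
  long$species <- factor(long$species, c("C_T", "C_6", "C_10"),
                         labels = c("TNF-α", "IL-6", "IL-10"))
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc,
                                           colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (hr)", y = "concentration (nM)", colour = NULL)
  if (!is.null(params)) {
    gg <- gg + ggplot2::geom_vline(xintercept = params$t_delay,
                                   linetype = "dashed", colour = "grey50")
  }
  gg
}

#' @export
plot.cytokine_trajectory <- function(x, ...) print(autoplot.cytokine_trajectory(x, ...))
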