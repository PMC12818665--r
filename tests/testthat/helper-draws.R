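# Random parameter draws used by property-style tests: log-uniform within
# the screened sensitivity ranges, all other fields at their defaults.
draw_params <- function(n, seed = 1) {
  ranges <- default_param_ranges()
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      vals <- exp(runif(nrow(ranges), log(ranges$low), log(ranges$high)))
      do.call(update_params,
              c(list(cytokine_params()), setNames(as.list(vals), ranges$name)))
    })
  })
}

# Fully random nonnegative states (concentrations up to ~2 nM).
draw_states <- function(n, seed = 1, t = 0) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      c(t = t, C_T = runif(1, 0, 2), C_6 = runif(1, 0, 2),
        C_10 = runif(1, 0, 2))
    })
  })
}

# Brute-force equilibrium oracle: dense sign-change scan of the scalar
# steady-state residual, independent of enumerate_equilibria's bisection.
brute_force_roots <- function(params, regime = "post_delay", n = 1e6,
                              C10_max = NULL) {
  if (is.null(C10_max)) {
    C10_max <- attr(enumerate_equilibria(params, regime = regime,
                                         scan_points = 101), "C10_max")
  }
  grid <- seq(0, C10_max, length.out = n)
  f <- cytotriad:::equilibrium_residual(params, grid, regime)
  ok <- is.finite(f)
  ch <- which(ok[-length(ok)] & ok[-1] & f[-length(f)] * f[-1] < 0)
  # polish each bracket with stats::uniroot, independent of the package's
  # own bisection loop
  refined <- vapply(ch, function(i) {
    stats::uniroot(function(x) cytotriad:::equilibrium_residual(params, x, regime),
                   lower = grid[i], upper = grid[i + 1], tol = 1e-12)$root
  }, numeric(1))
  sort(c(grid[which(ok & f == 0)], refined))
}
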