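#' Intervention events
#'
#' `bolus_event()` describes an instantaneous addition of a species (e.g. a
#' 0.05 nM IL-10 bolus at 24 hr); `param_modulation()` a multiplicative
#' scaling of one model parameter over a time window (e.g. halving basal
#' TNF-alpha production to mimic sustained anti-TNF blockade);
#' `intervention_schedule()` bundles any number of each.
#'
#' @param time Bolus time (hr, >= 0).
#' @param species One of `"C_T"`, `"C_6"`, `"C_10"`.
#' @param amount Added amount (nM, >= 0).
#' @return `bolus_event()` / `param_modulation()` return one-row tibbles;
#'   `intervention_schedule()` returns an `intervention_schedule` object.
#' @examples
#' intervention_schedule(boluses = bolus_event(24, "C_10", 0.05))
#' @export
bolus_event <- function(time, species, amount) {
  species <- match.arg(species, c("C_T", "C_6", "C_10"))
  stopifnot(is.finite(time), time >= 0, is.finite(amount), amount >= 0)
  tibble::tibble(time = time, species = species, amount = amount)
}

#' @rdname bolus_event
#' @param parameter A [cytokine_params()] field name.
#' @param factor Multiplicative factor (>= 0) applied while active.
#' @param start,end Activity window (hr), `0 <= start < end`.
#' @export
param_modulation <- function(parameter, factor, start, end) {
  if (!parameter %in% param_names()) {
    abort(paste0("unknown parameter: ", parameter))
  }
  stopifnot(is.finite(factor), factor >= 0,
            is.finite(start), is.finite(end), start >= 0, start < end)
  tibble::tibble(parameter = parameter, factor = factor,
                 start = start, end = end)
}

#' @rdname bolus_event
#' @param boluses A tibble of bolus events (rows from [bolus_event()]),
#'   or `NULL`.
#' @param modulations A tibble of parameter modulations (rows from
#'   [param_modulation()]), or `NULL`.
#' @export
intervention_schedule <- function(boluses = NULL, modulations = NULL) {
  empty_b <- tibble::tibble(time = numeric(), species = character(),
                            amount = numeric())
  empty_m <- tibble::tibble(parameter = character(), factor = numeric(),
                            start = numeric(), end = numeric())
  b <- if (is.null(boluses)) empty_b else tibble::as_tibble(boluses)
  m <- if (is.null(modulations)) empty_m else tibble::as_tibble(modulations)
  stopifnot(all(c("time", "species", "amount") %in% names(b)),
            all(c("parameter", "factor", "start", "end") %in% names(m)))
  if (nrow(b) > 0 && !all(is.finite(b$time))) abort("bolus times must be finite")
  if (nrow(m) > 0 && !all(is.finite(m$start) & is.finite(m$end))) {
    abort("modulation windows must be finite")
  }
  structure(list(boluses = b, modulations = m),
            class = "intervention_schedule")
}

#' @export
print.intervention_schedule <- function(x, ...) {
  cat("<intervention_schedule>", nrow(x$boluses), "bolus(es),",
      nrow(x$modulations), "modulation(s)\n")
  if (nrow(x$boluses) > 0) print(x$boluses)
  if (nrow(x$modulations) > 0) print(x$modulations)
  invisible(x)
}

# Parameter set with all modulations active on [t0, t1) applied
# multiplicatively; segment boundaries are grid breakpoints, so activity
# is decided by the segment's left endpoint.
effective_params <- function(params, schedule, t0) {
  m <- schedule$modulations
  if (nrow(m) == 0) return(params)
  act <- m$start <= t0 & t0 < m$end
  if (!any(act)) return(params)
  q <- unclass(params)
  for (i in which(act)) {
    q[[m$parameter[i]]] <- q[[m$parameter[i]]] * m$factor[i]
  }
  validate_params(structure(q, class = "cytokine_params"))
}
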