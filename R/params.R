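#' Model parameter set
#'
#' Constructs the full parameter set of the three-cytokine network model.
#' Defaults are the literature-calibrated values for acute post-stroke
#' inflammation; units are nanomolar (nM) for concentrations and hours (hr)
#' for time throughout.
#'
#' The model tracks TNF-alpha (`C_T`), IL-6 (`C_6`) and IL-10 (`C_10`):
#' \deqn{dC_T/dt = \alpha_T + k_{T6} C_6 - \beta_T C_T - \gamma_{T10} C_{10} C_T}
#' \deqn{dC_6/dt = \alpha_6 + k_{6T} C_T - \beta_6 C_6 - \gamma_{610} C_{10} C_6}
#' \deqn{dC_{10}/dt = \alpha_{10} + (k_{10T} C_T + k_{106} C_6)\, h(C_T - C_6)\,
#'       H(t - t_d) - \beta_{10} C_{10}}
#' where \eqn{h(d) = d^n / (K^n + d^n)} (with the pro-inflammatory excess
#' clamped at zero, \eqn{d = \max(C_T - C_6, 0)}) gates IL-10 induction
#' cooperatively, and the Heaviside step \eqn{H(t - t_d)} delays it until
#' \eqn{t_d} hours post-insult.
#'
#' @param alpha_T Basal TNF-alpha production (nM/hr).
#' @param alpha_6 Basal IL-6 production (nM/hr).
#' @param alpha_10 Basal IL-10 production (nM/hr).
#' @param k_T6 IL-6 -> TNF-alpha cross-activation rate (1/(nM hr)).
#' @param k_6T TNF-alpha -> IL-6 cross-activation rate (1/(nM hr)).
#' @param k_10T TNF-alpha-induced IL-10 production rate (1/(nM hr)).
#' @param k_106 IL-6-induced IL-10 production rate (1/(nM hr)).
#' @param gamma_T10 IL-10 suppression of TNF-alpha (1/(nM hr)).
#' @param gamma_610 IL-10 suppression of IL-6 (1/(nM hr)).
#' @param beta_T TNF-alpha first-order decay rate (1/hr).
#' @param beta_6 IL-6 first-order decay rate (1/hr).
#' @param beta_10 IL-10 first-order decay rate (1/hr).
#' @param hill_n Hill cooperativity of IL-10 induction (dimensionless,
#'   real-valued and at least 1 so sensitivity analysis can sample it
#'   continuously).
#' @param hill_K Half-maximal pro-inflammatory excess for IL-10 induction (nM).
#' @param t_delay Transcriptional delay before IL-10 induction switches on (hr).
#'
#' @return A validated object of class `cytokine_params` (a named list).
#' @examples
#' p <- cytokine_params()
#' p$gamma_T10
#' cytokine_params(gamma_T10 = 0.06)
#' @export
cytokine_params <- function(alpha_T = 0.02, alpha_6 = 0.01, alpha_10 = 0.005,
                            k_T6 = 0.45, k_6T = 0.40,
                            k_10T = 0.15, k_106 = 0.12,
                            gamma_T10 = 0.10, gamma_610 = 0.06,
                            beta_T = 1.8, beta_6 = 1.2, beta_10 = 0.35,
                            hill_n = 5, hill_K = 0.3, t_delay = 18) {
  p <- structure(
    list(alpha_T = alpha_T, alpha_6 = alpha_6, alpha_10 = alpha_10,
         k_T6 = k_T6, k_6T = k_6T, k_10T = k_10T, k_106 = k_106,
         gamma_T10 = gamma_T10, gamma_610 = gamma_610,
         beta_T = beta_T, beta_6 = beta_6, beta_10 = beta_10,
         hill_n = hill_n, hill_K = hill_K, t_delay = t_delay),
    class = "cytokine_params")
  validate_params(p)
}

#' Field names of a cytokine parameter set
#' @return Character vector of the 15 parameter names.
#' @export
param_names <- function() {
  c("alpha_T", "alpha_6", "alpha_10", "k_T6", "k_6T", "k_10T", "k_106",
    "gamma_T10", "gamma_610", "beta_T", "beta_6", "beta_10",
    "hill_n", "hill_K", "t_delay")
}

#' Validate a cytokine parameter set
#'
#' Checks every invariant of the parameter set: all fields finite numeric
#' scalars, rates and productions nonnegative, decay rates strictly positive,
#' `hill_K > 0`, `hill_n >= 1`, `t_delay >= 0`.  The error message names the
#' first violated field.
#'
#' @param p A `cytokine_params` object or a named list with the same fields.
#' @return `p`, invisibly unchanged, as a `cytokine_params` object.
#' @export
validate_params <- function(p) {
  nms <- param_names()
  extra <- setdiff(names(p), nms)
  if (length(extra) > 0) {
    abort(paste0("unknown parameter field(s): ", paste(extra, collapse = ", ")))
  }
  missing <- setdiff(nms, names(p))
  if (length(missing) > 0) {
    abort(paste0("missing parameter field(s): ", paste(missing, collapse = ", ")))
  }
  for (nm in nms) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(paste0(nm, " must be a finite numeric scalar"))
    }
  }
  for (nm in c("beta_T", "beta_6", "beta_10", "hill_K")) {
    if (p[[nm]] <= 0) abort(paste0(nm, " must be > 0"))
  }
  for (nm in c("alpha_T", "alpha_6", "alpha_10", "k_T6", "k_6T", "k_10T",
               "k_106", "gamma_T10", "gamma_610", "t_delay")) {
    if (p[[nm]] < 0) abort(paste0(nm, " must be >= 0"))
  }
  if (p$hill_n < 1) abort("hill_n must be >= 1")
  p <- structure(p[nms], class = "cytokine_params")
  invisible(p)
}

#' @export
print.cytokine_params <- function(x, ...) {
  cat("<cytokine_params>\n")
  df <- tibble::tibble(parameter = names(unclass(x)),
                       value = unlist(unclass(x), use.names = FALSE))
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' @export
as.list.cytokine_params <- function(x, ...) unclass(x)

#' Coerce a parameter set to a one-column-per-parameter tibble
#' @param x A `cytokine_params` object.
#' @param ... Unused.
#' @return A two-column tibble (`parameter`, `value`).
#' @method tidy cytokine_params
#' @export
tidy.cytokine_params <- function(x, ...) {
  tibble::tibble(parameter = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

#' Modify fields of a parameter set
#'
#' @param p A `cytokine_params` object.
#' @param ... Named fields to replace (unknown names are an error).
#' @return A validated `cytokine_params`.
#' @examples
#' update_params(cytokine_params(), gamma_T10 = 0.05)
#' @export
update_params <- function(p, ...) {
  upd <- list(...)
  extra <- setdiff(names(upd), param_names())
  if (length(extra) > 0) {
    abort(paste0("unknown parameter field(s): ", paste(extra, collapse = ", ")))
  }
  q <- unclass(p)
  q[names(upd)] <- upd
  validate_params(structure(q, class = "cytokine_params"))
}

#' Write / read a parameter set as a flat YAML or JSON mapping
#'
#' Serialization uses exactly the field names of [cytokine_params()]; unknown
#' keys on read are an error, guarding against silent typos such as
#' `"gamma_t10"`.
#'
#' @param p A `cytokine_params` object.
#' @param path File path; the format is chosen by extension (`.json` writes
#'   JSON, anything else YAML).
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a validated `cytokine_params`.
#' @export
write_params <- function(p, path) {
  vals <- lapply(unclass(p), as.numeric)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(vals)
}

# Build a parameter set from a partial named list, erroring on unknown keys.
params_from_list <- function(vals) {
  vals <- as.list(vals)
  extra <- setdiff(names(vals), param_names())
  if (length(extra) > 0) {
    abort(paste0("unknown parameter field(s): ", paste(extra, collapse = ", ")))
  }
  do.call(cytokine_params, vals)
}
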