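#' Load a run configuration
#'
#' Reads a YAML or JSON run configuration.  Recognised top-level keys:
#' `parameters` (partial mapping of [cytokine_params()] fields),
#' `initial_state` (mapping with `C_T`, `C_6`, `C_10`), `t_end`, `dt`,
#' `seed`, `schedule` (`boluses:` list of `{time, species, amount}`,
#' `modulations:` list of `{parameter, factor, start, end}`), `sweep`
#' (`parameter`, `from`, `to`, `points`) and `sensitivity` (`qoi`,
#' `n_base`, `n_bootstrap`).  Unknown keys at the top level, in
#' `parameters` and in `initial_state` are rejected (guarding against
#' silent typos); omitted fields take the model defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` object: list with validated `params`, `init`,
#'   `t_end`, `dt`, `seed`, `schedule`, `sweep`, `sensitivity`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

config_from_list <- function(raw) {
  known <- c("parameters", "initial_state", "t_end", "dt", "seed",
             "schedule", "sweep", "sensitivity")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  params <- params_from_list(raw$parameters %||% list())
  init_raw <- raw$initial_state %||% list()
  extra_i <- setdiff(names(init_raw), c("C_T", "C_6", "C_10"))
  if (length(extra_i) > 0) {
    abort(paste0("unknown initial_state key(s): ", paste(extra_i, collapse = ", ")))
  }
  init <- do.call(cytokine_state, c(list(t = 0), init_raw))
  t_end <- raw$t_end %||% 72
  dt <- raw$dt %||% 0.01
  if (!is.numeric(t_end) || t_end <= 0) abort("t_end must be > 0")
  if (!is.numeric(dt) || dt <= 0) abort("dt must be > 0")

  sched_raw <- raw$schedule %||% list()
  extra_s <- setdiff(names(sched_raw), c("boluses", "modulations"))
  if (length(extra_s) > 0) {
    abort(paste0("unknown schedule key(s): ", paste(extra_s, collapse = ", ")))
  }
  as_rows <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) return(tibble::as_tibble(x))
    dplyr::bind_rows(lapply(x, tibble::as_tibble))
  }
  b <- as_rows(sched_raw$boluses)
  m <- as_rows(sched_raw$modulations)
  if (!is.null(b) && nrow(b) > 0) {
    b <- dplyr::bind_rows(purrr::pmap(b, bolus_event))
  }
  if (!is.null(m) && nrow(m) > 0) {
    m <- dplyr::bind_rows(purrr::pmap(m, param_modulation))
  }
  schedule <- intervention_schedule(boluses = b, modulations = m)

  structure(list(params = params, init = init, t_end = t_end, dt = dt,
                 seed = raw$seed %||% 1L, schedule = schedule,
                 sweep = raw$sweep, sensitivity = raw$sensitivity),
            class = "run_config")
}

#' Write a run configuration
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config A `run_config`.
#' @param path Output path (`.json` writes JSON, anything else YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- list(
    parameters = lapply(unclass(config$params), as.numeric),
    initial_state = as.list(config$init[1, c("C_T", "C_6", "C_10")]),
    t_end = config$t_end, dt = config$dt, seed = config$seed)
  sch <- config$schedule
  if (nrow(sch$boluses) > 0 || nrow(sch$modulations) > 0) {
    lst$schedule <- list()
    if (nrow(sch$boluses) > 0) {
      lst$schedule$boluses <- purrr::transpose(as.list(sch$boluses))
    }
    if (nrow(sch$modulations) > 0) {
      lst$schedule$modulations <- purrr::transpose(as.list(sch$modulations))
    }
  }
  if (!is.null(config$sweep)) lst$sweep <- config$sweep
  if (!is.null(config$sensitivity)) lst$sensitivity <- config$sensitivity
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

# JSON run manifest written alongside every CSV output.
write_manifest <- function(path, params, seed = NULL, extra = list()) {
  manifest <- c(list(
    package = "cytotriad",
    version = as.character(utils::packageVersion("cytotriad")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = lapply(unclass(params), as.numeric),
    seed = seed), extra)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write analysis results to CSV (with a JSON run manifest)
#'
#' Dispatches on the result type and writes an RFC-4180 CSV with a fixed,
#' documented schema, plus a `<path>.manifest.json` sidecar recording the
#' package version, effective parameter set and seed:
#' \itemize{
#'   \item trajectory: `time_hr,TNF_nM,IL6_nM,IL10_nM`
#'   \item equilibria: `regime,C10_root_nM,CT_nM,C6_nM,residual,stability,`
#'     `lambda1_re,lambda2_re,lambda3_re,lambda1_im,lambda2_im,lambda3_im`
#'   \item bifurcation diagram: `<parameter>,branch_index,CT_nM,C6_nM,`
#'     `IL10 column,stability`
#'   \item hysteresis: `<parameter>,direction,CT_nM,C6_nM,C10_nM`
#'   \item sensitivity: `parameter,S1,ST,S1_ci,ST_ci` (+ JSON sidecar with
#'     qoi, n_base, seed and ranges)
#' }
#' Numeric round-trip through [read.csv()] is exact to better than 1e-12
#' (values are written with full precision).
#'
#' @param x A result object from this package.
#' @param path Output CSV path.
#' @param seed Optional seed to record in the manifest.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path, seed = NULL) UseMethod("write_outputs")

write_csv_plain <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @export
write_outputs.cytokine_trajectory <- function(x, path, seed = NULL) {
  df <- tibble::tibble(time_hr = x$time, TNF_nM = x$C_T, IL6_nM = x$C_6,
                       IL10_nM = x$C_10)
  write_csv_plain(df, path)
  write_manifest(path, attr(x, "params"), seed,
                 extra = list(kind = "trajectory",
                              scenario = attr(x, "scenario")))
  invisible(path)
}

#' @export
write_outputs.equilibria_tbl <- function(x, path, seed = NULL) {
  df <- tibble::tibble(
    regime = x$regime, C10_root_nM = x$C_10, CT_nM = x$C_T, C6_nM = x$C_6,
    residual = x$residual_norm, stability = x$stability,
    lambda1_re = Re(x$lambda1), lambda2_re = Re(x$lambda2),
    lambda3_re = Re(x$lambda3),
    lambda1_im = Im(x$lambda1), lambda2_im = Im(x$lambda2),
    lambda3_im = Im(x$lambda3))
  write_csv_plain(df, path)
  write_manifest(path, attr(x, "params"), seed, extra = list(kind = "equilibria"))
  invisible(path)
}

#' @export
write_outputs.bifurcation_diagram <- function(x, path, seed = NULL) {
  df <- tibble::tibble(x$param_value, branch_index = x$branch_index,
                       CT_nM = x$C_T, C6_nM = x$C_6, C10_nM = x$C_10,
                       stability = x$stability)
  names(df)[1] <- attr(x, "parameter")
  write_csv_plain(df, path)
  write_manifest(path, attr(x, "params"), seed,
                 extra = list(kind = "bifurcation_diagram",
                              parameter = attr(x, "parameter"),
                              fold_locations = attr(x, "fold_locations")))
  invisible(path)
}

#' @export
write_outputs.hysteresis_result <- function(x, path, seed = NULL) {
  df <- tibble::tibble(x$param_value, direction = x$direction,
                       CT_nM = x$C_T, C6_nM = x$C_6, C10_nM = x$C_10)
  names(df)[1] <- attr(x, "parameter")
  write_csv_plain(df, path)
  write_manifest(path, attr(x, "params"), seed,
                 extra = list(kind = "hysteresis",
                              parameter = attr(x, "parameter"),
                              max_gap = attr(x, "max_gap")))
  invisible(path)
}

#' @export
write_outputs.sensitivity_result <- function(x, path, seed = NULL) {
  df <- tibble::tibble(parameter = x$parameter, S1 = x$first_order,
                       ST = x$total_order, S1_ci = x$first_order_ci,
                       ST_ci = x$total_order_ci)
  write_csv_plain(df, path)
  sidecar <- list(kind = "sensitivity", qoi_name = attr(x, "qoi_name"),
                  n_base = attr(x, "n_base"), seed = attr(x, "seed"),
                  ranges = attr(x, "ranges"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_manifest(path, attr(x, "params") %||% cytokine_params(),
                 seed %||% attr(x, "seed"),
                 extra = list(kind = "sensitivity"))
  invisible(path)
}

#' Read a trajectory CSV written by [write_outputs()]
#' @param path CSV path.
#' @return A tibble with columns `time`, `C_T`, `C_6`, `C_10`.
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(identical(names(df), c("time_hr", "TNF_nM", "IL6_nM", "IL10_nM")))
  tibble::tibble(time = df$time_hr, C_T = df$TNF_nM, C_6 = df$IL6_nM,
                 C_10 = df$IL10_nM)
}
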