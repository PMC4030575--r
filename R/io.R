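## Parameter files and result serialization. JSON is the canonical config
## dialect; YAML is accepted. Keys are the field names of the constructor
## functions; all values in M, s^-1 or M^-1 s^-1 — no unit conversion is
## ever performed inside computations.

#' Load a rate-parameter set from a config file
#'
#' Reads a JSON (canonical) or YAML parameter file with blocks `micro_apo`,
#' `substrate`, `hydrolysis`, `pool` and optional `micro_bound`, each
#' holding the keys of the corresponding constructor
#' ([exchange_rates()], [substrate_kinetics()], [hydrolysis_rates()],
#' [nucleotide_pool()]). The bundled fixture reproduces the DnaK/DnaJ set:
#' `load_parameters(hsp70cycle_example("dnak_table1.json"))`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return An `hsp70_rates` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop_invalid("parameter file not found: ", path)
  cfg <- switch(tolower(tools::file_ext(path)),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop_invalid("unsupported parameter file extension '",
                             tools::file_ext(path),
                             "' (use .json, .yaml or .yml): ", path))
  rates_from_config(cfg, path)
}

rates_from_config <- function(cfg, path = "<config>") {
  need <- function(block, keys) {
    if (is.null(cfg[[block]])) {
      stop_invalid("missing block '", block, "' in ", path)
    }
    missing_keys <- setdiff(keys, names(cfg[[block]]))
    if (length(missing_keys)) {
      stop_invalid("missing key(s) ", paste0("'", block, ".", missing_keys,
                                             "'", collapse = ", "),
                   " in ", path)
    }
    lapply(setNames(keys, keys), function(k) {
      v <- cfg[[block]][[k]]
      if (!is.numeric(v) || length(v) != 1L) {
        stop_invalid("key '", block, ".", k, "' in ", path,
                     " must be a single number")
      }
      v
    })
  }
  ex_keys <- c("k_ATP_minus", "k_ATP_plus", "k_ADP_minus", "k_ADP_plus")
  apo <- need("micro_apo", ex_keys)
  sk <- need("substrate", c("k_on_ATP", "k_off_ATP", "k_on_ADP", "k_off_ADP"))
  hyd_keys <- c("k_h", "k_h_S")
  hyd <- need("hydrolysis", hyd_keys)
  k_synth <- cfg$hydrolysis$k_synth %||% 0
  pool <- need("pool", c("ATP", "ADP"))
  micro_apo <- do.call(exchange_rates, apo)
  micro_bound <- if (!is.null(cfg$micro_bound)) {
    do.call(exchange_rates, need("micro_bound", ex_keys))
  } else micro_apo
  tryCatch(
    hsp70_rates(
      substrate = do.call(substrate_kinetics, sk),
      hydrolysis = hydrolysis_rates(hyd$k_h, hyd$k_h_S, k_synth = k_synth),
      micro_apo = micro_apo, micro_bound = micro_bound,
      pool = nucleotide_pool(pool$ATP, pool$ADP)
    ),
    hsp70_invalid_parameter = function(e) {
      stop_invalid(conditionMessage(e), " (while loading ", path, ")")
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a rate-parameter set to a config file
#'
#' Writes JSON or YAML (by extension) that [load_parameters()] reads back
#' into an identical object.
#'
#' @param rates an `hsp70_rates` object.
#' @param path output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(rates, path) {
  stopifnot(inherits(rates, "hsp70_rates"))
  cfg <- list(
    micro_apo = unclass(rates$micro_apo),
    micro_bound = unclass(rates$micro_bound),
    substrate = unclass(rates$substrate),
    hydrolysis = unclass(rates$hydrolysis),
    pool = unclass(rates$pool)
  )
  switch(tolower(tools::file_ext(path)),
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         yaml = ,
         yml = yaml::write_yaml(cfg, path),
         stop_invalid("unsupported parameter file extension: ", path))
  invisible(path)
}

#' Path to a bundled example file
#'
#' @param file file name under the package's `extdata`; when missing,
#'   lists the available files.
#' @return Full path, or a character vector of available files.
#' @export
hsp70cycle_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "hsp70cycle"))
  } else {
    path <- system.file("extdata", file, package = "hsp70cycle",
                        mustWork = FALSE)
    if (!nzchar(path)) stop_invalid("no bundled file named '", file, "'")
    path
  }
}

#' Write a steady state to JSON
#'
#' Serializes the state concentrations and derived observables, with the
#' full generating parameters as provenance.
#'
#' @param state an `hsp70_steady_state` object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_steady_state <- function(state, path) {
  stopifnot(inherits(state, "hsp70_steady_state"))
  out <- list(
    states = as.list(state$conc),
    S_free_M = state$S_free,
    observables = list(K_eff_M = state$K_eff, P_diss_M_per_s = state$P_diss),
    composition = unclass(state$composition),
    parameters = list(
      micro_apo = unclass(state$rates$micro_apo),
      micro_bound = unclass(state$rates$micro_bound),
      substrate = unclass(state$rates$substrate),
      hydrolysis = unclass(state$rates$hydrolysis),
      pool = unclass(state$rates$pool)
    ),
    package_version = as.character(packageVersion("hsp70cycle"))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a sweep to CSV with a JSON provenance sidecar
#'
#' The CSV holds the long-format grid and observables; a `<path>.meta.json`
#' sidecar records the base parameters, composition, grids and package
#' version, sufficient to reproduce the sweep exactly.
#'
#' @param sweep an `hsp70_sweep` object.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "hsp70_sweep"))
  write.csv(as.data.frame(sweep), path, row.names = FALSE)
  rates <- attr(sweep, "rates")
  meta <- list(
    parameters = list(
      micro_apo = unclass(rates$micro_apo),
      micro_bound = unclass(rates$micro_bound),
      substrate = unclass(rates$substrate),
      hydrolysis = unclass(rates$hydrolysis),
      pool = unclass(rates$pool)
    ),
    composition = unclass(attr(sweep, "composition")),
    grids = attr(sweep, "grids"),
    physiological_accel = attr(sweep, "physiological_accel"),
    package_version = attr(sweep, "package_version")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a stochastic trajectory to CSV
#'
#' Columns: `time`, copy numbers of the four chaperone states and free
#' substrate, and the cumulative hydrolysis-event count.
#'
#' @param traj an `hsp70_trajectory` object.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hsp70_trajectory"))
  df <- data.frame(time = traj$times, traj$counts,
                   hydrolysis_count = traj$hydrolysis_cum)
  names(df) <- c("time", "T", "D", "TS", "DS", "S_free", "hydrolysis_count")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
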