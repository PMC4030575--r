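## Parameter-scan engines: hydrolysis acceleration, binding-timescale
## separation, substrate stoichiometry.

#' Log-spaced grid
#'
#' @param from,to positive endpoints.
#' @param n number of points.
#' @return Strictly increasing numeric vector of length `n`, log-spaced.
#' @export
log_grid <- function(from, to, n = 61) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

#' Classify a dissociation constant against the equilibrium band
#'
#' At equilibrium the effective dissociation constant is confined to
#' `[KD(ADP), KD(ATP)]`; values below that band are reachable only by
#' breaking detailed balance (ultra-affinity).
#'
#' @param K_eff dissociation constant(s) (M).
#' @param sk a [substrate_kinetics()] object or an `hsp70_rates` object.
#' @return Logical vector: is `K_eff` inside the equilibrium band?
#' @export
in_equilibrium_band <- function(K_eff, sk) {
  if (inherits(sk, "hsp70_rates")) sk <- sk$substrate
  kd <- dissociation_constants(sk)
  K_eff >= min(kd) & K_eff <= max(kd)
}

## physiological range of JDP-driven hydrolysis acceleration annotated on
## every sweep
PHYSIOLOGICAL_ACCEL <- c(1e3, 1e4)

new_sweep <- function(df, rates, comp, grids) {
  structure(df,
            class = c("hsp70_sweep", "data.frame"),
            rates = rates, composition = comp, grids = grids,
            physiological_accel = PHYSIOLOGICAL_ACCEL,
            package_version = as.character(packageVersion("hsp70cycle")))
}

sweep_point <- function(rates, comp, idx = NULL) {
  st <- tryCatch(solve_steady_state(rates, comp), error = function(e) {
    stop("sweep failed at grid point ", paste(idx, collapse = ", "),
         ": ", conditionMessage(e))
  })
  c(K_eff_M = st$K_eff,
    K_eff0_M = keff_zero_order(rates),
    P_diss_M_per_s = st$P_diss,
    S_free_M = st$S_free)
}

#' Sweep the hydrolysis acceleration ratio
#'
#' For each acceleration ratio `r` sets `k_h_S = r * k_h`, re-derives the
#' closure-dependent effective rates, solves the steady state and records
#' the effective dissociation constant, its zero-order approximation and
#' the hydrolysis flux. Along the grid the dissociation constant is
#' non-increasing while the flux grows and saturates once the rate-limiting
#' exchange step dominates.
#'
#' @param rates base `hsp70_rates` object.
#' @param comp a [system_composition()] object.
#' @param accel acceleration grid (`k_h_S / k_h`), strictly increasing;
#'   values below 1 (deceleration) require `allow_deceleration = TRUE`.
#' @param allow_deceleration permit ratios below 1.
#' @return An `hsp70_sweep` data frame with one row per grid point and
#'   columns `accel`, `K_eff_M`, `K_eff0_M`, `P_diss_M_per_s`, `S_free_M`,
#'   `in_equilibrium_band`. Base parameters, composition and grids are
#'   attached as attributes, sufficient to reproduce the sweep exactly.
#' @examples
#' sw <- sweep_hydrolysis_acceleration(dnak_rates(),
#'                                     system_composition(40e-6, 4e-6),
#'                                     accel = log_grid(1, 1e7, 15))
#' @export
sweep_hydrolysis_acceleration <- function(rates, comp,
                                          accel = log_grid(1, 1e7, 61),
                                          allow_deceleration = FALSE) {
  stopifnot(inherits(rates, "hsp70_rates"), inherits(comp, "hsp70_composition"))
  check_grid(accel, "accel")
  if (!allow_deceleration && any(accel < 1)) {
    stop_invalid("acceleration ratios below 1 mean k_h_S < k_h; ",
                 "set allow_deceleration = TRUE if intended")
  }
  rows <- vapply(seq_along(accel), function(i) {
    sweep_point(set_acceleration(rates, accel[i]), comp, idx = i)
  }, numeric(4))
  df <- data.frame(accel = accel, t(rows))
  df$in_equilibrium_band <- in_equilibrium_band(df$K_eff_M, rates)
  new_sweep(df, rates, comp, list(accel = accel))
}

#' Sweep binding-timescale separation and hydrolysis acceleration
#'
#' Varies the ratio `k_off_ADP / k_off_ATP`, which measures the separation
#' between the substrate-exchange timescales of the two nucleotide states,
#' while holding `KD(ADP)` fixed by co-scaling `k_on_ADP`. Ultra-affinity
#' requires the ADP state to be the slow one (`off_ratio < 1`); for
#' `off_ratio >= 1` the dissociation constant stays inside the equilibrium
#' band for every acceleration.
#'
#' @inheritParams sweep_hydrolysis_acceleration
#' @param off_ratio grid of `k_off_ADP / k_off_ATP` values (> 0).
#' @return An `hsp70_sweep` data frame in long format with columns
#'   `off_ratio`, `accel`, and the observables of
#'   [sweep_hydrolysis_acceleration()].
#' @export
sweep_timescale_separation <- function(rates, comp, off_ratio,
                                       accel = log_grid(1, 1e7, 61)) {
  stopifnot(inherits(rates, "hsp70_rates"), inherits(comp, "hsp70_composition"))
  check_grid(off_ratio, "off_ratio", positive = TRUE)
  check_grid(accel, "accel")
  kd <- dissociation_constants(rates$substrate)
  out <- lapply(seq_along(off_ratio), function(i) {
    r <- rates
    r$substrate$k_off_ADP <- off_ratio[i] * rates$substrate$k_off_ATP
    r$substrate$k_on_ADP <- r$substrate$k_off_ADP / kd[["KD_ADP"]]
    rows <- vapply(seq_along(accel), function(j) {
      sweep_point(set_acceleration(r, accel[j]), comp, idx = c(i, j))
    }, numeric(4))
    data.frame(off_ratio = off_ratio[i], accel = accel, t(rows),
               in_equilibrium_band = in_equilibrium_band(t(rows)[, "K_eff_M"],
                                                         r$substrate))
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  new_sweep(df, rates, comp, list(off_ratio = off_ratio, accel = accel))
}

#' Sweep substrate stoichiometry and hydrolysis acceleration
#'
#' Varies the stoichiometric ratio `S_tot / Hsp70_tot` at fixed total
#' chaperone concentration. Ultra-affinity is a chaperone-excess
#' phenomenon: the gain in affinity collapses sharply as the ratio crosses
#' 1, because in substrate excess binding to the ADP state dominates and
#' the cycle can no longer exploit the timescale separation.
#'
#' @inheritParams sweep_hydrolysis_acceleration
#' @param Hsp70_tot total chaperone concentration (M).
#' @param stoich grid of `S_tot / Hsp70_tot` ratios (> 0).
#' @return An `hsp70_sweep` data frame in long format with columns
#'   `stoich`, `accel`, and the standard observables.
#' @export
sweep_stoichiometry <- function(rates, Hsp70_tot = 40e-6, stoich,
                                accel = log_grid(1, 1e7, 61)) {
  stopifnot(inherits(rates, "hsp70_rates"))
  Hsp70_tot <- check_rate(Hsp70_tot, "Hsp70_tot", positive = TRUE)
  check_grid(stoich, "stoich", positive = TRUE)
  check_grid(accel, "accel")
  out <- lapply(seq_along(stoich), function(i) {
    comp <- system_composition(Hsp70_tot, stoich[i] * Hsp70_tot)
    rows <- vapply(seq_along(accel), function(j) {
      sweep_point(set_acceleration(rates, accel[j]), comp, idx = c(i, j))
    }, numeric(4))
    data.frame(stoich = stoich[i], accel = accel, t(rows),
               in_equilibrium_band = in_equilibrium_band(t(rows)[, "K_eff_M"],
                                                         rates))
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  new_sweep(df, rates, system_composition(Hsp70_tot, stoich[1] * Hsp70_tot),
            list(stoich = stoich, accel = accel))
}

check_grid <- function(g, name, positive = FALSE) {
  if (!is.numeric(g) || length(g) < 1L || anyNA(g)) {
    stop_invalid("'", name, "' must be a numeric grid without NA")
  }
  if (positive && any(g <= 0)) stop_invalid("'", name, "' must be > 0")
  if (is.unsorted(g, strictly = TRUE)) {
    stop_invalid("'", name, "' grid must be strictly increasing")
  }
  invisible(g)
}

#' Asymptotic lower bound of the dissociation constant
#'
#' In the limit of extreme hydrolysis acceleration the substrate binds
#' exclusively to the ATP state (fastest binding) and unbinds exclusively
#' from the ADP state (slowest unbinding), so
#' \deqn{K_{eff}^{neq} \to k_{off}^{ADP} / k_{on}^{ATP}.}
#'
#' @param sk a [substrate_kinetics()] object or an `hsp70_rates` object.
#' @return Lower bound (M).
#' @examples
#' keff_lower_bound(dnak_rates())   # ~1.04e-9 M
#' @export
keff_lower_bound <- function(sk) {
  if (inherits(sk, "hsp70_rates")) sk <- sk$substrate
  stopifnot(inherits(sk, "hsp70_substrate_kinetics"))
  if (sk$k_on_ATP <= 0) stop_invalid("k_on_ATP must be > 0")
  sk$k_off_ADP / sk$k_on_ATP
}

#' @export
print.hsp70_sweep <- function(x, ...) {
  grids <- attr(x, "grids")
  cat("Hsp70 cycle parameter sweep (", nrow(x), " points; axes: ",
      paste(names(grids), collapse = ", "), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}
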