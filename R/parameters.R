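#' @useDynLib hsp70cycle, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd quantile setNames uniroot nls coef fitted resid predict
#' @importFrom utils write.csv read.csv packageVersion modifyList
NULL

## ---- validation helpers ------------------------------------------------

stop_invalid <- function(...) {
  stop(structure(
    class = c("hsp70_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

check_rate <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("'", name, "' must be a single finite number")
  }
  if (positive && x <= 0) stop_invalid("'", name, "' must be > 0 (got ", x, ")")
  if (!positive && x < 0) stop_invalid("'", name, "' must be >= 0 (got ", x, ")")
  as.numeric(x)
}

## ---- constructors ------------------------------------------------------

#' Microscopic nucleotide exchange rates
#'
#' Rate constants for the two-step exchange process in which the chaperone
#' releases its bound nucleotide, transiently visits the apo state, and binds
#' ATP or ADP from the chemostatted pool.
#'
#' @param k_ATP_minus ATP release rate (s^-1).
#' @param k_ATP_plus ATP binding rate (M^-1 s^-1).
#' @param k_ADP_minus ADP release rate (s^-1).
#' @param k_ADP_plus ADP binding rate (M^-1 s^-1).
#' @return An object of class `hsp70_exchange_rates`.
#' @examples
#' exchange_rates(1.33e-4, 1.3e5, 0.022, 2.67e5)
#' @export
exchange_rates <- function(k_ATP_minus, k_ATP_plus, k_ADP_minus, k_ADP_plus) {
  out <- list(
    k_ATP_minus = check_rate(k_ATP_minus, "k_ATP_minus"),
    k_ATP_plus  = check_rate(k_ATP_plus, "k_ATP_plus", positive = TRUE),
    k_ADP_minus = check_rate(k_ADP_minus, "k_ADP_minus"),
    k_ADP_plus  = check_rate(k_ADP_plus, "k_ADP_plus", positive = TRUE)
  )
  structure(out, class = "hsp70_exchange_rates")
}

#' Chemostatted nucleotide pool
#'
#' ATP and ADP concentrations held fixed by the cellular chemostat. Only
#' their ratio enters the coarse-grained exchange rates; the default mimics
#' the physiological excess of ATP over ADP, `[ATP]/[ADP] = 10`.
#'
#' @param ATP ATP concentration (M).
#' @param ADP ADP concentration (M).
#' @return An object of class `hsp70_nucleotide_pool`.
#' @export
nucleotide_pool <- function(ATP = 1e-3, ADP = 1e-4) {
  ATP <- check_rate(ATP, "ATP")
  ADP <- check_rate(ADP, "ADP")
  if (ATP == 0 && ADP == 0) {
    stop_invalid("nucleotide pool must contain ATP or ADP (both are zero)")
  }
  structure(list(ATP = ATP, ADP = ADP), class = "hsp70_nucleotide_pool")
}

#' Substrate binding and unbinding kinetics
#'
#' Association/dissociation rate constants of the substrate with the ATP-
#' and ADP-bound chaperone states. The ATP state typically exchanges the
#' substrate orders of magnitude faster than the ADP state.
#'
#' @param k_on_ATP,k_off_ATP binding (M^-1 s^-1) and unbinding (s^-1) rates
#'   for the ATP-bound state.
#' @param k_on_ADP,k_off_ADP same for the ADP-bound state.
#' @return An object of class `hsp70_substrate_kinetics`.
#' @export
substrate_kinetics <- function(k_on_ATP, k_off_ATP, k_on_ADP, k_off_ADP) {
  out <- list(
    k_on_ATP  = check_rate(k_on_ATP, "k_on_ATP", positive = TRUE),
    k_off_ATP = check_rate(k_off_ATP, "k_off_ATP"),
    k_on_ADP  = check_rate(k_on_ADP, "k_on_ADP", positive = TRUE),
    k_off_ADP = check_rate(k_off_ADP, "k_off_ADP")
  )
  structure(out, class = "hsp70_substrate_kinetics")
}

#' ATP hydrolysis rates
#'
#' Basal (`k_h`) and substrate-stimulated (`k_h_S`) hydrolysis rates of the
#' ATP-bound chaperone. J-domain co-chaperones act on `k_h_S` only. The ATP
#' synthesis rate `k_synth` (microscopic reverse of hydrolysis) is below
#' detectability in vivo and defaults to exactly zero; values above 1e-6
#' s^-1 are rejected unless `max_k_synth` is raised.
#'
#' @param k_h basal hydrolysis rate (s^-1).
#' @param k_h_S substrate-stimulated hydrolysis rate (s^-1).
#' @param k_synth ATP synthesis rate (s^-1), default 0.
#' @param max_k_synth upper bound enforced on `k_synth` (s^-1).
#' @return An object of class `hsp70_hydrolysis_rates`.
#' @export
hydrolysis_rates <- function(k_h, k_h_S = k_h, k_synth = 0,
                             max_k_synth = 1e-6) {
  out <- list(
    k_h     = check_rate(k_h, "k_h"),
    k_h_S   = check_rate(k_h_S, "k_h_S"),
    k_synth = check_rate(k_synth, "k_synth")
  )
  if (out$k_synth > max_k_synth) {
    stop_invalid("'k_synth' = ", k_synth, " exceeds the allowed bound ",
                 max_k_synth, " s^-1; raise 'max_k_synth' to override")
  }
  structure(out, class = "hsp70_hydrolysis_rates")
}

#' Full rate-parameter set of the Hsp70 cycle
#'
#' Bundles the microscopic exchange rates (apo and, optionally, substrate
#' bound), the substrate kinetics, the hydrolysis rates and the nucleotide
#' pool. Validation is eager: an invalid combination fails here, not in the
#' middle of a sweep. When `micro_bound` is omitted it defaults to the apo
#' set, so the substrate-bound ADP-to-ATP exchange rate equals the apo one
#' and the substrate-bound ATP-to-ADP exchange rate follows from the
#' detailed-balance closure (see [effective_rates()]).
#'
#' @param substrate an [substrate_kinetics()] object.
#' @param hydrolysis an [hydrolysis_rates()] object.
#' @param micro_apo an [exchange_rates()] object for the substrate-free
#'   chaperone.
#' @param micro_bound an [exchange_rates()] object for the substrate-bound
#'   chaperone; defaults to `micro_apo`.
#' @param pool a [nucleotide_pool()] object.
#' @return An object of class `hsp70_rates`.
#' @seealso [dnak_rates()] for the DnaK/DnaJ parameter set,
#'   [effective_rates()] for the coarse-grained cycle rates.
#' @export
hsp70_rates <- function(substrate, hydrolysis, micro_apo,
                        micro_bound = micro_apo, pool = nucleotide_pool()) {
  stopifnot(inherits(substrate, "hsp70_substrate_kinetics"),
            inherits(hydrolysis, "hsp70_hydrolysis_rates"),
            inherits(micro_apo, "hsp70_exchange_rates"),
            inherits(micro_bound, "hsp70_exchange_rates"),
            inherits(pool, "hsp70_nucleotide_pool"))
  out <- structure(
    list(micro_apo = micro_apo, micro_bound = micro_bound,
         substrate = substrate, hydrolysis = hydrolysis, pool = pool),
    class = "hsp70_rates"
  )
  ## eager composability check: must yield valid effective rates
  effective_rates(out)
  out
}

#' Total chaperone and substrate concentrations
#'
#' @param Hsp70_tot total chaperone concentration (M).
#' @param S_tot total substrate concentration (M).
#' @return An object of class `hsp70_composition`.
#' @export
system_composition <- function(Hsp70_tot = 40e-6, S_tot = 4e-6) {
  structure(
    list(Hsp70_tot = check_rate(Hsp70_tot, "Hsp70_tot"),
         S_tot = check_rate(S_tot, "S_tot")),
    class = "hsp70_composition"
  )
}

#' DnaK/DnaJ rate parameters
#'
#' The experimentally determined parameter set for the Escherichia coli
#' DnaK-DnaJ system: basal hydrolysis 6e-4 s^-1, maximal DnaJ-stimulated
#' hydrolysis 1.8 s^-1 (acceleration 3000), substrate kinetics
#' (4.5e5, 2, 1e3, 4.7e-4) and microscopic nucleotide exchange rates
#' (1.33e-4, 1.3e5, 0.022, 2.67e5), with a chemostatted pool at
#' `[ATP]/[ADP] = 10`.
#'
#' @param accel hydrolysis acceleration ratio `k_h_S / k_h`; the default
#'   3000 corresponds to the maximal measured stimulated rate 1.8 s^-1.
#' @param atp_adp_ratio nucleotide pool ratio `[ATP]/[ADP]`.
#' @param ATP ATP concentration (M); ADP is `ATP / atp_adp_ratio`.
#' @return An object of class `hsp70_rates`.
#' @examples
#' r <- dnak_rates()
#' effective_rates(r)
#' @export
dnak_rates <- function(accel = 3000, atp_adp_ratio = 10, ATP = 1e-3) {
  k_h <- 6e-4
  hsp70_rates(
    substrate = substrate_kinetics(k_on_ATP = 4.5e5, k_off_ATP = 2,
                                   k_on_ADP = 1e3, k_off_ADP = 4.7e-4),
    hydrolysis = hydrolysis_rates(k_h = k_h, k_h_S = accel * k_h),
    micro_apo = exchange_rates(k_ATP_minus = 1.33e-4, k_ATP_plus = 1.3e5,
                               k_ADP_minus = 0.022, k_ADP_plus = 2.67e5),
    pool = nucleotide_pool(ATP = ATP, ADP = ATP / atp_adp_ratio)
  )
}

#' Modify the hydrolysis acceleration of a rate set
#'
#' Returns a copy of `rates` with `k_h_S = accel * k_h`. Only the hydrolysis
#' branch changes; the exchange rates (and hence the detailed-balance
#' closure of the exchange sub-cycle) are untouched.
#'
#' @param rates an `hsp70_rates` object.
#' @param accel acceleration ratio `k_h_S / k_h`.
#' @return An `hsp70_rates` object.
#' @export
set_acceleration <- function(rates, accel) {
  stopifnot(inherits(rates, "hsp70_rates"))
  accel <- check_rate(accel, "accel")
  rates$hydrolysis$k_h_S <- accel * rates$hydrolysis$k_h
  rates
}

#' @export
print.hsp70_rates <- function(x, ...) {
  eff <- effective_rates(x)
  kd <- dissociation_constants(x$substrate)
  cat("Hsp70 cycle rate parameters\n")
  cat(sprintf("  substrate:  k_on_ATP=%.3g  k_off_ATP=%.3g  k_on_ADP=%.3g  k_off_ADP=%.3g\n",
              x$substrate$k_on_ATP, x$substrate$k_off_ATP,
              x$substrate$k_on_ADP, x$substrate$k_off_ADP))
  cat(sprintf("  KD(ATP) = %.3g M,  KD(ADP) = %.3g M\n", kd[["KD_ATP"]], kd[["KD_ADP"]]))
  cat(sprintf("  hydrolysis: k_h=%.3g  k_h_S=%.3g  (accel %.3g)  k_synth=%.3g\n",
              x$hydrolysis$k_h, x$hydrolysis$k_h_S,
              if (x$hydrolysis$k_h > 0) x$hydrolysis$k_h_S / x$hydrolysis$k_h else NA,
              x$hydrolysis$k_synth))
  cat(sprintf("  pool: [ATP]=%.3g M  [ADP]=%.3g M\n", x$pool$ATP, x$pool$ADP))
  cat(sprintf("  effective:  k_TD_ex=%.4g  k_DT=%.4g  k_TD_ex_S=%.4g  k_DT_S=%.4g (s^-1)\n",
              eff$k_TD_ex, eff$k_DT, eff$k_TD_ex_S, eff$k_DT_S))
  invisible(x)
}
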