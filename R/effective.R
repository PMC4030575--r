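## Coarse-graining of the nucleotide exchange process and thermodynamic
## closure of the cycle.

#' Effective nucleotide exchange rates
#'
#' Coarse-grains the two-step exchange process (nucleotide release, apo
#' intermediate, nucleotide binding) against a chemostatted ATP/ADP pool
#' into first-order interconversion rates between the ATP- and ADP-bound
#' chaperone states:
#' \deqn{k_{TD}^{ex} = \frac{k_{ATP}^- k_{ADP}^+ [ADP]}
#'   {k_{ATP}^+ [ATP] + k_{ADP}^+ [ADP]}, \qquad
#'   k_{DT} = \frac{k_{ADP}^- k_{ATP}^+ [ATP]}
#'   {k_{ATP}^+ [ATP] + k_{ADP}^+ [ADP]}.}
#' Release rates set upper bounds, further modulated by the partitioning of
#' the apo state between ATP and ADP binding; the ratio
#' `k_TD_ex / k_DT` reproduces the exchange equilibrium constant.
#'
#' @param micro an [exchange_rates()] object.
#' @param pool a [nucleotide_pool()] object.
#' @return Named numeric vector with elements `k_TD_ex` and `k_DT` (s^-1).
#' @examples
#' effective_exchange_rates(
#'   exchange_rates(1.33e-4, 1.3e5, 0.022, 2.67e5),
#'   nucleotide_pool(ATP = 1e-3, ADP = 1e-4))
#' @export
effective_exchange_rates <- function(micro, pool) {
  stopifnot(inherits(micro, "hsp70_exchange_rates"),
            inherits(pool, "hsp70_nucleotide_pool"))
  den <- micro$k_ATP_plus * pool$ATP + micro$k_ADP_plus * pool$ADP
  if (den <= 0) {
    stop_invalid("zero exchange denominator: k_ATP_plus*[ATP] + ",
                 "k_ADP_plus*[ADP] must be > 0 (k_ATP_plus=", micro$k_ATP_plus,
                 ", [ATP]=", pool$ATP, ", k_ADP_plus=", micro$k_ADP_plus,
                 ", [ADP]=", pool$ADP, ")")
  }
  c(k_TD_ex = micro$k_ATP_minus * micro$k_ADP_plus * pool$ADP / den,
    k_DT    = micro$k_ADP_minus * micro$k_ATP_plus * pool$ATP / den)
}

#' Nucleotide-state dissociation constants
#'
#' @param sk a [substrate_kinetics()] object.
#' @return Named numeric vector with `KD_ATP = k_off_ATP / k_on_ATP` and
#'   `KD_ADP = k_off_ADP / k_on_ADP` (M).
#' @export
dissociation_constants <- function(sk) {
  stopifnot(inherits(sk, "hsp70_substrate_kinetics"))
  if (sk$k_on_ATP <= 0 || sk$k_on_ADP <= 0) {
    stop_invalid("substrate on-rates must be > 0 to define dissociation constants")
  }
  c(KD_ATP = sk$k_off_ATP / sk$k_on_ATP,
    KD_ADP = sk$k_off_ADP / sk$k_on_ADP)
}

#' Detailed-balance closure for the substrate-bound exchange rate
#'
#' A cycle at thermodynamic equilibrium accumulates zero free energy, which
#' fixes the substrate-bound ATP-to-ADP exchange rate in terms of the other
#' rates:
#' \deqn{k_{TD}^{ex,S} = \frac{k_{TD}^{ex}\, K_D(ATP)\, k_{DT}^S}
#'   {K_D(ADP)\, k_{DT}}.}
#' With this closure the product of forward over backward rates around the
#' hydrolysis-free loop is exactly 1.
#'
#' @param k_TD_ex apo ATP-to-ADP exchange rate (s^-1).
#' @param k_DT apo ADP-to-ATP exchange rate (s^-1).
#' @param k_DT_S substrate-bound ADP-to-ATP exchange rate (s^-1).
#' @param KD_ATP,KD_ADP nucleotide-state dissociation constants (M).
#' @return The substrate-bound ATP-to-ADP exchange rate `k_TD_ex_S` (s^-1).
#' @export
closure_k_TD_ex_S <- function(k_TD_ex, k_DT, k_DT_S, KD_ATP, KD_ADP) {
  k_TD_ex <- check_rate(k_TD_ex, "k_TD_ex")
  k_DT <- check_rate(k_DT, "k_DT", positive = TRUE)
  k_DT_S <- check_rate(k_DT_S, "k_DT_S")
  KD_ATP <- check_rate(KD_ATP, "KD_ATP")
  KD_ADP <- check_rate(KD_ADP, "KD_ADP", positive = TRUE)
  k_TD_ex * KD_ATP * k_DT_S / (KD_ADP * k_DT)
}

#' Effective first-order rates of the four-state cycle
#'
#' Collapses a full [hsp70_rates()] set into the six first-order
#' interconversion rates of the coarse-grained cycle. The apo rates come
#' from [effective_exchange_rates()] on `micro_apo`; the substrate-bound
#' ADP-to-ATP rate `k_DT_S` is computed identically from `micro_bound`, and
#' the substrate-bound ATP-to-ADP *exchange* rate follows from the
#' detailed-balance closure [closure_k_TD_ex_S()]. Hydrolysis then adds on
#' top of exchange: `k_TD = k_TD_ex + k_h`, `k_TD_S = k_TD_ex_S + k_h_S`.
#' A nonzero `k_synth` adds uniformly to `k_DT` and `k_DT_S`.
#'
#' @param rates an `hsp70_rates` object.
#' @return An object of class `hsp70_effective_rates`: a list with elements
#'   `k_TD_ex`, `k_DT`, `k_TD_ex_S`, `k_DT_S`, `k_TD`, `k_TD_S` (all s^-1).
#' @export
effective_rates <- function(rates) {
  stopifnot(inherits(rates, "hsp70_rates"))
  apo <- effective_exchange_rates(rates$micro_apo, rates$pool)
  bnd <- effective_exchange_rates(rates$micro_bound, rates$pool)
  kd <- dissociation_constants(rates$substrate)
  hyd <- rates$hydrolysis
  k_DT <- unname(apo[["k_DT"]] + hyd$k_synth)
  k_DT_S <- unname(bnd[["k_DT"]] + hyd$k_synth)
  k_TD_ex <- unname(apo[["k_TD_ex"]])
  k_TD_ex_S <- closure_k_TD_ex_S(k_TD_ex, k_DT, k_DT_S,
                                 kd[["KD_ATP"]], kd[["KD_ADP"]])
  structure(
    list(k_TD_ex = k_TD_ex, k_DT = k_DT,
         k_TD_ex_S = k_TD_ex_S, k_DT_S = k_DT_S,
         k_TD = k_TD_ex + hyd$k_h, k_TD_S = k_TD_ex_S + hyd$k_h_S),
    class = "hsp70_effective_rates"
  )
}

#' Thermodynamic affinity of the four-state loop
#'
#' The log product of forward over backward rates around the loop
#' T -> TS -> DS -> D -> T,
#' \deqn{\ln\frac{k_{on}^{ATP}\, k_{TD}^S\, k_{off}^{ADP}\, k_{DT}}
#'   {k_{off}^{ATP}\, k_{DT}^S\, k_{on}^{ADP}\, k_{TD}}.}
#' Zero if and only if detailed balance holds around the loop; ATP
#' hydrolysis makes it positive, measuring the free energy driving the
#' cycle.
#'
#' @param eff an `hsp70_effective_rates` object (or an `hsp70_rates` object,
#'   which is collapsed first).
#' @param sk a [substrate_kinetics()] object; taken from `eff` when an
#'   `hsp70_rates` object is supplied.
#' @return Dimensionless log cycle product.
#' @export
cycle_affinity <- function(eff, sk) {
  if (inherits(eff, "hsp70_rates")) {
    if (missing(sk)) sk <- eff$substrate
    eff <- effective_rates(eff)
  }
  stopifnot(inherits(eff, "hsp70_effective_rates"),
            inherits(sk, "hsp70_substrate_kinetics"))
  rs <- c(sk$k_on_ATP, eff$k_TD_S, sk$k_off_ADP, eff$k_DT,
          sk$k_off_ATP, eff$k_DT_S, sk$k_on_ADP, eff$k_TD)
  if (any(rs <= 0)) {
    stop_invalid("cycle affinity undefined: all eight loop rates must be > 0")
  }
  log((sk$k_on_ATP * eff$k_TD_S * sk$k_off_ADP * eff$k_DT) /
        (sk$k_off_ATP * eff$k_DT_S * sk$k_on_ADP * eff$k_TD))
}
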