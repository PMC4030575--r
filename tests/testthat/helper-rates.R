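# Shared fixtures: the DnaK/DnaJ parameter set, a hydrolysis-free variant,
# and randomized positive rate sets for property-style tests.

dnak_table1_constants <- list(
  k_h = 6e-4, k_h_S_max = 1.8,
  k_on_ATP = 4.5e5, k_off_ATP = 2, k_on_ADP = 1e3, k_off_ADP = 4.7e-4,
  k_ATP_minus = 1.33e-4, k_ATP_plus = 1.3e5,
  k_ADP_minus = 0.022, k_ADP_plus = 2.67e5
)

# DnaK parameters with the hydrolysis branch switched off entirely:
# detailed balance holds around the loop.
dnak_no_hydrolysis <- function(atp_adp_ratio = 10) {
  hsp70_rates(
    substrate = substrate_kinetics(4.5e5, 2, 1e3, 4.7e-4),
    hydrolysis = hydrolysis_rates(k_h = 0, k_h_S = 0),
    micro_apo = exchange_rates(1.33e-4, 1.3e5, 0.022, 2.67e5),
    pool = nucleotide_pool(ATP = 1e-3, ADP = 1e-3 / atp_adp_ratio)
  )
}

# Random positive parameter set, log-uniform over physically broad ranges.
# The RNG state is the caller's responsibility (wrap in withr::with_seed or
# set.seed at the top of the test).
random_rates <- function(hydrolysis_on = TRUE) {
  lrunif <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  hsp70_rates(
    substrate = substrate_kinetics(
      k_on_ATP = lrunif(1e3, 1e7), k_off_ATP = lrunif(1e-3, 1e2),
      k_on_ADP = lrunif(1e1, 1e5), k_off_ADP = lrunif(1e-5, 1e0)),
    hydrolysis = if (hydrolysis_on) {
      hydrolysis_rates(k_h = lrunif(1e-5, 1e-2), k_h_S = lrunif(1e-3, 1e1))
    } else {
      hydrolysis_rates(k_h = 0, k_h_S = 0)
    },
    micro_apo = exchange_rates(
      k_ATP_minus = lrunif(1e-5, 1e-2), k_ATP_plus = lrunif(1e4, 1e6),
      k_ADP_minus = lrunif(1e-3, 1e0), k_ADP_plus = lrunif(1e4, 1e6)),
    pool = nucleotide_pool(ATP = lrunif(1e-4, 1e-2), ADP = lrunif(1e-5, 1e-3))
  )
}

random_composition <- function() {
  lrunif <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  system_composition(Hsp70_tot = lrunif(1e-7, 1e-4),
                     S_tot = lrunif(1e-8, 1e-4))
}
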