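# Coarse-grained exchange rates, dissociation constants, thermodynamic
# closure and the loop-affinity diagnostic.

test_that("effective exchange rates reproduce the coarse-grained quotients", {
  micro <- with(dnak_table1_constants,
                exchange_rates(k_ATP_minus, k_ATP_plus,
                               k_ADP_minus, k_ADP_plus))
  eff <- effective_exchange_rates(micro, nucleotide_pool(1e-3, 1e-4))
  # frozen from direct arithmetic evaluation of the quotients
  expect_equal(eff[["k_TD_ex"]], 2.266177409061902e-05, tolerance = 1e-12)
  expect_equal(eff[["k_DT"]], 1.8251435864709637e-02, tolerance = 1e-12)

  # limits: a single-nucleotide pool collapses to the release rates
  only_atp <- effective_exchange_rates(micro, nucleotide_pool(1e-3, 0))
  expect_identical(only_atp[["k_TD_ex"]], 0)
  expect_equal(only_atp[["k_DT"]], dnak_table1_constants$k_ADP_minus)
  only_adp <- effective_exchange_rates(micro, nucleotide_pool(0, 1e-4))
  expect_identical(only_adp[["k_DT"]], 0)
  expect_equal(only_adp[["k_TD_ex"]], dnak_table1_constants$k_ATP_minus)
})

test_that("exchange-rate ratio reproduces the T/D equilibrium constant", {
  set.seed(101)
  for (i in 1:25) {
    r <- random_rates()
    eff <- effective_exchange_rates(r$micro_apo, r$pool)
    expected <- with(r$micro_apo, k_ATP_minus * k_ADP_plus * r$pool$ADP /
                       (k_ADP_minus * k_ATP_plus * r$pool$ATP))
    expect_equal(eff[["k_TD_ex"]] / eff[["k_DT"]], expected,
                 tolerance = 1e-12)
    expect_true(all(eff >= 0))
  }
})

test_that("dissociation constants are off/on ratios", {
  sk <- with(dnak_table1_constants,
             substrate_kinetics(k_on_ATP, k_off_ATP, k_on_ADP, k_off_ADP))
  kd <- dissociation_constants(sk)
  expect_equal(kd[["KD_ATP"]], 2 / 4.5e5, tolerance = 1e-14)
  expect_equal(kd[["KD_ADP"]], 4.7e-4 / 1e3, tolerance = 1e-14)
  identity_case <- substrate_kinetics(3, 3, 7, 7)
  expect_equal(unname(dissociation_constants(identity_case)), c(1, 1))
})

test_that("closure fixes the substrate-bound exchange rate", {
  # DnaK parameters with k_DT_S = k_DT: k_TD_ex_S = k_TD_ex * KD_T / KD_D
  k_TD_ex <- 2.266177409061902e-05
  k_DT <- 1.8251435864709637e-02
  got <- closure_k_TD_ex_S(k_TD_ex, k_DT, k_DT, 2 / 4.5e5, 4.7e-7)
  expect_equal(got, 2.142957360815037e-04, tolerance = 1e-12)
  # symmetric cycle: equal KDs and equal D->T rates leave the rate unchanged
  expect_equal(closure_k_TD_ex_S(0.3, 5, 5, 1e-6, 1e-6), 0.3)
  expect_error(closure_k_TD_ex_S(0.3, 0, 5, 1e-6, 1e-6),
               class = "hsp70_invalid_parameter")
})

test_that("closure zeroes the loop affinity whenever hydrolysis is off", {
  set.seed(202)
  for (i in 1:25) {
    r <- random_rates(hydrolysis_on = FALSE)
    expect_equal(cycle_affinity(r), 0, tolerance = 1e-12)
    # hydrolysis-free cycle product around the loop is exactly 1
    eff <- effective_rates(r)
    sk <- r$substrate
    prod <- (sk$k_on_ATP * eff$k_TD_ex_S * sk$k_off_ADP * eff$k_DT) /
      (sk$k_off_ATP * eff$k_DT_S * sk$k_on_ADP * eff$k_TD_ex)
    expect_equal(prod, 1, tolerance = 1e-12)
  }
})

test_that("hydrolysis drives the loop affinity positive; it is a pure ratio", {
  r <- dnak_rates(accel = 3000)
  expect_gt(cycle_affinity(r), 0)
  # doubling both substrate-bound interconversion rates cancels
  eff <- effective_rates(r)
  eff2 <- eff
  eff2$k_TD_S <- 2 * eff$k_TD_S
  eff2$k_DT_S <- 2 * eff$k_DT_S
  expect_equal(cycle_affinity(eff2, r$substrate),
               cycle_affinity(eff, r$substrate), tolerance = 1e-12)
})

test_that("effective rates satisfy the total-rate decomposition", {
  set.seed(303)
  for (i in 1:10) {
    r <- random_rates()
    eff <- effective_rates(r)
    expect_equal(eff$k_TD, eff$k_TD_ex + r$hydrolysis$k_h)
    expect_equal(eff$k_TD_S, eff$k_TD_ex_S + r$hydrolysis$k_h_S)
    expect_true(all(unlist(eff) >= 0))
  }
})

test_that("constructors validate eagerly and name the offending rate", {
  expect_error(substrate_kinetics(-1, 2, 1e3, 4.7e-4), "k_on_ATP",
               class = "hsp70_invalid_parameter")
  expect_error(exchange_rates(1e-4, 0, 0.02, 2e5), "k_ATP_plus",
               class = "hsp70_invalid_parameter")
  expect_error(nucleotide_pool(0, 0), class = "hsp70_invalid_parameter")
  expect_error(hydrolysis_rates(6e-4, 1.8, k_synth = 1e-3),
               "k_synth", class = "hsp70_invalid_parameter")
  # zero binding rates make the exchange denominator collapse
  expect_error(
    effective_exchange_rates(
      structure(list(k_ATP_minus = 1, k_ATP_plus = 0,
                     k_ADP_minus = 1, k_ADP_plus = 0),
                class = "hsp70_exchange_rates"),
      nucleotide_pool(1e-3, 1e-4)),
    "denominator", class = "hsp70_invalid_parameter")
})

test_that("a configured ATP synthesis rate adds uniformly to the D->T rates", {
  base <- dnak_rates()
  with_synth <- hsp70_rates(
    substrate = base$substrate,
    hydrolysis = hydrolysis_rates(6e-4, 1.8, k_synth = 1e-6),
    micro_apo = base$micro_apo, pool = base$pool
  )
  e0 <- effective_rates(base)
  e1 <- effective_rates(with_synth)
  expect_equal(e1$k_DT, e0$k_DT + 1e-6)
  expect_equal(e1$k_DT_S, e0$k_DT_S + 1e-6)
})
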