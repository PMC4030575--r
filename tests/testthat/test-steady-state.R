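# Steady-state solver, closed-form dissociation constants and hydrolysis
# flux.

dnak <- dnak_rates(accel = 3000)
comp40_4 <- system_composition(40e-6, 4e-6)

test_that("equilibrium constant is the exchange-weighted average of the KDs", {
  r <- dnak_no_hydrolysis()
  kd <- dissociation_constants(r$substrate)
  keq <- keff_equilibrium(r)
  # frozen from the weighted average with k_DT_S = 1.8251e-2, k_TD_S = 2.1430e-4
  expect_equal(keq, 4.398320818467947e-06, tolerance = 1e-12)
  # at physiological ATP excess, near the upper bound KD(ATP)
  expect_equal(keq, kd[["KD_ATP"]], tolerance = 0.02)
  expect_true(keq >= min(kd) && keq <= max(kd))

  # degenerate weight: no ATP->ADP conversion at all pins K_eff at KD(ATP)
  r_no_td <- hsp70_rates(
    substrate = r$substrate,
    hydrolysis = hydrolysis_rates(0, 0),
    micro_apo = exchange_rates(0, 1.3e5, 0.022, 2.67e5),
    pool = r$pool)
  expect_equal(keff_equilibrium(r_no_td), kd[["KD_ATP"]])
  set.seed(11)
  for (i in 1:20) {
    rr <- random_rates(hydrolysis_on = sample(c(TRUE, FALSE), 1))
    kdr <- dissociation_constants(rr$substrate)
    expect_true(keff_equilibrium(rr) >= min(kdr) - 1e-15 &&
                  keff_equilibrium(rr) <= max(kdr) + 1e-15)
  }
})

test_that("solver at equilibrium matches the weighted average and balances every branch", {
  r <- dnak_no_hydrolysis()
  st <- solve_steady_state(r, comp40_4)
  expect_equal(st$K_eff, keff_equilibrium(r), tolerance = 1e-9)

  # detailed balance: each branch individually balanced
  eff <- effective_rates(r)
  sk <- r$substrate
  with(as.list(st$conc), {
    expect_equal(sk$k_on_ATP * st$S_free * T, sk$k_off_ATP * TS,
                 tolerance = 1e-8)
    expect_equal(sk$k_on_ADP * st$S_free * D, sk$k_off_ADP * DS,
                 tolerance = 1e-8)
    expect_equal(eff$k_TD * T, eff$k_DT * D, tolerance = 1e-8)
    expect_equal(eff$k_TD_S * TS, eff$k_DT_S * DS, tolerance = 1e-8)
  })

  # equilibrium K_eff is independent of the total concentrations
  for (f in c(0.01, 100)) {
    st2 <- solve_steady_state(
      r, system_composition(40e-6 * f, 4e-6))
    st3 <- solve_steady_state(
      r, system_composition(40e-6, 4e-6 * f))
    expect_equal(st2$K_eff, st$K_eff, tolerance = 1e-8)
    expect_equal(st3$K_eff, st$K_eff, tolerance = 1e-8)
  }
})

test_that("solver K_eff equals the closed form at the solved free substrate", {
  set.seed(404)
  for (i in 1:30) {
    r <- random_rates()
    comp <- random_composition()
    st <- solve_steady_state(r, comp)
    expect_equal(st$K_eff, keff_nonequilibrium(r, st$S_free),
                 tolerance = 1e-8)
    # both conservation laws
    expect_equal(sum(st$conc), comp$Hsp70_tot, tolerance = 1e-9)
    expect_equal(st$S_free + st$conc[["TS"]] + st$conc[["DS"]], comp$S_tot,
                 tolerance = 1e-9)
    expect_true(all(st$conc >= 0) && st$S_free >= 0)
  }
})

test_that("solver agrees with independent ODE integration to stationarity", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    with(as.list(c(y, p)), {
      bindT <- k_on_ATP * S * T; unbT <- k_off_ATP * TS
      bindD <- k_on_ADP * S * D; unbD <- k_off_ADP * DS
      list(c(
        T = -bindT + unbT - k_TD * T + k_DT * D,
        D = -bindD + unbD + k_TD * T - k_DT * D,
        TS = bindT - unbT - k_TD_S * TS + k_DT_S * DS,
        DS = bindD - unbD + k_TD_S * TS - k_DT_S * DS,
        S = -bindT + unbT - bindD + unbD))
    })
  }
  for (accel in c(1, 3000)) {
    r <- dnak_rates(accel = accel)
    eff <- effective_rates(r)
    p <- c(unlist(r$substrate), k_TD = eff$k_TD, k_DT = eff$k_DT,
           k_TD_S = eff$k_TD_S, k_DT_S = eff$k_DT_S)
    y0 <- c(T = 40e-6, D = 0, TS = 0, DS = 0, S = 4e-6)
    out <- deSolve::ode(y0, c(0, 1e6), rhs, p, method = "lsoda",
                        rtol = 1e-10, atol = 1e-16)
    yss <- out[nrow(out), -1]
    st <- solve_steady_state(r, comp40_4)
    expect_equal(unname(yss[c("T", "D", "TS", "DS")]), unname(st$conc),
                 tolerance = 1e-6)
    expect_equal(unname(yss[["S"]]), st$S_free, tolerance = 1e-6)
  }
})

test_that("degenerate compositions solve in closed form", {
  r <- dnak
  st0 <- solve_steady_state(r, system_composition(40e-6, 0))
  expect_equal(unname(st0$conc[c("TS", "DS")]), c(0, 0), tolerance = 1e-15)
  eff <- effective_rates(r)
  expect_equal(st0$conc[["T"]] / st0$conc[["D"]], eff$k_DT / eff$k_TD,
               tolerance = 1e-10)
  expect_error(keff_from_state(st0), class = "hsp70_invalid_parameter")

  stH <- solve_steady_state(r, system_composition(0, 4e-6))
  expect_identical(unname(stH$conc), c(0, 0, 0, 0))
  expect_identical(stH$S_free, 4e-6)
})

test_that("K_eff from a state is the plug-in ratio with its invariances", {
  st <- solve_steady_state(dnak, comp40_4)
  expect_equal(keff_from_state(st), st$K_eff)
  # equal free and bound chaperone makes K_eff the free substrate itself
  st2 <- st
  st2$conc <- c(T = 1e-6, D = 1e-6, TS = 1.5e-6, DS = 0.5e-6)
  expect_equal(keff_from_state(st2), st2$S_free)
  # scale invariance of the ratio
  st3 <- st
  st3$conc <- st$conc * 2
  expect_equal(keff_from_state(st3), keff_from_state(st))
})

test_that("hydrolysis flux matches the stationarity identity and saturates", {
  # at steady state with k_synth = 0, dissipation equals the net D->T
  # exchange flux minus the T->D exchange flux
  set.seed(505)
  for (i in 1:10) {
    r <- random_rates()
    comp <- random_composition()
    st <- solve_steady_state(r, comp)
    eff <- effective_rates(r)
    net_exchange <- (eff$k_DT * st$conc[["D"]] + eff$k_DT_S * st$conc[["DS"]]) -
      (eff$k_TD_ex * st$conc[["T"]] + eff$k_TD_ex_S * st$conc[["TS"]])
    expect_equal(hydrolysis_flux(st), net_exchange, tolerance = 1e-6)
  }

  r0 <- dnak_no_hydrolysis()
  expect_equal(hydrolysis_flux(solve_steady_state(r0, comp40_4)), 0)

  accel <- log_grid(1, 1e7, 15)
  flux <- vapply(accel, function(a) {
    solve_steady_state(set_acceleration(dnak, a), comp40_4)$P_diss
  }, numeric(1))
  expect_true(all(diff(flux) >= -1e-15))
  # saturation: the last decade changes the flux by well under 1%
  expect_lt(flux[15] / flux[13] - 1, 0.01)
})

test_that("zero-order approximation tracks the closed form in the physiological range", {
  kd <- dissociation_constants(dnak$substrate)
  for (a in log_grid(1, 1e4, 9)) {
    r <- set_acceleration(dnak, a)
    full <- keff_nonequilibrium(r, 0)
    approx <- keff_zero_order(r)
    expect_gt(approx / full, 0.5)
    expect_lt(approx / full, 2)
  }
  # negligible ATP->ADP exchange and hydrolysis: reduces to KD(ATP)
  expect_equal(keff_zero_order(dnak_no_hydrolysis()), kd[["KD_ATP"]],
               tolerance = 0.05)
  # extreme acceleration sends the approximation to zero
  expect_lt(keff_zero_order(set_acceleration(dnak, 1e12)), 1e-12)
})

test_that("ultra-affinity onset: K_eff non-increasing in k_h_S, below KD(ADP) by accel 1e4", {
  kd <- dissociation_constants(dnak$substrate)
  accel <- log_grid(1, 1e4, 13)
  keff <- vapply(accel, function(a) {
    solve_steady_state(set_acceleration(dnak, a), comp40_4)$K_eff
  }, numeric(1))
  expect_true(all(diff(keff) < 0))
  expect_lt(keff[length(keff)], kd[["KD_ADP"]])
})
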