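## Equilibrium and non-equilibrium steady-state solutions of the cycle.

## Flat numeric view of all first-order/bimolecular rates entering the
## mass-action system. Internal.
cycle_rate_vector <- function(rates) {
  eff <- effective_rates(rates)
  sk <- rates$substrate
  c(k_on_ATP = sk$k_on_ATP, k_off_ATP = sk$k_off_ATP,
    k_on_ADP = sk$k_on_ADP, k_off_ADP = sk$k_off_ADP,
    k_TD = eff$k_TD, k_DT = eff$k_DT,
    k_TD_S = eff$k_TD_S, k_DT_S = eff$k_DT_S,
    k_TD_ex = eff$k_TD_ex, k_TD_ex_S = eff$k_TD_ex_S,
    k_h = rates$hydrolysis$k_h, k_h_S = rates$hydrolysis$k_h_S)
}

## 4x4 linear solve of the chaperone states (T, D, TS, DS) at fixed free
## substrate concentration S, normalised to total chaperone Htot.
## Rank-3 rate matrix + chaperone conservation in the last row; falls back
## to an SVD pseudo-inverse when the system is numerically singular.
solve_states_at_S <- function(rv, S, Htot) {
  A <- matrix(c(
    -(rv[["k_on_ATP"]] * S + rv[["k_TD"]]), rv[["k_DT"]], rv[["k_off_ATP"]], 0,
    rv[["k_TD"]], -(rv[["k_on_ADP"]] * S + rv[["k_DT"]]), 0, rv[["k_off_ADP"]],
    rv[["k_on_ATP"]] * S, 0, -(rv[["k_off_ATP"]] + rv[["k_TD_S"]]), rv[["k_DT_S"]],
    1, 1, 1, 1), nrow = 4, byrow = TRUE)
  b <- c(0, 0, 0, Htot)
  x <- tryCatch(solve(A, b), error = function(e) {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-13
    drop(sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
  })
  ## tiny negative round-off is clamped; genuinely negative solutions would
  ## indicate a defect in the rate matrix and must not happen
  if (any(x < -1e-10 * max(Htot, 1e-300))) {
    stop("internal error: negative steady-state concentration ",
         paste(signif(x, 6), collapse = ", "))
  }
  pmax(x, 0)
}

#' Equilibrium effective dissociation constant
#'
#' With hydrolysis off, every branch of the cycle balances individually and
#' the effective dissociation constant is the exchange-weighted average of
#' the two nucleotide-state constants,
#' \deqn{K_{eff}^{eq} = \frac{k_{DT}^S K_D(ATP) + k_{TD}^S K_D(ADP)}
#'   {k_{DT}^S + k_{TD}^S},}
#' which always lies between \eqn{K_D(ADP)} and \eqn{K_D(ATP)}. At the
#' physiological ATP excess the weight is dominated by `k_DT_S`, so the
#' equilibrium constant sits near its upper bound \eqn{K_D(ATP)}.
#'
#' @param rates an `hsp70_rates` object.
#' @return Equilibrium dissociation constant (M).
#' @examples
#' keff_equilibrium(dnak_rates())
#' @export
keff_equilibrium <- function(rates) {
  eff <- effective_rates(rates)
  kd <- dissociation_constants(rates$substrate)
  den <- eff$k_DT_S + eff$k_TD_S
  if (den <= 0) stop_invalid("k_DT_S + k_TD_S must be > 0")
  (eff$k_DT_S * kd[["KD_ATP"]] + eff$k_TD_S * kd[["KD_ADP"]]) / den
}

#' Non-equilibrium effective dissociation constant (closed form)
#'
#' Evaluates the closed-form steady-state solution of the four-state cycle
#' at a given free substrate concentration:
#' \deqn{K_{eff}^{neq} = \frac{(k_{DT}^S k_{off}^{ATP} + k_{TD}^S
#'   k_{off}^{ADP} + k_{off}^{ATP} k_{off}^{ADP})(k_{DT} + k_{TD}) +
#'   (k_{DT}^S k_{off}^{ATP} k_{on}^{ADP} + k_{TD}^S k_{off}^{ADP}
#'   k_{on}^{ATP})[S]}{k_{DT}(k_{off}^{ADP} + k_{DT}^S + k_{TD}^S)
#'   k_{on}^{ATP} + k_{TD}(k_{off}^{ATP} + k_{DT}^S + k_{TD}^S)
#'   k_{on}^{ADP} + (k_{DT}^S + k_{TD}^S) k_{on}^{ATP} k_{on}^{ADP}[S]}.}
#' When detailed balance holds (hydrolysis off with closure-consistent
#' rates) this reduces to [keff_equilibrium()] for every `S_free`.
#'
#' @param rates an `hsp70_rates` object.
#' @param S_free free substrate concentration (M); `0` gives the
#'   vanishing-substrate limit.
#' @return Effective dissociation constant (M).
#' @examples
#' keff_nonequilibrium(dnak_rates(accel = 3000))      # ultra-affinity
#' keff_nonequilibrium(dnak_rates(accel = 1))
#' @export
keff_nonequilibrium <- function(rates, S_free = 0) {
  S_free <- check_rate(S_free, "S_free")
  rv <- cycle_rate_vector(rates)
  num <- (rv[["k_DT_S"]] * rv[["k_off_ATP"]] +
            rv[["k_TD_S"]] * rv[["k_off_ADP"]] +
            rv[["k_off_ATP"]] * rv[["k_off_ADP"]]) *
    (rv[["k_DT"]] + rv[["k_TD"]]) +
    (rv[["k_DT_S"]] * rv[["k_off_ATP"]] * rv[["k_on_ADP"]] +
       rv[["k_TD_S"]] * rv[["k_off_ADP"]] * rv[["k_on_ATP"]]) * S_free
  den <- rv[["k_DT"]] * (rv[["k_off_ADP"]] + rv[["k_DT_S"]] + rv[["k_TD_S"]]) *
    rv[["k_on_ATP"]] +
    rv[["k_TD"]] * (rv[["k_off_ATP"]] + rv[["k_DT_S"]] + rv[["k_TD_S"]]) *
    rv[["k_on_ADP"]] +
    (rv[["k_DT_S"]] + rv[["k_TD_S"]]) * rv[["k_on_ATP"]] * rv[["k_on_ADP"]] * S_free
  if (den <= 0) stop_invalid("zero denominator in the closed-form K_eff")
  unname(num / den)
}

#' Zero-order approximation of the non-equilibrium dissociation constant
#'
#' In the limit of large timescale separation (ADP-state binding and
#' unbinding negligible) the non-equilibrium dissociation constant reduces
#' to
#' \deqn{K_{eff,0}^{neq} = K_D(ATP)\,\frac{k_{DT}^S (k_{DT} + k_{TD}^{ex} +
#'   k_h)}{k_{DT} (k_{DT}^S + k_{TD}^{ex,S} + k_h^S)},}
#' a good approximation of the exact constant over the physiological range
#' of hydrolysis acceleration.
#'
#' @inheritParams keff_equilibrium
#' @return Approximate dissociation constant (M).
#' @export
keff_zero_order <- function(rates) {
  rv <- cycle_rate_vector(rates)
  kd <- dissociation_constants(rates$substrate)
  den <- rv[["k_DT"]] *
    (rv[["k_DT_S"]] + rv[["k_TD_ex_S"]] + rv[["k_h_S"]])
  if (den <= 0) stop_invalid("zero divisor in the zero-order K_eff")
  unname(kd[["KD_ATP"]] * rv[["k_DT_S"]] *
           (rv[["k_DT"]] + rv[["k_TD_ex"]] + rv[["k_h"]]) / den)
}

#' Solve the mass-action steady state of the cycle
#'
#' Finds the unique physical fixed point of the four-state mass-action
#' network under both conservation laws. For fixed free substrate the four
#' chaperone-state concentrations solve a linear system (rank-3 rate matrix
#' plus chaperone conservation); the free substrate concentration is then
#' pinned by substrate conservation through a bracketed scalar root-find on
#' `S_free` in `[max(0, S_tot - Hsp70_tot), S_tot]`, over which the bound
#' substrate is monotone increasing, so the root is unique.
#'
#' @param rates an `hsp70_rates` object.
#' @param comp a [system_composition()] object.
#' @param tol relative tolerance of the outer root-find on `S_free`; the
#'   default drives the bracketed search essentially to machine precision,
#'   which the self-consistency between the solved state and the closed-form
#'   dissociation constant requires when the binding curve is steep.
#' @return An object of class `hsp70_steady_state`: list with `conc`
#'   (named vector, M, states `T`, `D`, `TS`, `DS`), `S_free` (M), the
#'   derived observables `K_eff` (M) and `P_diss` (M s^-1), the
#'   composition, and solver diagnostics.
#' @examples
#' st <- solve_steady_state(dnak_rates(accel = 3000),
#'                          system_composition(40e-6, 4e-6))
#' st$K_eff            # far below KD(ADP) = 4.7e-7 M: ultra-affinity
#' @export
solve_steady_state <- function(rates, comp, tol = 1e-15) {
  stopifnot(inherits(rates, "hsp70_rates"), inherits(comp, "hsp70_composition"))
  rv <- cycle_rate_vector(rates)
  Htot <- comp$Hsp70_tot
  Stot <- comp$S_tot

  if (Htot == 0) {
    conc <- c(T = 0, D = 0, TS = 0, DS = 0)
    return(new_steady_state(conc, Stot, rates, comp, iterations = 0L))
  }
  if (Stot == 0) {
    x <- solve_states_at_S(rv, 0, Htot)
    conc <- c(T = x[1], D = x[2], TS = x[3], DS = x[4])
    return(new_steady_state(conc, 0, rates, comp, iterations = 0L))
  }

  bound_at <- function(S) {
    x <- solve_states_at_S(rv, S, Htot)
    x[3] + x[4]
  }
  f <- function(S) Stot - S - bound_at(S)
  lo <- max(0, Stot - Htot)
  hi <- Stot
  flo <- f(lo)
  fhi <- f(hi)
  if (flo < 0 || fhi > 0) {
    stop("steady-state root-find lost its bracket: f(", signif(lo, 6), ") = ",
         signif(flo, 6), ", f(", signif(hi, 6), ") = ", signif(fhi, 6),
         "; check the rate parameters")
  }
  root <- if (fhi == 0) {
    list(root = hi, iter = 0L, estim.prec = 0)
  } else if (flo == 0) {
    list(root = lo, iter = 0L, estim.prec = 0)
  } else {
    uniroot(f, c(lo, hi),
            tol = max(tol * Stot, .Machine$double.eps * Stot / 4),
            maxiter = 1000L)
  }
  S_free <- root$root
  x <- solve_states_at_S(rv, S_free, Htot)
  conc <- c(T = x[1], D = x[2], TS = x[3], DS = x[4])
  resid <- Stot - S_free - (conc[["TS"]] + conc[["DS"]])
  if (abs(resid) > 1e-9 * Stot) {
    stop("steady-state root-find did not converge: substrate-conservation ",
         "residual ", signif(resid, 4), " M on bracket [", signif(lo, 6),
         ", ", signif(hi, 6), "] after ", root$iter, " iterations")
  }
  new_steady_state(conc, S_free, rates, comp, iterations = root$iter)
}

new_steady_state <- function(conc, S_free, rates, comp, iterations) {
  names(conc) <- c("T", "D", "TS", "DS")
  hyd <- rates$hydrolysis
  bound <- conc[["TS"]] + conc[["DS"]]
  st <- structure(
    list(conc = conc, S_free = unname(S_free), composition = comp,
         rates = rates,
         K_eff = if (bound > 0) unname(S_free * (conc[["T"]] + conc[["D"]]) / bound) else NA_real_,
         P_diss = unname(hyd$k_h * conc[["T"]] + hyd$k_h_S * conc[["TS"]]),
         iterations = iterations),
    class = "hsp70_steady_state"
  )
  st
}

#' Effective dissociation constant from a solved state
#'
#' The defining plug-in ratio
#' \eqn{K_{eff} = [S]([Hsp70 \cdot ATP] + [Hsp70 \cdot ADP]) /
#' ([Hsp70 \cdot ATP \cdot S] + [Hsp70 \cdot ADP \cdot S])}.
#'
#' @param state an `hsp70_steady_state` object.
#' @return Dissociation constant (M).
#' @export
keff_from_state <- function(state) {
  stopifnot(inherits(state, "hsp70_steady_state"))
  bound <- state$conc[["TS"]] + state$conc[["DS"]]
  if (bound <= 0) {
    stop_invalid("K_eff undefined: no substrate-bound chaperone at this state")
  }
  unname(state$S_free * (state$conc[["T"]] + state$conc[["D"]]) / bound)
}

#' ATP hydrolysis flux
#'
#' The experimentally measurable energy-consumption observable
#' \deqn{P_{diss} = k_h [Hsp70 \cdot ATP] + k_h^S [Hsp70 \cdot ATP \cdot S].}
#'
#' @param state an `hsp70_steady_state` object.
#' @param hyd an [hydrolysis_rates()] object; defaults to the rates the
#'   state was solved with.
#' @return Flux in M s^-1.
#' @export
hydrolysis_flux <- function(state, hyd = state$rates$hydrolysis) {
  stopifnot(inherits(state, "hsp70_steady_state"),
            inherits(hyd, "hsp70_hydrolysis_rates"))
  unname(hyd$k_h * state$conc[["T"]] + hyd$k_h_S * state$conc[["TS"]])
}

#' @export
print.hsp70_steady_state <- function(x, ...) {
  cat("Hsp70 cycle steady state\n")
  cat(sprintf("  [Hsp70.ATP]   = %.6g M\n", x$conc[["T"]]))
  cat(sprintf("  [Hsp70.ADP]   = %.6g M\n", x$conc[["D"]]))
  cat(sprintf("  [Hsp70.ATP.S] = %.6g M\n", x$conc[["TS"]]))
  cat(sprintf("  [Hsp70.ADP.S] = %.6g M\n", x$conc[["DS"]]))
  cat(sprintf("  [S] free      = %.6g M\n", x$S_free))
  cat(sprintf("  K_eff  = %.6g M (%.4g nM)\n", x$K_eff, x$K_eff * 1e9))
  cat(sprintf("  P_diss = %.6g M s^-1\n", x$P_diss))
  invisible(x)
}
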