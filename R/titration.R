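## Synthetic equilibrium-binding titration data and isotherm fitting for
## parameter-recovery studies.

#' Generate a synthetic binding-titration dataset
#'
#' Emulates a noisy titration assay: for each total chaperone concentration
#' on the grid, the steady state of the cycle is solved at fixed total
#' substrate, the bound fraction `([TS] + [DS]) / S_tot` is computed, and
#' independent Gaussian noise is added (clipped to `[0, 1]`). The
#' generating dissociation constant — the closed-form steady-state
#' `K_eff` in the vanishing-substrate limit — is stored with the dataset,
#' along with the exact per-point values, so recovery can be scored.
#'
#' @param rates an `hsp70_rates` object.
#' @param chaperone_grid total chaperone concentrations (M), increasing.
#' @param S_tot total substrate concentration (M); keep it below the
#'   smallest grid concentration so the chaperone-excess isotherm applies.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   the bound fraction.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `hsp70_titration` (a data frame with columns
#'   `Hsp70_tot_M`, `bound_fraction`, `bound_true`, `K_eff_true_M`), with
#'   the generating `K_eff`, noise model and seed in attributes.
#' @examples
#' grid <- log_grid(5e-9, 5e-7, 12)
#' d <- generate_titration(dnak_rates(accel = 3000), grid,
#'                         S_tot = 1e-9, noise_sd = 0.02, seed = 7)
#' fit_keff(d)
#' @export
generate_titration <- function(rates, chaperone_grid, S_tot,
                               noise_sd = 0.02, seed = NULL) {
  stopifnot(inherits(rates, "hsp70_rates"))
  check_grid(chaperone_grid, "chaperone_grid", positive = TRUE)
  S_tot <- check_rate(S_tot, "S_tot", positive = TRUE)
  noise_sd <- check_rate(noise_sd, "noise_sd")
  if (!is.null(seed)) set.seed(seed)

  states <- lapply(chaperone_grid, function(H) {
    solve_steady_state(rates, system_composition(H, S_tot))
  })
  bound_true <- vapply(states, function(st) {
    (st$conc[["TS"]] + st$conc[["DS"]]) / S_tot
  }, numeric(1))
  keff_true <- vapply(states, function(st) st$K_eff, numeric(1))
  noise <- if (noise_sd > 0) rnorm(length(chaperone_grid), 0, noise_sd) else 0
  df <- data.frame(
    Hsp70_tot_M = chaperone_grid,
    bound_fraction = pmin(1, pmax(0, bound_true + noise)),
    bound_true = bound_true,
    K_eff_true_M = keff_true
  )
  structure(df,
            class = c("hsp70_titration", "data.frame"),
            generating_keff = keff_nonequilibrium(rates, S_free = 0),
            noise_sd = noise_sd, seed = seed, S_tot = S_tot, rates = rates)
}

#' Fit a single-site isotherm to a titration dataset
#'
#' Least-squares fit of `bound = [Hsp70] / (K_eff + [Hsp70])` (valid under
#' chaperone excess) with a residual-bootstrap confidence interval on
#' `K_eff`: a Student-t interval on `log(K_eff)` whose spread is the
#' bootstrap standard error, appropriate for a positive scale parameter.
#' Outside the chaperone-excess regime the effective dissociation
#' constant is concentration dependent and the isotherm is only an
#' approximation; a warning is issued when `S_tot` is not below the
#' smallest titrated concentration.
#'
#' @param data an `hsp70_titration` object, or a data frame with columns
#'   `Hsp70_tot_M` and `bound_fraction`.
#' @param level confidence level of the bootstrap interval.
#' @param n_boot number of bootstrap replicates.
#' @return A list with `K_eff_hat` (M), `CI` (two-sided bootstrap interval,
#'   M), `level`, `n_boot` and the fitted model object.
#' @export
fit_keff <- function(data, level = 0.95, n_boot = 999) {
  H <- data$Hsp70_tot_M
  y <- data$bound_fraction
  if (length(H) < 4) {
    stop_invalid("at least 4 titration points are required")
  }
  if (max(y) - min(y) < 0.05) {
    stop(structure(class = c("hsp70_fit_failure", "error", "condition"),
                   list(message = paste0(
                     "titration response is flat (range ",
                     signif(max(y) - min(y), 3),
                     "); K_eff is not identifiable from these data"),
                     call = NULL)))
  }
  S_tot <- attr(data, "S_tot")
  if (!is.null(S_tot) && S_tot >= min(H)) {
    warning("chaperone-excess assumption violated: S_tot (", signif(S_tot, 3),
            " M) is not below the smallest titrated concentration; the ",
            "effective dissociation constant is concentration-dependent in ",
            "this regime", call. = FALSE)
  }

  fit1 <- function(yy) {
    ## start from the concentration closest to half-saturation
    K0 <- H[which.min(abs(yy - 0.5))]
    fit <- minpack.lm::nlsLM(yy ~ H / (K + H), start = list(K = K0),
                             lower = min(H) * 1e-6, upper = max(H) * 1e6,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    coef(fit)[["K"]]
  }
  K_hat <- fit1(y)
  fitted_y <- H / (K_hat + H)
  res <- y - fitted_y

  boot <- vapply(seq_len(n_boot), function(i) {
    yy <- pmin(1, pmax(0, fitted_y + sample(res, length(res), replace = TRUE)))
    tryCatch(fit1(yy), error = function(e) NA_real_)
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  if (length(boot) < n_boot / 2) {
    stop(structure(class = c("hsp70_fit_failure", "error", "condition"),
                   list(message = "bootstrap refits mostly failed; the grid may not span the binding transition",
                        call = NULL)))
  }
  alpha <- (1 - level) / 2
  t_crit <- stats::qt(1 - alpha, df = length(H) - 1L)
  ci <- exp(log(K_hat) + c(-1, 1) * t_crit * stats::sd(log(boot)))
  if (max(H) < K_hat / 2 || min(H) > K_hat * 2) {
    warning("titration grid does not span the binding transition around the ",
            "fitted K_eff; the estimate is poorly constrained", call. = FALSE)
  }
  list(K_eff_hat = unname(K_hat), CI = ci, level = level,
       n_boot = length(boot))
}
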