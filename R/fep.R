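# Free-energy differences between polymorph ensembles: cross-evaluation of
# EV trajectories under an alternate generator (e.g. a different Z'),
# exponential-averaging (Zwanzig) estimation, harmonic vibrational free
# energies, and the linear fit of the free-energy difference against
# temperature.

#' Zwanzig free-energy difference from energy-difference samples
#'
#' dF = -kB T log < exp(-dU / kB T) >, computed with log-sum-exp
#' stabilization so samples spanning hundreds of kJ/mol stay finite.  The
#' mean energy difference is returned alongside as the customary error
#' proxy, and a delta-method standard error of dF.
#'
#' @param dU Numeric vector of energy differences (target minus base),
#'   kJ/mol, sampled in the base ensemble.
#' @param T Temperature, K.
#' @return List with `dF`, `mean_dU`, `se_dF`, `n`.  The Gibbs-Bogoliubov
#'   bound dF <= <dU> holds for every sample set.
#' @export
#' @examples
#' zwanzig_fed(rep(2, 100), 300)$dF  # constant shift: exactly 2
zwanzig_fed <- function(dU, T) {
  dU <- as.numeric(dU)
  if (length(dU) == 0L || any(!is.finite(dU))) stop("need finite samples")
  if (T <= 0) stop("T must be positive")
  kT <- .kB * T
  n <- length(dU)
  lse <- .logsumexp(-dU / kT) - log(n)
  dF <- -kT * lse
  # delta method on the mean of w = exp(-dU/kT), stabilized
  w <- exp(-dU / kT - lse)   # w / mean(w)
  se <- if (n > 1L) kT * stats::sd(w) / sqrt(n) else NA_real_
  list(dF = dF, mean_dU = mean(dU), se_dF = se, n = n)
}

#' Harmonic vibrational free energy
#'
#' Per-mode F = h_bar w / 2 + kB T log(1 - exp(-h_bar w / kB T)), summed
#' over the spectrum; the T = 0 limit is the zero-point energy sum.
#'
#' @param freq Mode frequencies in cm^-1 (all positive).
#' @param T Temperature, K (>= 0).
#' @return Free energy, kJ/mol.
#' @export
#' @examples
#' vib_free_energy(c(50, 100), 0)  # ZPE
vib_free_energy <- function(freq, T) {
  freq <- as.numeric(freq)
  if (any(freq <= 0)) stop("frequencies must be positive")
  if (T < 0) stop("T must be >= 0")
  e <- freq * .CM1_KJMOL       # h_bar omega as molar energies
  zpe <- sum(e) / 2
  if (T == 0) return(zpe)
  kT <- .kB * T
  zpe + kT * sum(log1p(-exp(-e / kT)))
}

#' Vibrational free-energy difference between two spectra
#'
#' With `approx = "exact"` the difference of the exact harmonic free
#' energies is returned.  Note that in the exact classical limit the
#' zero-point terms cancel out of the linear-in-T behavior (the ln(1 - e^-x)
#' expansion contributes -x/2), so the intercept of a line fitted to the
#' exact difference estimates the quantum correction, not the ZPE
#' difference.  `approx = "high_T"` instead uses the simplified per-mode
#' model F ~ h_bar w / 2 + kB T log(h_bar w / kB T) -- the customary
#' straight-line picture whose intercept is exactly the ZPE difference and
#' whose slope is exactly kB sum log(w_b / w_a).
#'
#' @param freq_a,freq_b Spectra in cm^-1 (equal length for `high_T`).
#' @param T Temperature(s), K (vectorized).
#' @param approx `"exact"` (default) or `"high_T"`.
#' @return dF_vib = F_vib(b) - F_vib(a), kJ/mol.
#' @export
fed_vib <- function(freq_a, freq_b, T, approx = c("exact", "high_T")) {
  approx <- match.arg(approx)
  if (approx == "exact")
    return(vapply(T, function(tt)
      vib_free_energy(freq_b, tt) - vib_free_energy(freq_a, tt), 0))
  ea <- freq_a * .CM1_KJMOL; eb <- freq_b * .CM1_KJMOL
  dzpe <- (sum(eb) - sum(ea)) / 2
  slope <- .kB * sum(log(freq_b / freq_a))
  dzpe + slope * T
}

#' Fit the free-energy difference as a line in temperature
#'
#' Ordinary least squares dF(T) ~ slope * T + intercept.  The intercept is
#' the zero-point-energy difference of the harmonic picture; the root of
#' the line is the predicted transition temperature.
#'
#' @param T Temperatures, K (>= 2 points).
#' @param dF Free-energy differences, kJ/mol.
#' @return Object of class `fed_line_fit` with `slope` (kJ/mol/K),
#'   `intercept` (kJ/mol), `residuals`, `r_squared`, `T_crossing`.
#' @export
fit_fed_line <- function(T, dF) {
  if (length(T) < 2L || length(T) != length(dF))
    stop("need >= 2 matched (T, dF) points")
  fit <- stats::lm(dF ~ T)
  cf <- coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dF - mean(dF))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  slope <- unname(cf[2L]); intercept <- unname(cf[1L])
  structure(list(slope = slope, intercept = intercept,
                 residuals = unname(stats::residuals(fit)),
                 r_squared = r2,
                 T_crossing = if (slope != 0) -intercept / slope
                              else NA_real_),
            class = "fed_line_fit")
}

#' @export
print.fed_line_fit <- function(x, ...) {
  cat(sprintf(
    "dF(T) fit: slope = %.6g kJ/mol/K, intercept (ZPE diff) = %.6g kJ/mol\n",
    x$slope, x$intercept))
  if (is.finite(x$T_crossing) && x$T_crossing > 0)
    cat(sprintf("  crossing at T = %.1f K\n", x$T_crossing))
  invisible(x)
}

#' High-temperature slope of a harmonic free-energy difference
#'
#' In the classical limit the per-mode free energy tends to
#' kB T log(h_bar w / kB T), so the slope of dF_vib(T) tends to
#' kB * sum log(w_b / w_a).
#'
#' @param freq_a,freq_b Spectra in cm^-1 (equal length).
#' @return Slope, kJ/mol/K.
#' @export
fed_vib_high_T_slope <- function(freq_a, freq_b) {
  if (length(freq_a) != length(freq_b)) stop("spectra must match in length")
  .kB * sum(log(freq_b / freq_a))
}

## ---------------------------------------------------------------------------
## Cross-evaluation of trajectories between generators

#' Re-evaluate an EV trajectory under an alternate generator
#'
#' Feeds the extended variables of a Z' = A trajectory back into the
#' polymorph generator configured for Z' = B (B must divide A).  The
#' A-molecule EV cluster is split into A/B sub-clusters of B molecules;
#' each is re-evaluated by a fresh mini-batch and the per-molecule
#' conditional energies are averaged (the stoichiometric reweighting).
#' Energies are normalized per molecule on both sides: u = U_unb +
#' penalty / Z'.
#'
#' @param traj An `evccp_trajectory` from the base (Z' = A) run, crystal
#'   mode.
#' @param cfg_target An [evccp_config()] for the target generator.
#' @param mol,sg_target,bounds,pot Target generator settings.
#' @param zp_target Z' of the target ensemble.
#' @param n_eq Equilibration steps discarded from the head of the
#'   trajectory.
#' @param seed Seed for the target-side mini-batches.
#' @return Data frame with per-step `U_base`, `U_target`, `dU` (kJ/mol per
#'   molecule).
#' @export
crosseval_trajectory <- function(traj, cfg_target, mol, sg_target, bounds,
                                 pot = potential_config(), zp_target,
                                 n_eq = 0L, seed = 1L) {
  steps <- traj$steps
  if (n_eq > 0L) steps <- steps[-seq_len(min(n_eq, length(steps) - 1L))]
  zp_base <- nrow(steps[[1L]]$S$com)
  if (zp_base %% zp_target != 0L)
    stop("target Z' must divide the base Z'")
  nsub <- zp_base %/% zp_target
  stream <- rng_stream(seed)
  out <- data.frame(step = integer(0), U_base = numeric(0),
                    U_target = numeric(0), dU = numeric(0))
  for (srec in steps) {
    S <- srec$S
    u_base <- srec$U_cond / zp_base
    u_tgts <- numeric(nsub)
    for (k in seq_len(nsub)) {
      rows <- ((k - 1L) * zp_target + 1L):(k * zp_target)
      S_sub <- ev_state(S$com[rows, , drop = FALSE],
                        S$euler[rows, , drop = FALSE], box = S$box)
      mb <- mini_batch(S_sub, cfg_target, mol, sg_target, bounds, pot,
                       stream, E_best = Inf,
                       provenance = list(crosseval = TRUE, step = srec$iter,
                                         sub = k))
      u_tgts[k] <- mb$U_cond / zp_target
    }
    out <- rbind(out, data.frame(step = srec$iter, U_base = u_base,
                                 U_target = mean(u_tgts),
                                 dU = mean(u_tgts) - u_base))
  }
  out
}

#' Free-energy-difference study over a temperature ladder
#'
#' For each temperature: run an EVCCP trajectory of the base ensemble from
#' the supplied starting EV, discard equilibration, re-evaluate the EV path
#' under the target generator, and estimate the free-energy difference by
#' exponential averaging; finally fit dF against T as a line.
#'
#' In surrogate mode (`energy_base`/`energy_target` callables on the
#' flattened EV vector) the crystal generator is bypassed and dU is the
#' difference of the two surfaces along the base trajectory.
#'
#' @param temperatures Ladder of temperatures, K.
#' @param S0 Starting `ev_state`.
#' @param base_cfg Template [evccp_config()] for the base ensemble (its `T`
#'   is overridden per run).
#' @param mol,sg_base,sg_target,bounds,pot Crystal-mode settings.
#' @param zp_target Z' of the target ensemble (crystal mode).
#' @param cfg_target Template config for the target-side mini-batches.
#' @param energy_base,energy_target Surrogate callables (both or neither).
#' @param n_eq Equilibration steps discarded.
#' @param seed Master seed.
#' @param step_T_ref Reference temperature of the configured step sizes;
#'   per-run steps are scaled by sqrt(T / step_T_ref).
#' @return Object of class `fed_series`: per-T `mean_dU`, `dF`, `se_dF`,
#'   acceptance rates, plus the [fit_fed_line()] result.
#' @export
run_fed_study <- function(temperatures, S0, base_cfg,
                          mol = NULL, sg_base = NULL, sg_target = NULL,
                          bounds = NULL, pot = potential_config(),
                          zp_target = NULL, cfg_target = base_cfg,
                          energy_base = NULL, energy_target = NULL,
                          n_eq = 0L, seed = 1L, step_T_ref = 300) {
  surrogate <- !is.null(energy_base)
  if (surrogate && is.null(energy_target))
    stop("both surrogate energies are required")
  temperatures <- sort(as.numeric(temperatures))
  res <- data.frame(T = temperatures, mean_dU = NA_real_, dF = NA_real_,
                    se_dF = NA_real_, acceptance = NA_real_)
  master <- rng_stream(seed)
  for (i in seq_along(temperatures)) {
    cfg <- base_cfg
    cfg$T <- temperatures[i]
    # keep the acceptance ratio roughly even across the ladder: random-walk
    # displacements scale with the thermal width, sqrt(T)
    tfac <- sqrt(temperatures[i] / step_T_ref)
    cfg$step_com <- base_cfg$step_com * tfac
    cfg$step_euler <- base_cfg$step_euler * tfac
    cfg$seed <- .spawn_seed(master)
    traj <- run_evccpmc(S0, cfg, mol, sg_base, bounds, pot,
                        objective = if (surrogate) energy_base else NULL)
    if (surrogate) {
      sv <- trajectory_ev(traj)
      if (n_eq > 0L) sv <- sv[-seq_len(min(n_eq, nrow(sv) - 1L)), ,
                              drop = FALSE]
      dU <- apply(sv, 1L, function(v) energy_target(v) - energy_base(v))
    } else {
      ce <- crosseval_trajectory(traj, cfg_target, mol, sg_target, bounds,
                                 pot, zp_target, n_eq = n_eq,
                                 seed = .spawn_seed(master))
      dU <- ce$dU
    }
    z <- zwanzig_fed(dU, temperatures[i])
    res$mean_dU[i] <- z$mean_dU
    res$dF[i] <- z$dF
    # chain samples are autocorrelated: inflate the iid standard error by
    # the integrated autocorrelation time of the Boltzmann weights
    res$se_dF[i] <- z$se_dF * sqrt(.iact(exp(-(dU - min(dU)) /
                                             (.kB * temperatures[i]))))
    res$acceptance[i] <- traj$acceptance_rate
    if (is.finite(res$acceptance[i]) &&
        (res$acceptance[i] < 0.3 || res$acceptance[i] > 0.7))
      warning(sprintf(
        "acceptance rate %.2f at T = %g K outside [0.3, 0.7]; consider retuning step sizes",
        res$acceptance[i], temperatures[i]))
  }
  fit <- fit_fed_line(res$T, res$dF)
  structure(list(series = res, fit = fit, n_eq = n_eq),
            class = "fed_series")
}

# integrated autocorrelation time (initial positive-sequence truncation)
.iact <- function(x, max_lag = min(length(x) - 1L, 200L)) {
  if (length(x) < 10L || stats::sd(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1L]
  pos <- which(rho < 0.05)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  max(1, 1 + 2 * sum(rho))
}

#' @export
print.fed_series <- function(x, ...) {
  cat("Free-energy difference series:\n")
  print(x$series, row.names = FALSE, digits = 5)
  print(x$fit)
  invisible(x)
}
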