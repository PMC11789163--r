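# The core extended-variable coupled crystal polymorph Monte Carlo chain:
# mini-batch generation under fixed S, selection of the mini-batch minimum,
# and Metropolis propagation of S at bath temperature T.

#' EVCCP sampler configuration
#'
#' @param coupling A [coupling_spec()].
#' @param M Mini-batch size: polymorphs minimized per MC step under one S.
#' @param T Bath temperature, K.
#' @param step_com Maximum proposal displacement per center component,
#'   Angstrom.
#' @param step_euler Maximum proposal displacement per Euler component,
#'   degrees.
#' @param E_threshold Pre-rejection threshold, kJ/mol.  `NULL` (default)
#'   keeps an adaptive threshold at `E_margin` above the best unbiased
#'   energy seen so far in the run.
#' @param E_margin Margin for the adaptive threshold, kJ/mol.
#' @param n_steps Number of Metropolis steps.
#' @param seed Integer seed.
#' @param maxit Minimizer iteration cap per batch member.
#' @param retry_cap Redraws allowed per prefiltered batch member.
#' @param smoothing If `TRUE`, the step energy is the log-sum-exp of the
#'   batch at temperature `T` instead of the hard batch minimum.
#' @param kT_step_scaling If `TRUE`, proposal steps are multiplied by
#'   kB*T (temperature-dependent step sizes); default off.
#' @return An object of class `evccp_config`.
#' @export
evccp_config <- function(coupling = coupling_spec(), M = 10L, T = 300,
                         step_com = 0.5, step_euler = 10,
                         E_threshold = NULL, E_margin = 1000,
                         n_steps = 100L, seed = 1L, maxit = 500L,
                         retry_cap = 20L, smoothing = FALSE,
                         kT_step_scaling = FALSE) {
  if (M < 1L) stop("M must be >= 1")
  if (T <= 0) stop("T must be positive")
  if (step_com <= 0 || step_euler <= 0) stop("step sizes must be positive")
  structure(list(coupling = coupling, M = as.integer(M), T = T,
                 step_com = step_com, step_euler = step_euler,
                 E_threshold = E_threshold, E_margin = E_margin,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 maxit = as.integer(maxit), retry_cap = as.integer(retry_cap),
                 smoothing = isTRUE(smoothing),
                 kT_step_scaling = isTRUE(kT_step_scaling)),
            class = "evccp_config")
}

# flatten / unflatten EV states (com rows then euler rows, molecule-major)
.ev_flat <- function(S) c(as.numeric(t(S$com)), as.numeric(t(S$euler)))
.ev_unflat <- function(v, template) {
  zp <- nrow(template$com)
  ev_state(matrix(v[seq_len(3 * zp)], zp, 3, byrow = TRUE),
           matrix(v[3 * zp + seq_len(3 * zp)], zp, 3, byrow = TRUE),
           box = template$box)
}

#' Generate a mini-batch of polymorphs under a fixed EV state
#'
#' For each of the M members a fresh random cell is drawn within bounds,
#' the packing coordinates are seeded at X0 = S, the configuration is
#' pre-filtered against the energy threshold (redrawn up to a retry cap),
#' and the biased objective is locally minimized with S held fixed.
#'
#' @param S An `ev_state`.
#' @param cfg An [evccp_config()].
#' @param mol,sg,pot As in [lattice_energy()].
#' @param bounds A [sampler_bounds()].
#' @param stream An [rng_stream()] (cell draws consume from it).
#' @param E_best Best unbiased energy seen so far (for the adaptive
#'   threshold); `Inf` disables pre-rejection on the first calls.
#' @param provenance Merged into each record's provenance.
#' @return List with `records`, `U_min` (minimum biased energy, the step's
#'   conditional energy), `X_min` (the argmin `packing_state`), `U_cond`
#'   (equal to `U_min`, or the log-sum-exp batch energy when smoothing is
#'   on) and `n_prefiltered`.
#' @export
mini_batch <- function(S, cfg, mol, sg, bounds, pot = potential_config(),
                       stream = rng_stream(cfg$seed), E_best = Inf,
                       provenance = list()) {
  thr <- if (!is.null(cfg$E_threshold)) cfg$E_threshold
         else if (is.finite(E_best)) E_best + cfg$E_margin else Inf
  records <- vector("list", cfg$M)
  n_pref <- 0L
  kept <- 0L
  for (m in seq_len(cfg$M)) {
    ok <- FALSE
    for (try in seq_len(cfg$retry_cap)) {
      cell <- with_stream(stream, function()
        tryCatch(.sample_cell(bounds, sg, nrow(S$com), mol),
                 error = function(e) NULL))
      if (is.null(cell)) next
      start <- packing_state(S$com, S$euler, cell, sg)
      if (!prefilter(start, mol, sg, pot, thr)) { n_pref <- n_pref + 1L; next }
      rec <- local_minimize(start, mol, sg, pot, S = S,
                            coupling = cfg$coupling, bounds = bounds,
                            maxit = cfg$maxit,
                            provenance = c(provenance, list(batch = m)))
      ok <- TRUE
      break
    }
    if (ok) { kept <- kept + 1L; records[[kept]] <- rec }
  }
  if (kept == 0L)
    stop(sprintf(
      "step-infeasible: all %d mini-batch members pre-rejected (threshold %.3g, %d rejections)",
      cfg$M, thr, n_pref))
  records <- records[seq_len(kept)]
  ub <- vapply(records, function(r) r$U_biased, 0)
  i <- which.min(ub)
  U_min <- ub[i]
  U_cond <- if (cfg$smoothing) {
    kT <- .kB * cfg$T
    -kT * (.logsumexp(-ub / kT) - log(length(ub)))
  } else U_min
  list(records = records, U_min = U_min, X_min = records[[i]]$state,
       U_cond = U_cond, n_prefiltered = n_pref)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Evaluate the conditional energy of S: surrogate callable or crystal
# mini-batch.  Returns list(U_cond, records, X_min, n_prefiltered) or NULL
# on a step-infeasible batch.
.eval_S <- function(S, cfg, mol, sg, bounds, pot, stream, E_best,
                    objective = NULL, provenance = list()) {
  if (!is.null(objective)) {
    return(list(U_cond = objective(.ev_flat(S)), records = list(),
                X_min = NULL, n_prefiltered = 0L))
  }
  tryCatch(
    mini_batch(S, cfg, mol, sg, bounds, pot, stream, E_best, provenance),
    error = function(e) {
      if (grepl("step-infeasible", conditionMessage(e))) NULL else stop(e)
    })
}

#' One Metropolis update of the extended variables
#'
#' Proposes S_test = S + dS with each component uniform on
#' (-step, +step), evaluates the conditional energy of the proposal (via a
#' fresh mini-batch, or the surrogate objective), and accepts with
#' probability min(1, exp(-dU / kB T)).  An optional extra bias (the
#' history-dependent kernel potential) is added to both current and test
#' energies.  Step-infeasible proposals count as rejections.
#'
#' @param S_iter Current `ev_state`.
#' @param U_iter Current conditional energy (without extra bias).
#' @param cfg,mol,sg,bounds,pot,stream,E_best As in [mini_batch()].
#' @param objective Optional surrogate energy callable on the flattened EV
#'   vector (bypasses the crystal generator).
#' @param extra_bias Optional function of an `ev_state` returning kJ/mol.
#' @param provenance Passed through to batch records.
#' @return List with `S`, `U_cond`, `accepted`, `eval` (the proposal
#'   evaluation, or NULL if infeasible).
#' @export
metropolis_update <- function(S_iter, U_iter, cfg, mol = NULL, sg = NULL,
                              bounds = NULL, pot = potential_config(),
                              stream = rng_stream(cfg$seed), E_best = Inf,
                              objective = NULL, extra_bias = NULL,
                              provenance = list()) {
  zp <- nrow(S_iter$com)
  scale <- if (cfg$kT_step_scaling) .kB * cfg$T else 1
  d_com <- with_stream(stream, function()
    matrix(runif(zp * 3, -cfg$step_com, cfg$step_com), zp, 3)) * scale
  d_eul <- with_stream(stream, function()
    matrix(runif(zp * 3, -cfg$step_euler, cfg$step_euler), zp, 3)) * scale
  S_test <- ev_state(S_iter$com + d_com, S_iter$euler + d_eul,
                     box = S_iter$box)
  ev <- .eval_S(S_test, cfg, mol, sg, bounds, pot, stream, E_best,
                objective, provenance)
  if (is.null(ev)) {
    return(list(S = S_iter, U_cond = U_iter, accepted = FALSE, eval = NULL,
                infeasible = TRUE))
  }
  b_cur <- if (is.null(extra_bias)) 0 else extra_bias(S_iter)
  b_test <- if (is.null(extra_bias)) 0 else extra_bias(S_test)
  dU <- (ev$U_cond + b_test) - (U_iter + b_cur)
  acc <- if (dU <= 0) TRUE else {
    with_stream(stream, function() runif(1)) < exp(-dU / (.kB * cfg$T))
  }
  if (acc) list(S = S_test, U_cond = ev$U_cond, accepted = TRUE, eval = ev)
  else list(S = S_iter, U_cond = U_iter, accepted = FALSE, eval = ev)
}

#' Run an EVCCP Monte Carlo trajectory
#'
#' Propagates the extended variables for `n_steps` Metropolis updates.
#' Every generated polymorph -- from accepted and rejected proposals alike
#' -- is retained with provenance.
#'
#' @param S0 Initial `ev_state` (typically a known or randomly selected
#'   polymorph's coordinates).
#' @param cfg An [evccp_config()].
#' @param mol,sg,bounds,pot As in [mini_batch()]; ignored in surrogate mode.
#' @param objective Optional surrogate energy callable on the flattened EV
#'   vector; replaces the crystal generator.
#' @param stream Optional [rng_stream()]; defaults to a stream seeded from
#'   `cfg$seed`.
#' @param extra_bias Optional function of an `ev_state` (history bias).
#' @param callback Optional function called as `callback(step_record)` after
#'   each step (used by the replica-exchange driver).
#' @return Object of class `evccp_trajectory`: list with `steps` (each
#'   holding `iter`, `S`, `U_cond`, `accepted`, `records`,
#'   `n_prefiltered`), `acceptance_rate`, `E_best`, and the configuration.
#' @export
run_evccpmc <- function(S0, cfg, mol = NULL, sg = NULL, bounds = NULL,
                        pot = potential_config(), objective = NULL,
                        stream = NULL, extra_bias = NULL, callback = NULL) {
  if (is.null(stream)) stream <- rng_stream(cfg$seed)
  E_best <- Inf
  ev0 <- .eval_S(S0, cfg, mol, sg, bounds, pot, stream, E_best, objective,
                 provenance = list(iter = 0L))
  if (is.null(ev0)) stop("initial EV state is step-infeasible")
  if (length(ev0$records))
    E_best <- min(E_best, min(vapply(ev0$records, function(r) r$U_unb, 0)))
  steps <- vector("list", cfg$n_steps + 1L)
  steps[[1L]] <- list(iter = 0L, S = S0, U_cond = ev0$U_cond,
                      accepted = NA, records = ev0$records,
                      X_min = ev0$X_min, n_prefiltered = ev0$n_prefiltered)
  S <- S0; U <- ev0$U_cond
  n_acc <- 0L
  for (it in seq_len(cfg$n_steps)) {
    up <- metropolis_update(S, U, cfg, mol, sg, bounds, pot, stream, E_best,
                            objective, extra_bias,
                            provenance = list(iter = it))
    S <- up$S; U <- up$U_cond
    recs <- if (is.null(up$eval)) list() else up$eval$records
    if (length(recs))
      E_best <- min(E_best, min(vapply(recs, function(r) r$U_unb, 0)))
    if (isTRUE(up$accepted)) n_acc <- n_acc + 1L
    steps[[it + 1L]] <- list(
      iter = it, S = S, U_cond = U, accepted = up$accepted, records = recs,
      X_min = if (is.null(up$eval)) NULL else up$eval$X_min,
      n_prefiltered = if (is.null(up$eval)) NA_integer_
                      else up$eval$n_prefiltered)
    if (!is.null(callback)) callback(steps[[it + 1L]])
  }
  structure(list(steps = steps, cfg = cfg, E_best = E_best,
                 acceptance_rate = if (cfg$n_steps > 0)
                   n_acc / cfg$n_steps else NA_real_,
                 surrogate = !is.null(objective)),
            class = "evccp_trajectory")
}

#' @export
print.evccp_trajectory <- function(x, ...) {
  cat(sprintf(
    "EVCCP trajectory: %d steps, T = %g K, acceptance = %.3f%s\n",
    x$cfg$n_steps, x$cfg$T,
    x$acceptance_rate, if (x$surrogate) " (surrogate)" else ""))
  if (is.finite(x$E_best)) cat(sprintf("  best U = %.4f kJ/mol\n", x$E_best))
  invisible(x)
}

#' All polymorph records of a trajectory
#'
#' @param traj An `evccp_trajectory`.
#' @return Flat list of `polymorph_record`s in generation order.
#' @export
trajectory_records <- function(traj) {
  do.call(c, lapply(traj$steps, function(s) s$records))
}

#' Conditional-energy trace of a trajectory
#'
#' @param traj An `evccp_trajectory`.
#' @return Numeric vector of U(X,H|S) values, one per step (step 0 first).
#' @export
trajectory_energies <- function(traj) {
  vapply(traj$steps, function(s) s$U_cond, 0)
}

#' Extended-variable trace of a trajectory
#'
#' @param traj An `evccp_trajectory`.
#' @return Matrix, one row per step, of flattened EV coordinates.
#' @export
trajectory_ev <- function(traj) {
  do.call(rbind, lapply(traj$steps, function(s) .ev_flat(s$S)))
}

#' @export
summary.evccp_trajectory <- function(object, ...) {
  u <- trajectory_energies(object)
  recs <- trajectory_records(object)
  cat(sprintf("EVCCP trajectory: %d steps (+initial), %d polymorphs\n",
              object$cfg$n_steps, length(recs)))
  cat(sprintf("  U(X,H|S): min %.4f  mean %.4f  max %.4f kJ/mol\n",
              min(u), mean(u), max(u)))
  cat(sprintf("  acceptance rate: %.3f\n", object$acceptance_rate))
  invisible(list(U_cond = u, n_records = length(recs),
                 acceptance = object$acceptance_rate))
}
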