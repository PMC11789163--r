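# Modified replica exchange over EVCCP chains: only the extended variables
# S swap between temperature baths.  Variants add a history-dependent
# Gaussian bias (MRE1), per-bath forced relaxation to the best basin at the
# start of each cycle (MRE2), or a global relaxation-restart from the fully
# re-minimized unbiased minimum (MRE3).

#' Replica ladder
#'
#' A set of EVCCP baths sharing everything but temperature, plus the
#' exchange schedule.
#'
#' @param base_cfg An [evccp_config()]; per-bath configs copy it and
#'   override `T` (bath seeds are derived deterministically from
#'   `base_cfg$seed`).
#' @param temperatures Strictly increasing bath temperatures, K (>= 2).
#' @param steps MC steps per cycle per bath.
#' @param cycles Number of MC cycles.
#' @param exchange_interval Steps between exchange sweeps.
#' @return Object of class `replica_ladder`.
#' @export
replica_ladder <- function(base_cfg, temperatures, steps = base_cfg$n_steps,
                           cycles = 1L, exchange_interval = 5L) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 2L || any(diff(temperatures) <= 0))
    stop("need >= 2 strictly increasing temperatures")
  baths <- lapply(seq_along(temperatures), function(b) {
    cfg <- base_cfg
    cfg$T <- temperatures[b]
    cfg$n_steps <- as.integer(steps)
    cfg$seed <- as.integer((base_cfg$seed + 7919 * b) %% 2147483647L)
    cfg
  })
  structure(list(baths = baths, temperatures = temperatures,
                 steps = as.integer(steps), cycles = as.integer(cycles),
                 exchange_interval = as.integer(exchange_interval)),
            class = "replica_ladder")
}

#' Geometric temperature ladder
#'
#' Auto-spaced ladder with constant temperature ratio, the standard choice
#' for keeping neighbor exchange acceptance roughly even across the ladder
#' (target near 0.5).
#'
#' @param T_min,T_max Ladder endpoints, K.
#' @param n_baths Number of baths.
#' @return Numeric vector of temperatures.
#' @export
#' @examples
#' tune_ladder(263, 1142, 4)
tune_ladder <- function(T_min, T_max, n_baths) {
  if (T_min <= 0 || T_max <= T_min || n_baths < 2)
    stop("need 0 < T_min < T_max and >= 2 baths")
  T_min * (T_max / T_min)^((seq_len(n_baths) - 1) / (n_baths - 1))
}

#' Attempt an exchange of extended variables between two baths
#'
#' Only S (and its cached conditional energy) swaps; the swap is accepted
#' with probability min(1, exp((beta_i - beta_j)(U_i - U_j))).
#'
#' @param bath_i,bath_j Lists with elements `T`, `S`, `U_cond`.
#' @param stream An [rng_stream()].
#' @return List with updated `bath_i`, `bath_j` and `swapped` flag.
#' @export
attempt_exchange <- function(bath_i, bath_j, stream) {
  bi <- 1 / (.kB * bath_i$T); bj <- 1 / (.kB * bath_j$T)
  larg <- (bi - bj) * (bath_i$U_cond - bath_j$U_cond)
  p <- if (larg >= 0) 1 else exp(larg)
  sw <- with_stream(stream, function() runif(1)) <= p
  if (sw) {
    tmp_S <- bath_i$S; tmp_U <- bath_i$U_cond
    bath_i$S <- bath_j$S; bath_i$U_cond <- bath_j$U_cond
    bath_j$S <- tmp_S; bath_j$U_cond <- tmp_U
  }
  list(bath_i = bath_i, bath_j = bath_j, swapped = sw)
}

## ---------------------------------------------------------------------------
## History bias (MRE1)

#' History-dependent Gaussian bias
#'
#' A metadynamics-style repulsive potential: Gaussian kernels of height `w`
#' are deposited at accepted EV states, penalizing revisits.
#'
#' @param w Kernel height, kJ/mol (>= 0).
#' @param sigma_com Kernel width on center components, Angstrom.
#' @param sigma_euler Kernel width on Euler components, degrees.
#' @param cap Maximum number of kernels kept (FIFO).
#' @return An environment of class `history_bias`.
#' @export
history_bias <- function(w = 2, sigma_com = 0.5, sigma_euler = 10,
                         cap = 2000L) {
  if (w < 0) stop("w must be >= 0")
  if (sigma_com <= 0 || sigma_euler <= 0) stop("widths must be positive")
  e <- new.env(parent = emptyenv())
  e$w <- w; e$sigma_com <- sigma_com; e$sigma_euler <- sigma_euler
  e$cap <- as.integer(cap)
  e$centers <- NULL   # rows = flattened EVs
  class(e) <- "history_bias"
  e
}

#' Evaluate the history bias at an EV state
#'
#' @param S An `ev_state`.
#' @param bias A [history_bias()].
#' @return Bias energy, kJ/mol (0 for an empty history).
#' @export
history_bias_energy <- function(S, bias) {
  if (is.null(bias$centers) || nrow(bias$centers) == 0L) return(0)
  v <- .ev_flat(S)
  d <- length(v)
  ncom <- d / 2
  dv <- sweep(bias$centers, 2L, v)
  dv[, (ncom + 1):d] <- (dv[, (ncom + 1):d] + 180) %% 360 - 180
  dv[, 1:ncom] <- dv[, 1:ncom] / bias$sigma_com
  dv[, (ncom + 1):d] <- dv[, (ncom + 1):d] / bias$sigma_euler
  sum(bias$w * exp(-rowSums(dv^2) / 2))
}

#' Deposit a kernel at an EV state
#'
#' @param bias A [history_bias()].
#' @param S An `ev_state`.
#' @return The bias, invisibly.
#' @export
deposit_kernel <- function(bias, S) {
  v <- .ev_flat(S)
  bias$centers <- rbind(bias$centers, v)
  if (nrow(bias$centers) > bias$cap)
    bias$centers <- bias$centers[-1L, , drop = FALSE]
  invisible(bias)
}

## ---------------------------------------------------------------------------
## Replica-exchange driver

#' Run a modified replica-exchange search
#'
#' Round-robin Metropolis steps over the temperature baths with periodic
#' exchange sweeps of the extended variables (nearest-neighbor pairs,
#' alternating parity).  Variants: `"MRE0"` plain exchange; `"MRE1"` adds
#' the history bias; `"MRE2"` resets each bath's S to its best-seen basin at
#' the start of every cycle after the first; `"MRE3"` instead re-minimizes
#' the archived candidates with tightened tolerances after every cycle and
#' restarts all baths from the unbiased global minimum.
#'
#' @param variant One of "MRE0", "MRE1", "MRE2", "MRE3".
#' @param ladder A [replica_ladder()].
#' @param mol,sg,bounds,pot As in [mini_batch()]; ignored in surrogate mode.
#' @param S0 Initial `ev_state` shared by all baths.
#' @param objective Optional surrogate energy callable (flattened EV
#'   vector); replaces the crystal generator.
#' @param exchange If `FALSE`, no exchange sweeps are performed (each bath
#'   is then an independent EVCCP chain, bit-identical to [run_evccpmc()]
#'   at the bath's seed).
#' @param bias A [history_bias()] used when `variant = "MRE1"`.
#' @param re_evaluate_on_swap If `TRUE`, conditional energies are recomputed
#'   by a fresh mini-batch after each accepted swap instead of swapping the
#'   cached values.
#' @param restart_pool Number of lowest-energy archived candidates
#'   re-minimized during an MRE3 restart.
#' @return Object of class `mre_result`: per-bath trajectories, the merged
#'   record stream (`records`; per-step proposal batches only, so
#'   `baths * steps * cycles * M` records absent prefilter losses, with the
#'   initial evaluations under `initial_records`), exchange statistics and
#'   the archive.
#' @export
run_mre <- function(variant = c("MRE0", "MRE1", "MRE2", "MRE3"),
                    ladder, mol = NULL, sg = NULL, bounds = NULL,
                    pot = potential_config(), S0, objective = NULL,
                    exchange = TRUE, bias = history_bias(),
                    re_evaluate_on_swap = FALSE, restart_pool = 20L) {
  variant <- match.arg(variant)
  nb <- length(ladder$baths)
  ex_stream <- rng_stream(ladder$baths[[1L]]$seed + 104729L)
  baths <- vector("list", nb)
  extra <- if (variant == "MRE1")
    function(S) history_bias_energy(S, bias) else NULL

  merged <- vector("list", length(ladder$baths) *
                             (ladder$cycles * ladder$steps + 2L))
  n_merged <- 0L
  initial_records <- list()
  for (b in seq_len(nb)) {
    cfg <- ladder$baths[[b]]
    stream <- rng_stream(cfg$seed)
    ev0 <- .eval_S(S0, cfg, mol, sg, bounds, pot, stream, Inf, objective,
                   provenance = list(replica = b, cycle = 0L, iter = 0L))
    if (is.null(ev0)) stop("initial EV state is step-infeasible")
    E_best <- if (length(ev0$records))
      min(vapply(ev0$records, function(r) r$U_unb, 0)) else Inf
    steps0 <- vector("list", ladder$cycles * ladder$steps + 1L)
    steps0[[1L]] <- list(iter = 0L, cycle = 0L, S = S0, U_cond = ev0$U_cond,
                         accepted = NA)
    bt <- new.env(parent = emptyenv())
    bt$cfg <- cfg; bt$stream <- stream; bt$S <- S0; bt$U_cond <- ev0$U_cond
    bt$E_best <- E_best; bt$n_acc <- 0L; bt$n_steps <- 0L
    bt$best <- list(S = S0, U_cond = ev0$U_cond, X_min = ev0$X_min,
                    U_unb = E_best)
    bt$steps <- steps0
    baths[[b]] <- bt
    initial_records <- c(initial_records, ev0$records)
    if (variant == "MRE1") deposit_kernel(bias, S0)
  }

  ex_attempt <- 0L; ex_acc <- 0L
  sweep_no <- 0L
  global_step <- 0L

  for (cyc in seq_len(ladder$cycles)) {
    if (cyc > 1L && variant == "MRE2")
      baths <- forced_relaxation(baths)
    if (cyc > 1L && variant == "MRE3") {
      rr <- relaxation_restart(baths, merged, mol, sg, bounds, pot,
                               restart_pool = restart_pool)
      baths <- rr$baths
    }
    for (st in seq_len(ladder$steps)) {
      global_step <- global_step + 1L
      for (b in seq_len(nb)) {
        bt <- baths[[b]]
        up <- metropolis_update(
          bt$S, bt$U_cond, bt$cfg, mol, sg, bounds, pot, bt$stream,
          bt$E_best, objective, extra,
          provenance = list(replica = b, cycle = cyc, iter = global_step))
        bt$S <- up$S; bt$U_cond <- up$U_cond
        bt$n_steps <- bt$n_steps + 1L
        if (isTRUE(up$accepted)) {
          bt$n_acc <- bt$n_acc + 1L
          if (variant == "MRE1") deposit_kernel(bias, bt$S)
        }
        if (!is.null(up$eval)) {
          recs <- up$eval$records
          if (length(recs)) {
            u <- vapply(recs, function(r) r$U_unb, 0)
            bt$E_best <- min(bt$E_best, min(u))
            n_merged <- n_merged + 1L
            merged[[n_merged]] <- recs
          }
          if (up$eval$U_cond < bt$best$U_cond ||
              (isTRUE(up$accepted) && bt$U_cond < bt$best$U_cond)) {
            bt$best <- list(S = up$S, U_cond = up$eval$U_cond,
                            X_min = up$eval$X_min,
                            U_unb = if (length(up$eval$records))
                              min(vapply(up$eval$records,
                                         function(r) r$U_unb, 0))
                            else up$eval$U_cond)
          }
        }
        bt$steps[[global_step + 1L]] <-
          list(iter = global_step, cycle = cyc, S = bt$S,
               U_cond = bt$U_cond, accepted = up$accepted)
      }
      if (exchange && global_step %% ladder$exchange_interval == 0L) {
        sweep_no <- sweep_no + 1L
        first <- if (sweep_no %% 2L == 1L) 1L else 2L
        ii <- if (first > nb - 1L) integer(0)
              else seq(first, nb - 1L, by = 2L)
        for (i in ii) {
          ex_attempt <- ex_attempt + 1L
          res <- attempt_exchange(
            list(T = baths[[i]]$cfg$T, S = baths[[i]]$S,
                 U_cond = baths[[i]]$U_cond),
            list(T = baths[[i + 1L]]$cfg$T, S = baths[[i + 1L]]$S,
                 U_cond = baths[[i + 1L]]$U_cond),
            ex_stream)
          if (res$swapped) {
            ex_acc <- ex_acc + 1L
            baths[[i]]$S <- res$bath_i$S
            baths[[i + 1L]]$S <- res$bath_j$S
            if (re_evaluate_on_swap && is.null(objective)) {
              for (k in c(i, i + 1L)) {
                ev <- .eval_S(baths[[k]]$S, baths[[k]]$cfg, mol, sg, bounds,
                              pot, baths[[k]]$stream, baths[[k]]$E_best,
                              objective,
                              provenance = list(replica = k, cycle = cyc,
                                                iter = global_step,
                                                swap_reeval = TRUE))
                if (!is.null(ev)) {
                  baths[[k]]$U_cond <- ev$U_cond
                  if (length(ev$records)) {
                    n_merged <- n_merged + 1L
                    merged[[n_merged]] <- ev$records
                  }
                }
              }
            } else {
              baths[[i]]$U_cond <- res$bath_i$U_cond
              baths[[i + 1L]]$U_cond <- res$bath_j$U_cond
            }
          }
        }
      }
    }
  }

  merged <- do.call(c, merged[seq_len(n_merged)])
  if (is.null(merged)) merged <- list()
  structure(list(
    variant = variant, baths = baths, records = merged,
    initial_records = initial_records,
    temperatures = ladder$temperatures,
    exchange = exchange,
    exchange_attempts = ex_attempt, exchange_accepted = ex_acc,
    exchange_rate = if (ex_attempt > 0) ex_acc / ex_attempt else NA_real_,
    bias = if (variant == "MRE1") bias else NULL),
    class = "mre_result")
}

#' @export
print.mre_result <- function(x, ...) {
  cat(sprintf("%s run: %d baths (%s K), %d polymorphs archived\n",
              x$variant, length(x$baths),
              paste(signif(x$temperatures, 4), collapse = ", "),
              length(x$records)))
  if (!is.na(x$exchange_rate))
    cat(sprintf("  exchange acceptance: %.3f (%d/%d)\n", x$exchange_rate,
                x$exchange_accepted, x$exchange_attempts))
  invisible(x)
}

#' Forced relaxation (MRE2 move)
#'
#' Resets each bath's extended variables to the bath's best-seen basin (the
#' step with the lowest conditional energy so far).  With an empty archive
#' the move is a no-op.
#'
#' @param baths Internal per-bath state list (environments, as carried by
#'   [run_mre()]).
#' @return The baths, updated in place.
#' @export
forced_relaxation <- function(baths) {
  for (b in seq_along(baths)) {
    best <- baths[[b]]$best
    if (is.null(best)) next
    baths[[b]]$S <- best$S
    baths[[b]]$U_cond <- best$U_cond
  }
  baths
}

#' Relaxation restart (MRE3 move)
#'
#' Re-minimizes the lowest-energy archived candidates with tightened
#' tolerances, selects the unbiased global minimum, and resets every bath's
#' extended variables to its packing coordinates.
#'
#' @param baths Internal per-bath state list.
#' @param records Archived `polymorph_record`s from the completed cycles.
#' @param mol,sg,bounds,pot As in [local_minimize()].
#' @param restart_pool Number of candidates (by unbiased energy)
#'   re-minimized.
#' @return List with updated `baths`, the winning `record`, and the
#'   re-minimized `candidates`.
#' @export
relaxation_restart <- function(baths, records, mol, sg, bounds = NULL,
                               pot = potential_config(), restart_pool = 20L) {
  if (length(records) == 0L) return(list(baths = baths, record = NULL,
                                         candidates = list()))
  u <- vapply(records, function(r) r$U_unb, 0)
  pool <- records[order(u)[seq_len(min(restart_pool, length(records)))]]
  cand <- lapply(pool, function(r)
    local_minimize(r$state, mol, sg, pot, bounds = bounds, maxit = 2000L,
                   grad_tol = 1e-3,
                   provenance = c(r$provenance, list(restart_reopt = TRUE))))
  uu <- vapply(cand, function(r) r$U_unb, 0)
  win <- cand[[which.min(uu)]]
  box <- baths[[1L]]$S$box
  S_new <- as_ev_state(win$state, box = box)
  for (b in seq_along(baths)) {
    baths[[b]]$S <- S_new
    baths[[b]]$U_cond <- win$U_unb
    baths[[b]]$best <- list(S = S_new, U_cond = win$U_unb,
                            X_min = win$state, U_unb = win$U_unb)
  }
  list(baths = baths, record = win, candidates = cand)
}
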