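# Pseudo-random structure generation, biased/unbiased local minimization,
# threshold pre-rejection, and duplicate clustering.

#' Sampler bounds
#'
#' Ranges for the pseudo-random generator: per-parameter cell-length range,
#' a density window enforced by rejection, centers uniform in the cell and
#' Euler angles uniform on [0, 360).
#'
#' @param cell_min,cell_max Cell length range, Angstrom (applied to each
#'   free length).
#' @param rho_min,rho_max Density window, g/cm^3.
#' @param angle_min,angle_max Range for free cell angles, degrees.
#' @return An object of class `sampler_bounds`.
#' @export
sampler_bounds <- function(cell_min = 3, cell_max = 12,
                           rho_min = 0.2, rho_max = 3,
                           angle_min = 60, angle_max = 120) {
  if (cell_min <= 0 || cell_max <= cell_min) stop("bad cell length range")
  if (rho_min >= rho_max) stop("rho_min must be < rho_max")
  structure(list(cell_min = cell_min, cell_max = cell_max,
                 rho_min = rho_min, rho_max = rho_max,
                 angle_min = angle_min, angle_max = angle_max),
            class = "sampler_bounds")
}

# Draw a cell satisfying the group constraints and density window.
.sample_cell <- function(bounds, sg, zp, mol, max_tries = 1000L) {
  free <- free_cell_params(sg)
  for (i in seq_len(max_tries)) {
    cell <- c(0, 0, 0, 90, 90, 90)
    for (f in free) {
      cell[f] <- if (f <= 3) runif(1, bounds$cell_min, bounds$cell_max)
                 else runif(1, bounds$angle_min, bounds$angle_max)
    }
    cell <- apply_cell_constraints(cell, sg)
    v2 <- tryCatch(cell_volume(cell), error = function(e) NA_real_)
    if (!is.finite(v2) || v2 <= 0) next
    rho <- sg$n_ops * zp * mol$molar_mass / (.AVOGADRO * v2 * 1e-24)
    if (rho >= bounds$rho_min && rho <= bounds$rho_max) return(cell)
  }
  stop("bounds-infeasible: ", max_tries,
       " consecutive density rejections while sampling a cell")
}

#' Draw a random packing state
#'
#' Cell parameters are uniform within their ranges subject to the space
#' group's constraints and the density window (rejection sampling); centers
#' are uniform in the cell; Euler angles are uniform.
#'
#' @param bounds A [sampler_bounds()].
#' @param sg A `space_group`.
#' @param zp Z', molecules in the asymmetric unit.
#' @param mol The `rigid_molecule` (for the density window).
#' @return A `packing_state`.
#' @export
sample_random_start <- function(bounds, sg, zp, mol) {
  cell <- .sample_cell(bounds, sg, zp, mol)
  H <- cell_matrix(cell)
  f <- matrix(runif(zp * 3), zp, 3)
  com <- f %*% H
  euler <- matrix(runif(zp * 3, 0, 360), zp, 3)
  packing_state(com, euler, cell, sg)
}

#' Construct a polymorph record
#'
#' @param state Minimized `packing_state`.
#' @param U_unb Unbiased lattice energy, kJ/mol per molecule.
#' @param penalty Harmonic coupling penalty, kJ/mol.
#' @param converged Logical convergence flag.
#' @param provenance Named list (run id, step, batch index, replica, ...).
#' @param seed Seed associated with the generating draw, if any.
#' @return An object of class `polymorph_record`.
#' @export
polymorph_record <- function(state, U_unb, penalty = 0, converged = TRUE,
                             provenance = list(), seed = NA_integer_) {
  structure(list(state = state, U_unb = U_unb, penalty = penalty,
                 U_biased = U_unb + penalty, converged = converged,
                 provenance = provenance, seed = seed),
            class = "polymorph_record")
}

#' @export
print.polymorph_record <- function(x, ...) {
  cat(sprintf(
    "Polymorph: U = %.4f kJ/mol (penalty %.4f), %s\n", x$U_unb, x$penalty,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Locally minimize a packing state
#'
#' Quasi-Newton (L-BFGS-B) minimization of the lattice energy -- or, when an
#' EV state is supplied, of the biased objective U(X,H) + harmonic penalty
#' with S held fixed -- over the centers, Euler angles and free cell
#' parameters.  Gradients are central finite differences evaluated in
#' compiled code.  Cell parameters are box-constrained to keep the cell
#' non-degenerate; centers and angles are unconstrained.
#'
#' @param start A `packing_state`.
#' @param mol,sg,pot As in [lattice_energy()].
#' @param S Optional `ev_state`; requires `coupling`.
#' @param coupling Optional [coupling_spec()].
#' @param bounds Optional [sampler_bounds()] used to set the cell box
#'   constraints (widened by 50%).
#' @param maxit Maximum L-BFGS-B iterations.
#' @param grad_tol Per-coordinate gradient target (kJ/mol per Angstrom or
#'   degree): the optimizer stops at this projected-gradient norm and the
#'   record is flagged converged when the final gradient is within 3x of
#'   it.  The default 1e-2 moves energies by far less than the duplicate
#'   tolerance; reference-polymorph polishing uses a tighter value.
#' @param provenance,seed Stored on the record.
#' @return A `polymorph_record`; non-converged results are flagged, never
#'   dropped.
#' @export
local_minimize <- function(start, mol, sg, pot = potential_config(),
                           S = NULL, coupling = NULL,
                           bounds = NULL, maxit = 500L, grad_tol = 1e-2,
                           provenance = list(), seed = NA_integer_) {
  if (!is.null(S) && is.null(coupling))
    stop("coupling must be supplied together with S")
  if (!is.null(coupling) && coupling$k_com == 0 && coupling$k_euler == 0)
    S_eff <- NULL
  else S_eff <- S
  zp <- nrow(start$com)
  sys <- .build_sys(mol, sg, pot, zp, start$cell, S = S_eff,
                    coupling = coupling, clamp = TRUE)
  par0 <- .pack_par(start, sg)
  free <- free_cell_params(sg)
  n <- length(par0)
  lower <- rep(-Inf, n); upper <- rep(Inf, n)
  bl <- if (is.null(bounds)) sampler_bounds() else bounds
  span <- bl$cell_max - bl$cell_min
  for (i in seq_along(free)) {
    j <- 6 * zp + i
    if (free[i] <= 3) {
      lower[j] <- max(1, bl$cell_min - 0.5 * span)
      upper[j] <- bl$cell_max + 0.5 * span
    } else {
      lower[j] <- 40; upper[j] <- 140
    }
  }
  fit <- stats::optim(par0, fn = cpp_energy_total, gr = cpp_energy_grad,
                      sys = sys, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e7,
                                     pgtol = grad_tol))
  g <- cpp_energy_grad(fit$par, sys)
  converged <- fit$convergence == 0L && max(abs(g)) <= 3 * grad_tol
  up <- .unpack_par(fit$par, zp, sg, start$cell)
  state <- packing_state(up$com, up$euler, up$cell, sg)
  sys_exact <- .build_sys(mol, sg, pot, zp, state$cell, S = S_eff,
                          coupling = coupling, clamp = FALSE)
  e <- cpp_energy_terms(.pack_par(state, sg), sys_exact)
  polymorph_record(state, U_unb = e[1], penalty = e[2],
                   converged = converged, provenance = provenance,
                   seed = seed)
}

#' Energy threshold pre-rejection
#'
#' Accepts a candidate only if the lattice energy of the unoptimized
#' configuration with X set to the test EV coordinates is at most
#' `E_threshold`, so hopeless starts are rejected before any minimization.
#'
#' @param state The trial `packing_state` (X = S_test, random H).
#' @param mol,sg,pot As in [lattice_energy()].
#' @param E_threshold Threshold, kJ/mol per molecule.
#' @return Logical.
#' @export
prefilter <- function(state, mol, sg, pot = potential_config(),
                      E_threshold = Inf) {
  if (is.na(E_threshold)) stop("E_threshold must not be NA")
  u <- lattice_energy(state, mol, sg, pot)
  is.finite(u) && u <= E_threshold
}

## ---------------------------------------------------------------------------
## Duplicate detection

#' Duplicate tolerances
#'
#' @param tol_E Energy tolerance, kJ/mol.
#' @param tol_len Cell length tolerance, Angstrom.
#' @param tol_ang Cell angle tolerance, degrees.
#' @param tol_r Center RMSD tolerance, Angstrom.
#' @return A named list.
#' @export
duplicate_tol <- function(tol_E = 0.1, tol_len = 0.1, tol_ang = 0.5,
                          tol_r = 0.3) {
  list(tol_E = tol_E, tol_len = tol_len, tol_ang = tol_ang, tol_r = tol_r)
}

# Best center RMSD between two packings of the same (mol, sg, Z'), taken
# over symmetry images of b, molecule permutations, an aligning origin
# shift, and minimum-image wrapping.
.match_rmsd_com <- function(a, b, sg) {
  Ha <- cell_matrix(a$cell)
  fa <- (a$com %*% solve(Ha)) %% 1
  fb0 <- b$com %*% solve(cell_matrix(b$cell))
  zp <- nrow(fa)
  perms <- .permutations(zp)
  best <- Inf
  for (op in sg$ops) {
    fb <- t(op$W %*% t(fb0) + op$t) %% 1
    for (p in perms) {
      dmat <- fa - fb[p, , drop = FALSE]
      # align on the first molecule, wrap residuals to nearest image
      dmat <- sweep(dmat, 2L, dmat[1L, ])
      dmat <- dmat - round(dmat)
      cart <- dmat %*% Ha
      r <- sqrt(mean(rowSums(cart^2)))
      if (r < best) best <- r
    }
  }
  best
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, (seq_len(n)[-i])[rest])
    }
  }
  out
}

#' Are two polymorph records duplicates?
#'
#' Records are duplicates iff their unbiased energies and their
#' Niggli-reduced cell parameters agree within tolerance, and -- when the two
#' records share the same cell setting -- the best-matching center RMSD
#' (over symmetry images, molecule permutations and lattice translations) is
#' below tolerance.  Comparing reduced cells merges re-descriptions of one
#' lattice in different basis settings, where a direct coordinate match is
#' not meaningful.
#'
#' @param a,b `polymorph_record`s sharing molecule, space group and Z'.
#' @param sg The shared `space_group`.
#' @param tol A [duplicate_tol()] list.
#' @return Logical.
#' @export
is_duplicate <- function(a, b, sg, tol = duplicate_tol()) {
  if (abs(a$U_unb - b$U_unb) >= tol$tol_E) return(FALSE)
  ra <- niggli_reduce(a$state$cell)
  rb <- niggli_reduce(b$state$cell)
  dr <- abs(ra - rb)
  if (any(dr[1:3] >= tol$tol_len) || any(dr[4:6] >= tol$tol_ang))
    return(FALSE)
  dc <- abs(a$state$cell - b$state$cell)
  same_setting <- all(dc[1:3] < tol$tol_len) && all(dc[4:6] < tol$tol_ang)
  if (!same_setting) return(TRUE)
  .match_rmsd_com(a$state, b$state, sg) < tol$tol_r
}

#' Remove duplicate polymorph records
#'
#' Greedy clustering in order of increasing energy; each cluster keeps its
#' lowest-energy representative.
#'
#' @param records List of `polymorph_record`s.
#' @param sg The shared `space_group`.
#' @param tol A [duplicate_tol()] list.
#' @return List of distinct records (lowest-energy representatives),
#'   ordered by energy.
#' @export
deduplicate <- function(records, sg, tol = duplicate_tol()) {
  if (length(records) == 0L) return(records)
  ord <- order(vapply(records, function(r) r$U_unb, 0))
  records <- records[ord]
  keep <- list()
  energies <- numeric(0)
  for (r in records) {
    if (!is.finite(r$U_unb)) next
    dup <- FALSE
    cand <- which(abs(energies - r$U_unb) < tol$tol_E)
    for (i in cand) {
      if (is_duplicate(keep[[i]], r, sg, tol)) { dup <- TRUE; break }
    }
    if (!dup) {
      keep[[length(keep) + 1L]] <- r
      energies <- c(energies, r$U_unb)
    }
  }
  keep
}

## ---------------------------------------------------------------------------
## Pseudo-random search

#' Pseudo-random polymorph search
#'
#' The unbiased baseline: N independent draws from the random generator,
#' each locally minimized.
#'
#' @param n Number of sample-minimize trials.
#' @param bounds A [sampler_bounds()].
#' @param mol,sg,pot As in [lattice_energy()].
#' @param zp Z'.
#' @param seed Integer seed (a private RNG stream is used).
#' @param maxit Minimizer iteration cap.
#' @param run_id Stored in each record's provenance.
#' @return Object of class `pr_search` (list of `polymorph_record`s plus
#'   metadata).
#' @export
pr_search <- function(n, bounds, mol, sg, zp, pot = potential_config(),
                      seed = 1L, maxit = 500L, run_id = "pr") {
  stopifnot(n >= 1)
  stream <- rng_stream(seed)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    start <- with_stream(stream, function()
      sample_random_start(bounds, sg, zp, mol))
    records[[i]] <- local_minimize(start, mol, sg, pot, bounds = bounds,
                                   maxit = maxit,
                                   provenance = list(run = run_id, trial = i),
                                   seed = seed)
  }
  structure(list(records = records, n = n, seed = seed, sg = sg$symbol,
                 zp = zp, molecule = mol$label),
            class = "pr_search")
}

#' @export
print.pr_search <- function(x, ...) {
  u <- vapply(x$records, function(r) r$U_unb, 0)
  cat(sprintf("Pseudo-random search: N = %d, %s, Z' = %d\n", x$n, x$sg,
              x$zp))
  cat(sprintf("  E_min = %.4f, mean E = %.4f kJ/mol\n",
              min(u), mean(u[is.finite(u)])))
  invisible(x)
}

#' Post-process archived records to full unbiased convergence
#'
#' Sampler archives hold structures minimized under the harmonic EV bias;
#' for landscape statistics and hit counting each record is re-minimized on
#' the unbiased surface (the usual post-processing stage: chains do not
#' fully converge structures on the fly).
#'
#' @param records List of `polymorph_record`s (or an object carrying
#'   `records`).
#' @param mol,sg,pot,bounds,maxit,grad_tol As in [local_minimize()].
#' @return List of re-minimized `polymorph_record`s (same order).
#' @export
postprocess_records <- function(records, mol, sg, pot = potential_config(),
                                bounds = NULL, maxit = 500L,
                                grad_tol = 1e-2) {
  if (!is.null(records$records)) records <- records$records
  lapply(records, function(r)
    local_minimize(r$state, mol, sg, pot, bounds = bounds, maxit = maxit,
                   grad_tol = grad_tol,
                   provenance = c(r$provenance, list(postprocessed = TRUE)),
                   seed = r$seed))
}

#' Unbiased energies of a record collection
#'
#' @param records A list of `polymorph_record`s, or an object carrying a
#'   `records` element (`pr_search`, trajectories, MRE results).
#' @return Numeric vector of U_unb values.
#' @export
record_energies <- function(records) {
  if (!is.null(records$records)) records <- records$records
  vapply(records, function(r) r$U_unb, 0)
}
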