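# Synthetic test systems: toy rigid molecules, reference polymorphs obtained
# by seeded searches, and analytic surrogate EV systems.  These stand in for
# a real benchmark compound: parameter values are chosen for numerical
# robustness, not chemical realism.

#' Toy rigid molecules
#'
#' * `"atom"`: one LJ site (eps = 1 kJ/mol, sigma = 3.4 A, M = 40 g/mol).
#' * `"bent"`: a bent triatomic (bond 1.5 A, angle 105 degrees), uniform LJ
#'   sites, M = 60.
#' * `"bent_charged"`: the bent triatomic with charges (-0.2, +0.4, -0.2) e
#'   for Coulomb-path coverage.
#' * `"planar5"`: a planar 5-site ring (radius 1.4 A), M = 120 -- the
#'   "small aromatic" stand-in.
#'
#' @param name Molecule name.
#' @return A [rigid_molecule()].
#' @export
fixture_molecule <- function(name = c("atom", "bent", "bent_charged",
                                      "planar5")) {
  name <- match.arg(name)
  switch(name,
    atom = rigid_molecule("atom", matrix(0, 1, 3), 1, 3.4, 0, 40),
    bent = rigid_molecule("bent", .bent_sites(), 1, 3.4, 0, 60),
    bent_charged = rigid_molecule("bent_charged", .bent_sites(), 1, 3.4,
                                  c(-0.2, 0.4, -0.2), 60),
    planar5 = {
      th <- 2 * pi * (0:4) / 5
      rigid_molecule("planar5", cbind(1.4 * cos(th), 1.4 * sin(th), 0),
                     1, 3.4, 0, 120)
    })
}

.bent_sites <- function() {
  ang <- 105 * pi / 180
  rbind(c(0, 0, 0),
        c(1.5, 0, 0),
        c(1.5 * cos(ang), 1.5 * sin(ang), 0))
}

#' Sampler bounds adapted to a fixture system
#'
#' Sets the cell-length range and density window so random cells pack the
#' molecule at plausible fractions of the close-packed LJ density.
#'
#' @param mol A `rigid_molecule`.
#' @param sg A `space_group`.
#' @param zp Z'.
#' @return A [sampler_bounds()].
#' @export
fixture_bounds <- function(mol, sg, zp) {
  ns <- nrow(mol$sites)
  sig <- max(mol$sigma)
  # effective molecular volume: one sigma-cube for the first site plus a
  # fraction for each fused neighbor
  v_mol <- sig^3 * (1 + 0.45 * (ns - 1))
  v_cell <- sg$n_ops * zp * v_mol
  rho_cp <- sg$n_ops * zp * mol$molar_mass / (.AVOGADRO * v_cell * 1e-24)
  a_ref <- v_cell^(1 / 3)
  sampler_bounds(cell_min = max(2.5, 0.45 * a_ref), cell_max = 2.2 * a_ref,
                 rho_min = 0.55 * rho_cp, rho_max = 1.25 * rho_cp,
                 angle_min = 60, angle_max = 120)
}

# session cache for reference polymorphs
.fixture_cache <- new.env(parent = emptyenv())

#' Reference polymorph of a fixture system
#'
#' Runs a seeded pseudo-random search, deduplicates, and returns the global
#' minimum: the "known form" used to seed EV chains.  Results are cached
#' per session.
#'
#' @param mol A `rigid_molecule`.
#' @param sg A `space_group`.
#' @param zp Z'.
#' @param seed Seed of the generating search.
#' @param n Search size.
#' @param pot A [potential_config()].
#' @param bounds Optional [sampler_bounds()].
#' @return A `polymorph_record` that re-minimizes to itself.
#' @export
make_reference_polymorph <- function(mol, sg, zp, seed = 20240101L, n = 200L,
                                     pot = potential_config(),
                                     bounds = fixture_bounds(mol, sg, zp)) {
  key <- paste(mol$label, sg$symbol, zp, seed, n, pot$cutoff, sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  search <- pr_search(n, bounds, mol, sg, zp, pot, seed = seed,
                      run_id = "fixture")
  distinct <- deduplicate(search$records, sg)
  distinct <- Filter(function(r) isTRUE(r$converged), distinct)
  if (length(distinct) == 0L)
    stop("fixture-generation error: no converged structure found")
  best <- distinct[[1L]]
  # polish with tight tolerances so the record is a fixed point
  best <- local_minimize(best$state, mol, sg, pot, bounds = bounds,
                         maxit = 2000L, grad_tol = 1e-3,
                         provenance = list(run = "fixture", polished = TRUE),
                         seed = seed)
  .fixture_cache[[key]] <- best
  best
}

#' Distinct minima of a fixture system
#'
#' Seeded search + deduplication; used to pick "common" and "rare" minima
#' for sampler benchmarks.
#'
#' @inheritParams make_reference_polymorph
#' @return List of distinct `polymorph_record`s ordered by energy.
#' @export
fixture_minima <- function(mol, sg, zp, seed = 20240101L, n = 200L,
                           pot = potential_config(),
                           bounds = fixture_bounds(mol, sg, zp)) {
  key <- paste("minima", mol$label, sg$symbol, zp, seed, n, pot$cutoff,
               sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  search <- pr_search(n, bounds, mol, sg, zp, pot, seed = seed,
                      run_id = "fixture")
  distinct <- deduplicate(search$records, sg)
  distinct <- Filter(function(r) isTRUE(r$converged), distinct)
  .fixture_cache[[key]] <- distinct
  distinct
}

#' Analytic surrogate EV system
#'
#' Thin wrapper over [surrogate_surface()] that also returns the closed-form
#' facts needed by statistical tests (stationary variances, free-energy
#' differences, enumerated minima).
#'
#' @param name Surface name; see [surrogate_surface()].
#' @param params Parameter overrides.
#' @param seed Seed for the roughened surface's bumps.
#' @return List with `energy` (and `energy_b` for the pair), `facts`.
#' @export
make_surrogate_ev_system <- function(name, params = list(), seed = 42L) {
  params$seed <- params$seed %||% seed
  surrogate_surface(name, params)
}
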