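# The potential energy surface U(X,H), the harmonic EV coupling, and the
# analytic surrogate surfaces used for exact testing.

#' Potential configuration
#'
#' Settings of the site-site Lennard-Jones + Coulomb lattice-energy backend.
#' The backend replaces a force field: the sampling machinery is
#' potential-agnostic, and any callable with the same contract can be
#' substituted.  Electrostatics are plain real-space truncated Coulomb (no
#' Ewald); shipped fixtures keep charges zero or small so the cutoff
#' suffices.
#'
#' @param cutoff Pair cutoff radius, Angstrom.
#' @param image_shell_margin Extra integer padding added to the number of
#'   periodic image shells derived from the cell geometry.
#' @param coulomb_constant Coulomb prefactor, kJ mol^-1 Angstrom e^-2.
#' @param shift If `TRUE` (default) each pair interaction is shifted to zero
#'   at the cutoff (energy-shifted truncation), keeping the surface
#'   continuous for the minimizer.  Set `FALSE` for plain truncation.
#' @return An object of class `potential_config`.
#' @export
potential_config <- function(cutoff = 8,
                             image_shell_margin = 0L,
                             coulomb_constant = .COULOMB,
                             shift = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(cutoff = cutoff,
                 image_shell_margin = as.integer(image_shell_margin),
                 coulomb_constant = coulomb_constant,
                 shift = isTRUE(shift),
                 kB = .kB),
            class = "potential_config")
}

#' Harmonic coupling constants
#'
#' Spring constants tethering the packing coordinates X to the extended
#' variables S.  Centers and angles carry separate constants; the harmonic
#' form requires inverse-square units (kJ mol^-1 A^-2 and kJ mol^-1 deg^-2).
#'
#' @param k_com Spring constant on molecular centers.
#' @param k_euler Spring constant on Euler angles.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(k_com = 1000, k_euler = k_com) {
  if (k_com < 0 || k_euler < 0) stop("spring constants must be >= 0")
  structure(list(k_com = k_com, k_euler = k_euler), class = "coupling_spec")
}

## ---------------------------------------------------------------------------
## Parameter vector packing (internal)

# par = [com (3 Z'), euler (3 Z'), free cell params]
.pack_par <- function(state, sg) {
  free <- free_cell_params(sg)
  c(as.numeric(t(state$com)), as.numeric(t(state$euler)), state$cell[free])
}

.unpack_par <- function(par, zp, sg, cell_template) {
  free <- free_cell_params(sg)
  cell <- cell_template
  cell[free] <- par[6 * zp + seq_along(free)]
  cell <- apply_cell_constraints(cell, sg)
  list(com = matrix(par[seq_len(3 * zp)], zp, 3, byrow = TRUE),
       euler = matrix(par[3 * zp + seq_len(3 * zp)], zp, 3, byrow = TRUE),
       cell = cell)
}

# Assemble the list consumed by the C++ energy kernel.
.build_sys <- function(mol, sg, pot, zp, cell_template,
                       S = NULL, coupling = NULL, clamp = FALSE) {
  opsW <- unlist(lapply(sg$ops, function(o) as.vector(o$W)))
  opsT <- unlist(lapply(sg$ops, function(o) o$t))
  Smat <- NULL
  kcom <- 0; keul <- 0
  if (!is.null(S)) {
    if (nrow(S$com) != zp) stop("EV state layout incompatible with Z'")
    Smat <- cbind(S$com, S$euler)
    if (is.null(coupling)) stop("coupling must accompany an EV state")
    kcom <- coupling$k_com; keul <- coupling$k_euler
  }
  list(sites = mol$sites, eps = mol$epsilon, sig = mol$sigma, q = mol$charge,
       opsW = opsW, opsT = opsT, zp = as.integer(zp),
       cell0 = as.numeric(cell_template),
       freeCell = as.integer(free_cell_params(sg) - 1L),
       cutoff = pot$cutoff, kc = pot$coulomb_constant,
       kcom = kcom, keul = keul, S = Smat,
       margin = pot$image_shell_margin, clamp = clamp,
       shift = isTRUE(pot$shift))
}

## ---------------------------------------------------------------------------
## Energies

#' Lattice energy per molecule
#'
#' Sum over site pairs (asymmetric-unit sites against all symmetry and
#' periodic images within the cutoff) of the Lennard-Jones 12-6 term with
#' Lorentz-Berthelot mixing plus truncated Coulomb, halved for double
#' counting and divided by Z'.  Overlapping sites (r < 0.1 Angstrom) give
#' `Inf`, treated downstream as a rejected configuration.
#'
#' @param state A `packing_state`.
#' @param mol A `rigid_molecule`.
#' @param sg A `space_group`.
#' @param pot A [potential_config()].
#' @return Energy in kJ/mol per molecule.
#' @export
lattice_energy <- function(state, mol, sg, pot = potential_config()) {
  zp <- nrow(state$com)
  sys <- .build_sys(mol, sg, pot, zp, state$cell)
  cpp_energy_terms(.pack_par(state, sg), sys)[1]
}

#' Harmonic coupling penalty
#'
#' The spring energy (k_com/2) sum |com_i - s_com_i|^2 + (k_euler/2)
#' sum wrap(euler_i - s_euler_i)^2 over the Z' cluster, with angle
#' differences wrapped to (-180, 180] degrees.
#'
#' @param state A `packing_state` (or anything with `com`/`euler`).
#' @param S An `ev_state` with matching layout.
#' @param coupling A [coupling_spec()].
#' @return Penalty in kJ/mol (total over the cluster); zero iff X equals S
#'   modulo angle wrapping.
#' @export
harmonic_penalty <- function(state, S, coupling) {
  if (nrow(state$com) != nrow(S$com))
    stop("state and EV state layouts are incompatible")
  dcom <- state$com - S$com
  da <- (state$euler - S$euler + 180) %% 360 - 180
  0.5 * coupling$k_com * sum(dcom^2) + 0.5 * coupling$k_euler * sum(da^2)
}

#' Biased (coupled) energy
#'
#' Lattice energy plus the harmonic coupling penalty; the reference system
#' is non-self-interacting, so no U(S) term appears.
#'
#' @inheritParams lattice_energy
#' @param S An `ev_state`.
#' @param coupling A [coupling_spec()].
#' @return List with `U_unb`, `penalty`, `U_biased` (kJ/mol).
#' @export
biased_energy <- function(state, S, mol, sg, pot = potential_config(),
                          coupling = coupling_spec()) {
  zp <- nrow(state$com)
  sys <- .build_sys(mol, sg, pot, zp, state$cell, S = S, coupling = coupling)
  e <- cpp_energy_terms(.pack_par(state, sg), sys)
  list(U_unb = e[1], penalty = e[2], U_biased = e[1] + e[2])
}

## ---------------------------------------------------------------------------
## Analytic surrogate surfaces

#' Analytic surrogate energy surfaces
#'
#' Deterministic closed-form surfaces over the extended variables, used to
#' test the samplers against exact statistical mechanics.  All operate on
#' the flattened EV vector `s` (centers then angles, or any numeric vector
#' of matching length).
#'
#' * `quadratic`: U = sum k_i/2 (s_i - c_i)^2.  Facts: per-component
#'   stationary variance kB T / k_i.
#' * `double_well`: U = h ((s_1^2 - a^2)/a^2)^2 + sum_(i>1) k0/2 s_i^2, a
#'   symmetric double well of barrier height `h` and minima at +-a in the
#'   first coordinate.
#' * `rough_quadratic`: quadratic plus `n_bumps` seeded Gaussian dips, a
#'   corrugated single basin with reproducible local minima.
#' * `gaussian_pair`: a pair of displaced harmonic surfaces (`U_A`, `U_B`)
#'   with spring constants `k_a`, `k_b`, offset `delta` and energy shift
#'   `e0`; the free-energy difference is closed-form.
#'
#' @param name One of `"quadratic"`, `"double_well"`, `"rough_quadratic"`,
#'   `"gaussian_pair"`.
#' @param params Named list of parameters overriding the defaults
#'   (documented per surface above); `d` is the EV dimensionality.
#' @return A list with `energy` (function of a numeric vector; for
#'   `gaussian_pair` also `energy_b`), and `facts`, a list of closed-form
#'   properties (minima, variances, or `dF(T)`).
#' @export
#' @examples
#' qs <- surrogate_surface("quadratic", list(d = 2, k = 4))
#' qs$energy(c(0, 0))
surrogate_surface <- function(name, params = list()) {
  name <- match.arg(name, c("quadratic", "double_well", "rough_quadratic",
                            "gaussian_pair"))
  p <- params
  d <- p$d %||% 6L
  switch(name,
    quadratic = {
      k <- rep_len(p$k %||% 1000, d)
      center <- rep_len(p$center %||% 0, d)
      list(
        energy = function(s) sum(0.5 * k * (s - center)^2),
        facts = list(d = d, k = k, center = center,
                     variance = function(T) .kB * T / k)
      )
    },
    double_well = {
      h <- p$h %||% 5; a <- p$a %||% 1; k0 <- p$k0 %||% 1000
      list(
        energy = function(s) {
          rest <- if (length(s) > 1L) sum(0.5 * k0 * s[-1L]^2) else 0
          h * ((s[1L]^2 - a^2) / a^2)^2 + rest
        },
        facts = list(h = h, a = a, k0 = k0, minima = c(-a, a),
                     n_minima = 2L,
                     # unnormalized Boltzmann density of the well coordinate
                     density1 = function(x, T)
                       exp(-h * ((x^2 - a^2) / a^2)^2 / (.kB * T)))
      )
    },
    rough_quadratic = {
      k <- p$k %||% 5; n_bumps <- p$n_bumps %||% 8L
      w <- p$w %||% 3; sd_b <- p$sd %||% 0.25
      span <- p$span %||% 2; seed <- p$seed %||% 42L
      centers <- local({
        old <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv()) else NULL
        set.seed(seed)
        x <- matrix(stats::runif(n_bumps * d, -span, span), n_bumps, d)
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        x
      })
      list(
        energy = function(s) {
          d2 <- colSums((t(centers) - s)^2)
          sum(0.5 * k * s^2) - sum(w * exp(-d2 / (2 * sd_b^2)))
        },
        facts = list(k = k, centers = centers, w = w, sd = sd_b, seed = seed)
      )
    },
    gaussian_pair = {
      ka <- p$k_a %||% 1000; kb <- p$k_b %||% 1200
      delta <- rep_len(p$delta %||% 0.02, d); e0 <- p$e0 %||% 1
      list(
        energy = function(s) sum(0.5 * ka * s^2),
        energy_b = function(s) e0 + sum(0.5 * kb * (s - delta)^2),
        facts = list(d = d, k_a = ka, k_b = kb, delta = delta, e0 = e0,
                     dF = function(T) e0 + 0.5 * d * .kB * T * log(kb / ka))
      )
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
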