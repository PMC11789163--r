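# Coordinate conventions, rigid molecules, packing states, extended-variable
# states, and space-group symmetry.
#
# Conventions:
#   * Molecular centers (COMs) are Cartesian Angstrom; they are converted to
#     fractional coordinates (and wrapped into [0,1)) only when the unit cell
#     is expanded.
#   * Orientations are intrinsic ZYZ Euler angles in degrees.  At gimbal lock
#     (beta = 0 or 180) the extraction returns gamma = 0.
#   * Cell parameters are (a, b, c, alpha, beta, gamma) in Angstrom/degrees;
#     the cell matrix has the lattice vectors as rows, with a along x and b
#     in the xy plane.

#' Define a rigid molecule
#'
#' A rigid molecule is a set of interaction sites in a body frame together
#' with per-site Lennard-Jones parameters and charges.  The unweighted
#' centroid of the sites is moved to the origin at construction, so the
#' "center" coordinate of a packed molecule is always the site centroid.
#'
#' @param label Character tag.
#' @param sites Numeric matrix (n x 3) of body-frame site coordinates in
#'   Angstrom.
#' @param epsilon Per-site LJ well depths, kJ/mol (recycled to n sites).
#' @param sigma Per-site LJ diameters, Angstrom (recycled).
#' @param charge Per-site charges in elementary charge units (recycled).
#' @param molar_mass Molar mass in g/mol.
#' @return An object of class `rigid_molecule`.
#' @export
#' @examples
#' mol <- rigid_molecule("atom", matrix(0, 1, 3), 1, 3.4, 0, 40)
rigid_molecule <- function(label, sites, epsilon, sigma, charge, molar_mass) {
  sites <- as.matrix(sites)
  storage.mode(sites) <- "double"
  if (nrow(sites) < 1L || ncol(sites) != 3L || any(!is.finite(sites)))
    stop("`sites` must be a finite n x 3 matrix with n >= 1")
  n <- nrow(sites)
  epsilon <- rep_len(as.numeric(epsilon), n)
  sigma <- rep_len(as.numeric(sigma), n)
  charge <- rep_len(as.numeric(charge), n)
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be positive")
  sites <- sweep(sites, 2L, colMeans(sites))  # centroid at origin
  structure(
    list(label = as.character(label), sites = sites, epsilon = epsilon,
         sigma = sigma, charge = charge, molar_mass = as.numeric(molar_mass)),
    class = "rigid_molecule"
  )
}

#' @export
print.rigid_molecule <- function(x, ...) {
  cat(sprintf("Rigid molecule '%s': %d site(s), M = %g g/mol\n",
              x$label, nrow(x$sites), x$molar_mass))
  invisible(x)
}

#' Diameter of a rigid molecule
#'
#' Largest site-to-site distance plus the largest LJ sigma, a cheap bound on
#' the spatial extent used for reference-box sizing.
#'
#' @param mol A `rigid_molecule`.
#' @return Numeric, Angstrom.
#' @export
molecule_diameter <- function(mol) {
  d <- 0
  s <- mol$sites
  if (nrow(s) > 1L) d <- max(stats::dist(s))
  d + max(mol$sigma)
}

#' Construct a packing state
#'
#' A packing state pairs the collective variables `X` of the Z' molecules in
#' the asymmetric unit (center + Euler angles per molecule) with the cell
#' parameters `H`.
#'
#' @param com Z' x 3 matrix of Cartesian molecular centers, Angstrom.
#' @param euler Z' x 3 matrix of ZYZ Euler angles, degrees.
#' @param cell Numeric length-6: (a, b, c, alpha, beta, gamma).
#' @param sg Optional `space_group`; if given, the cell is checked (and
#'   completed) against the group's metric constraints.
#' @return An object of class `packing_state`.
#' @export
packing_state <- function(com, euler, cell, sg = NULL) {
  com <- matrix(as.numeric(com), ncol = 3L)
  euler <- matrix(as.numeric(euler), ncol = 3L)
  if (nrow(com) != nrow(euler)) stop("com and euler must have Z' rows each")
  cell <- as.numeric(cell)
  if (length(cell) != 6L) stop("cell must be (a,b,c,alpha,beta,gamma)")
  if (!is.null(sg)) cell <- apply_cell_constraints(cell, sg)
  if (any(cell[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  H <- cell_matrix(cell)
  if (det(H) <= 0) stop("degenerate cell: non-positive volume")
  structure(list(com = com, euler = euler, cell = cell),
            class = "packing_state")
}

#' @export
print.packing_state <- function(x, ...) {
  cat(sprintf("Packing state: Z' = %d, cell = (%s)\n", nrow(x$com),
              paste(sprintf("%.3f", x$cell), collapse = ", ")))
  invisible(x)
}

#' Construct an extended-variable state
#'
#' The extended variables S mirror the layout of the packing coordinates X:
#' Z' molecular centers (Cartesian Angstrom) and Euler angles (degrees),
#' living in an orthogonal, non-interacting reference box.
#'
#' @param com,euler As in [packing_state()].
#' @param box Length-3 edge lengths of the orthogonal reference box,
#'   Angstrom.
#' @param mol Optional `rigid_molecule` used to check that the box dwarfs the
#'   molecule (each edge at least 3x the molecular diameter).
#' @return An object of class `ev_state`.
#' @export
ev_state <- function(com, euler, box = c(60, 60, 60), mol = NULL) {
  com <- matrix(as.numeric(com), ncol = 3L)
  euler <- matrix(as.numeric(euler), ncol = 3L)
  if (nrow(com) != nrow(euler)) stop("com and euler must have Z' rows each")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  if (!is.null(mol) && any(box < 3 * molecule_diameter(mol)))
    stop("reference box edges must be at least 3x the molecular diameter")
  structure(list(com = com, euler = euler, box = box), class = "ev_state")
}

#' @export
print.ev_state <- function(x, ...) {
  cat(sprintf("EV state: Z' = %d (d = %d), box = (%s) A\n", nrow(x$com),
              6L * nrow(x$com), paste(x$box, collapse = ", ")))
  invisible(x)
}

#' Extract the packing coordinates of a state as an EV state
#'
#' @param state A `packing_state`.
#' @param box,mol Passed to [ev_state()].
#' @return An `ev_state` with the same centers and angles.
#' @export
as_ev_state <- function(state, box = c(60, 60, 60), mol = NULL) {
  ev_state(state$com, state$euler, box = box, mol = mol)
}

## ---------------------------------------------------------------------------
## Euler angles

#' Rotation matrix from intrinsic ZYZ Euler angles
#'
#' @param euler Length-3 numeric, (alpha, beta, gamma) in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
#' @examples
#' euler_to_matrix(c(0, 0, 0))  # identity
euler_to_matrix <- function(euler) {
  if (length(euler) != 3L || any(!is.finite(euler)))
    stop("euler must be 3 finite angles (degrees)")
  e <- euler * pi / 180
  ca <- cos(e[1]); sa <- sin(e[1])
  cb <- cos(e[2]); sb <- sin(e[2])
  cg <- cos(e[3]); sg <- sin(e[3])
  rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()].  At gimbal lock (beta = 0 or 180 degrees)
#' the decomposition is degenerate and the canonical form gamma = 0 is
#' returned.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return Length-3 numeric (alpha, beta, gamma), degrees, with beta in
#'   [0, 180].
#' @export
matrix_to_euler <- function(R) {
  if (!all(dim(R) == c(3L, 3L))) stop("R must be 3 x 3")
  cb <- max(-1, min(1, R[3, 3]))
  beta <- acos(cb)
  if (abs(R[3, 3]) > 1 - 1e-12) {
    # gimbal lock: alpha and gamma share an axis; put it all in alpha.
    # beta = 0: R = Rz(alpha + gamma); beta = 180: R = Rz(alpha - gamma) Ry(pi)
    gamma <- 0
    alpha <- if (R[3, 3] > 0) atan2(R[2, 1], R[1, 1])
             else atan2(-R[2, 1], -R[1, 1])
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha, beta, gamma) * 180 / pi
}

## ---------------------------------------------------------------------------
## Space groups

.sg_op <- function(W, t) list(W = matrix(W, 3, 3, byrow = TRUE), t = t)

# Hard-coded operator sets (fractional rotation part W, translation t) for
# the shipped groups, standard settings, monoclinic unique axis b.
.sg_table <- local({
  E <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
  inv <- -E
  twofold_y <- c(-1, 0, 0, 0, 1, 0, 0, 0, -1)   # 2 along b
  mirror_y <- c(1, 0, 0, 0, -1, 0, 0, 0, 1)     # m perp b
  twofold_z <- c(-1, 0, 0, 0, -1, 0, 0, 0, 1)
  twofold_x <- c(1, 0, 0, 0, -1, 0, 0, 0, -1)

  centered <- function(ops, tc) {
    c(ops, lapply(ops, function(o) .sg_op(o$W, (o$t + tc) %% 1)))
  }
  base <- list(
    "P1" = list(system = "triclinic", ops = list(.sg_op(E, c(0, 0, 0)))),
    "P-1" = list(system = "triclinic",
                 ops = list(.sg_op(E, c(0, 0, 0)), .sg_op(inv, c(0, 0, 0)))),
    "P21" = list(system = "monoclinic",
                 ops = list(.sg_op(E, c(0, 0, 0)),
                            .sg_op(twofold_y, c(0, 0.5, 0)))),
    "P21/m" = list(system = "monoclinic",
                   ops = list(.sg_op(E, c(0, 0, 0)),
                              .sg_op(twofold_y, c(0, 0.5, 0)),
                              .sg_op(inv, c(0, 0, 0)),
                              .sg_op(mirror_y, c(0, 0.5, 0)))),
    "P2/c" = list(system = "monoclinic",
                  ops = list(.sg_op(E, c(0, 0, 0)),
                             .sg_op(twofold_y, c(0, 0, 0.5)),
                             .sg_op(inv, c(0, 0, 0)),
                             .sg_op(mirror_y, c(0, 0, 0.5)))),
    "P21/c" = list(system = "monoclinic",
                   ops = list(.sg_op(E, c(0, 0, 0)),
                              .sg_op(twofold_y, c(0, 0.5, 0.5)),
                              .sg_op(inv, c(0, 0, 0)),
                              .sg_op(mirror_y, c(0, 0.5, 0.5)))),
    "C2" = list(system = "monoclinic",
                ops = centered(list(.sg_op(E, c(0, 0, 0)),
                                    .sg_op(twofold_y, c(0, 0, 0))),
                               c(0.5, 0.5, 0))),
    "Cc" = list(system = "monoclinic",
                ops = centered(list(.sg_op(E, c(0, 0, 0)),
                                    .sg_op(mirror_y, c(0, 0, 0.5))),
                               c(0.5, 0.5, 0))),
    "C2/c" = list(system = "monoclinic",
                  ops = centered(list(.sg_op(E, c(0, 0, 0)),
                                      .sg_op(twofold_y, c(0, 0, 0.5)),
                                      .sg_op(inv, c(0, 0, 0)),
                                      .sg_op(mirror_y, c(0, 0, 0.5))),
                                 c(0.5, 0.5, 0))),
    "P212121" = list(system = "orthorhombic",
                     ops = list(.sg_op(E, c(0, 0, 0)),
                                .sg_op(twofold_x, c(0.5, 0.5, 0)),
                                .sg_op(twofold_y, c(0, 0.5, 0.5)),
                                .sg_op(twofold_z, c(0.5, 0, 0.5)))),
    "Pca21" = list(system = "orthorhombic",
                   ops = list(.sg_op(E, c(0, 0, 0)),
                              .sg_op(twofold_z, c(0, 0, 0.5)),
                              .sg_op(mirror_y, c(0.5, 0, 0)),
                              .sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, 1),
                                     c(0.5, 0, 0.5)))),
    "Pna21" = list(system = "orthorhombic",
                   ops = list(.sg_op(E, c(0, 0, 0)),
                              .sg_op(twofold_z, c(0, 0, 0.5)),
                              .sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, 1),
                                     c(0.5, 0.5, 0.5)),
                              .sg_op(mirror_y, c(0.5, 0.5, 0)))),
    "Pbca" = list(system = "orthorhombic",
                  ops = list(.sg_op(E, c(0, 0, 0)),
                             .sg_op(twofold_z, c(0.5, 0, 0.5)),
                             .sg_op(twofold_y, c(0, 0.5, 0.5)),
                             .sg_op(twofold_x, c(0.5, 0.5, 0)),
                             .sg_op(inv, c(0, 0, 0)),
                             .sg_op(mirror_y, c(0, 0.5, 0.5)),
                             .sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, 1),
                                    c(0.5, 0.5, 0)),
                             .sg_op(c(1, 0, 0, 0, 1, 0, 0, 0, -1),
                                    c(0.5, 0, 0.5))))
  )
  # normalize translations into [0,1)
  lapply(base, function(g) {
    g$ops <- lapply(g$ops, function(o) .sg_op(t(o$W), o$t %% 1))
    # .sg_op(W,...) fills byrow, so pass transpose to keep W as intended
    g
  })
})

#' Shipped space groups
#'
#' @return Character vector of the Hermann-Mauguin symbols available to
#'   [space_group()].
#' @export
space_group_symbols <- function() names(.sg_table)

#' Retrieve a space group
#'
#' The package ships 13 hard-coded space groups common in molecular-crystal
#' work (no general symbol parser).  Each group carries its operator set
#' (fractional rotation parts and translations) and the metric constraints
#' of its crystal system.
#'
#' @param symbol Hermann-Mauguin symbol; see [space_group_symbols()].
#'   Subscripts are written inline (`"P212121"`, `"P21/c"`).
#' @return An object of class `space_group` with elements `symbol`, `ops`
#'   (list of `list(W, t)`), `n_ops`, and `system`.
#' @export
#' @examples
#' sg <- space_group("P212121")
#' sg$n_ops
space_group <- function(symbol) {
  symbol <- gsub("₁", "1", symbol)
  key <- toupper(gsub("\\s", "", symbol))
  key <- sub("^P-1$", "P-1", key)
  hit <- match(key, toupper(names(.sg_table)))
  if (is.na(hit))
    stop("unknown space group '", symbol, "'; shipped groups: ",
         paste(space_group_symbols(), collapse = ", "))
  g <- .sg_table[[hit]]
  structure(list(symbol = names(.sg_table)[hit], ops = g$ops,
                 n_ops = length(g$ops), system = g$system),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("Space group %s (%s, %d ops)\n", x$symbol, x$system, x$n_ops))
  invisible(x)
}

#' Impose a space group's metric constraints on cell parameters
#'
#' Triclinic cells are returned unchanged; monoclinic cells get
#' alpha = gamma = 90; orthorhombic cells get all angles 90.
#'
#' @param cell Length-6 (a, b, c, alpha, beta, gamma).
#' @param sg A `space_group`.
#' @return Constrained length-6 cell.
#' @export
apply_cell_constraints <- function(cell, sg) {
  cell <- as.numeric(cell)
  switch(sg$system,
         triclinic = cell,
         monoclinic = c(cell[1:3], 90, cell[5], 90),
         orthorhombic = c(cell[1:3], 90, 90, 90),
         stop("unknown crystal system"))
}

#' Indices of the free cell parameters of a space group
#'
#' @param sg A `space_group`.
#' @return Integer indices into (a, b, c, alpha, beta, gamma) that are free
#'   to vary; the rest are fixed at 90 degrees.
#' @export
free_cell_params <- function(sg) {
  switch(sg$system,
         triclinic = 1:6,
         monoclinic = c(1:3, 5L),
         orthorhombic = 1:3,
         stop("unknown crystal system"))
}

## ---------------------------------------------------------------------------
## Cell geometry

#' Cell matrix from cell parameters
#'
#' Rows are the lattice vectors a, b, c; a lies along x and b in the xy
#' plane.
#'
#' @param cell Length-6 (a, b, c, alpha, beta, gamma), Angstrom/degrees.
#' @return 3 x 3 matrix, Angstrom.
#' @export
cell_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  cal <- cos(al); cbe <- cos(be); cga <- cos(ga); sga <- sin(ga)
  v2 <- 1 - cal^2 - cbe^2 - cga^2 + 2 * cal * cbe * cga
  if (v2 <= 0) stop("degenerate cell: impossible angle combination")
  rbind(c(a, 0, 0),
        c(b * cga, b * sga, 0),
        c(cc * cbe, cc * (cal - cbe * cga) / sga, cc * sqrt(v2) / sga))
}

#' Unit-cell volume
#'
#' @param cell Length-6 cell parameters.
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) det(cell_matrix(cell))

#' Crystal density
#'
#' @param state A `packing_state`.
#' @param mol The `rigid_molecule`.
#' @param sg The `space_group`.
#' @return Density in g/cm^3: n_ops * Z' * M / (N_A * V_cell).
#' @export
#' @examples
#' mol <- rigid_molecule("atom", matrix(0, 1, 3), 1, 3.4, 0, 100)
#' st <- packing_state(matrix(0, 1, 3), matrix(0, 1, 3),
#'                     c(10, 10, 10, 90, 90, 90))
#' crystal_density(st, mol, space_group("P1"))  # 0.16605 g/cm3
crystal_density <- function(state, mol, sg) {
  v <- cell_volume(state$cell)  # A^3
  if (!is.finite(v) || v <= 0) stop("degenerate cell")
  n <- sg$n_ops * nrow(state$com)
  n * mol$molar_mass / (.AVOGADRO * v * 1e-24)
}

#' @describeIn crystal_density Method for the [stats::density()] generic.
#' @param x A `packing_state`.
#' @param ... Ignored.
#' @export
density.packing_state <- function(x, mol, sg, ...) crystal_density(x, mol, sg)

#' Expand a packing state to the full unit cell
#'
#' Applies every symmetry operator of the group to the Z' molecules of the
#' asymmetric unit.  Molecular centers are wrapped into the cell (fractional
#' [0,1)) before site offsets are added; orientations are transformed by the
#' Cartesian image of the fractional rotation part.
#'
#' @param state A `packing_state` (cell must satisfy the group metric).
#' @param mol The `rigid_molecule`.
#' @param sg The `space_group`.
#' @return A list with `sites` (n_ops * Z' * n_sites x 3 Cartesian
#'   Angstrom), `frac` (same sites in fractional coordinates), `mol_id`,
#'   `op_id`, `site_id` index vectors, and `com_frac` (wrapped fractional
#'   centers, (n_ops*Z') x 3).
#' @export
expand_to_cell <- function(state, mol, sg) {
  cellc <- apply_cell_constraints(state$cell, sg)
  if (max(abs(cellc - state$cell)) > 1e-8)
    stop("cell violates the space group's metric constraints")
  H <- cell_matrix(state$cell)     # rows = lattice vectors
  Hi <- solve(H)
  A <- t(H)                        # cart = A %*% frac
  Ai <- solve(A)
  zp <- nrow(state$com)
  fcom <- state$com %*% Hi         # fractional centers, Z' x 3
  ns <- nrow(mol$sites)
  out_sites <- vector("list", sg$n_ops * zp)
  mol_id <- op_id <- site_id <- integer(0)
  com_frac <- matrix(0, sg$n_ops * zp, 3)
  idx <- 0L
  for (k in seq_len(sg$n_ops)) {
    op <- sg$ops[[k]]
    Rcart <- A %*% op$W %*% Ai
    for (m in seq_len(zp)) {
      idx <- idx + 1L
      f <- as.numeric(op$W %*% fcom[m, ] + op$t) %% 1
      com_frac[idx, ] <- f
      ccart <- as.numeric(A %*% f)
      Rm <- Rcart %*% euler_to_matrix(state$euler[m, ])
      out_sites[[idx]] <- sweep(mol$sites %*% t(Rm), 2L, ccart, "+")
      mol_id <- c(mol_id, rep.int(m, ns))
      op_id <- c(op_id, rep.int(k, ns))
      site_id <- c(site_id, seq_len(ns))
    }
  }
  sites <- do.call(rbind, out_sites)
  list(sites = sites, frac = sites %*% Hi, mol_id = mol_id, op_id = op_id,
       site_id = site_id, com_frac = com_frac)
}
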