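# Independent R oracles used against the compiled implementation, plus the
# small systems shared across test files.  Everything here is deliberately
# written as plainly as possible (double loops, expand.grid images) and never
# calls the C++ kernel.

# Brute-force lattice energy: double loop over asymmetric-unit sites and all
# cell sites over a symmetric image block.
brute_lattice_energy <- function(state, mol, sg, cutoff, n_img = NULL,
                                 shift = FALSE) {
  ex <- expand_to_cell(state, mol, sg)
  H <- cell_matrix(state$cell)
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  V <- abs(det(H))
  if (is.null(n_img)) {
    sp <- c(V / sqrt(sum(cross3(H[2, ], H[3, ])^2)),
            V / sqrt(sum(cross3(H[3, ], H[1, ])^2)),
            V / sqrt(sum(cross3(H[1, ], H[2, ])^2)))
    n_img <- ceiling(cutoff / sp) + 1
  } else n_img <- rep(n_img, 3)
  img <- as.matrix(expand.grid(-n_img[1]:n_img[1], -n_img[2]:n_img[2],
                               -n_img[3]:n_img[3]))
  shifts <- img %*% H
  inst <- (ex$op_id - 1L) * nrow(state$com) + ex$mol_id
  nasym <- nrow(state$com) * nrow(mol$sites)
  E <- 0
  for (i in seq_len(nasym)) {
    for (j in seq_len(nrow(ex$sites))) {
      d <- sweep(shifts, 2L, ex$sites[i, ] - ex$sites[j, ], "-")
      rr <- sqrt(rowSums(d^2))
      excl <- (inst[j] == inst[i]) & rowSums(abs(img)) == 0
      rr <- rr[!excl & rr <= cutoff]
      if (!length(rr)) next
      sig <- 0.5 * (mol$sigma[ex$site_id[i]] + mol$sigma[ex$site_id[j]])
      eps <- sqrt(mol$epsilon[ex$site_id[i]] * mol$epsilon[ex$site_id[j]])
      qq <- mol$charge[ex$site_id[i]] * mol$charge[ex$site_id[j]] *
        evccp_constants()$coulomb
      u <- 4 * eps * ((sig / rr)^12 - (sig / rr)^6) + qq / rr
      if (shift) {
        sc6 <- (sig / cutoff)^6
        uc <- 4 * eps * (sc6^2 - sc6) + qq / cutoff
        duc <- -24 * eps * (2 * sc6^2 - sc6) / cutoff - qq / cutoff^2
        u <- u - uc - duc * (rr - cutoff)
      }
      E <- E + sum(u)
    }
  }
  0.5 * E / nrow(state$com)
}

# cell parameters from a 3x3 lattice-vector matrix (rows)
cellpar_from_H <- function(H) {
  a <- sqrt(sum(H[1, ]^2)); b <- sqrt(sum(H[2, ]^2)); cc <- sqrt(sum(H[3, ]^2))
  c(a, b, cc,
    acos(sum(H[2, ] * H[3, ]) / (b * cc)) * 180 / pi,
    acos(sum(H[1, ] * H[3, ]) / (a * cc)) * 180 / pi,
    acos(sum(H[1, ] * H[2, ]) / (a * b)) * 180 / pi)
}

random_unimodular <- function() {
  repeat {
    M <- matrix(sample(-1:1, 9, replace = TRUE), 3, 3)
    if (abs(det(M)) == 1) return(M)
  }
}

# shared fixture systems (reference polymorphs are memoized by the package)
fx_atom <- fixture_molecule("atom")
fx_bent <- fixture_molecule("bent")
sg_p1 <- space_group("P1")
sg_p21 <- space_group("P21")
pot8 <- potential_config()
pot6 <- potential_config(cutoff = 6)
bounds_atom_p1 <- fixture_bounds(fx_atom, sg_p1, 1L)
bounds_atom_p21 <- fixture_bounds(fx_atom, sg_p21, 1L)
bounds_bent_p21 <- fixture_bounds(fx_bent, sg_p21, 1L)

bent_reference <- function() {
  make_reference_polymorph(fx_bent, sg_p21, 1L, pot = pot6,
                           bounds = bounds_bent_p21)
}
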