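# The plain-truncation configurations used where exact pair values matter:
# a large cutoff makes the truncation error negligible.
pot_exact <- potential_config(cutoff = 25, shift = FALSE)

test_that("pair-potential anchor values are exact", {
  # isolated molecule: no interactions
  st0 <- packing_state(matrix(0, 1, 3), matrix(0, 1, 3),
                       c(60, 60, 60, 90, 90, 90))
  expect_equal(lattice_energy(st0, fx_atom, sg_p1, pot_exact), 0)
  # dimer beyond the cutoff
  far <- packing_state(rbind(c(0, 0, 0), c(30, 0, 0)), matrix(0, 2, 3),
                       c(90, 90, 90, 90, 90, 90))
  expect_equal(lattice_energy(far, fx_atom, sg_p1,
                              potential_config(cutoff = 8, shift = FALSE)),
               0)
  # dimer at the LJ zero crossing and at the minimum
  at_sigma <- packing_state(rbind(c(0, 0, 0), c(3.4, 0, 0)), matrix(0, 2, 3),
                            c(80, 80, 80, 90, 90, 90))
  expect_equal(lattice_energy(at_sigma, fx_atom, sg_p1, pot_exact), 0,
               tolerance = 1e-10)
  at_min <- packing_state(rbind(c(0, 0, 0), c(2^(1 / 6) * 3.4, 0, 0)),
                          matrix(0, 2, 3), c(80, 80, 80, 90, 90, 90))
  expect_equal(lattice_energy(at_min, fx_atom, sg_p1, pot_exact), -0.5,
               tolerance = 1e-6)
  # overlapping sites give the +Inf sentinel
  ovl <- packing_state(rbind(c(0, 0, 0), c(0.05, 0, 0)), matrix(0, 2, 3),
                       c(80, 80, 80, 90, 90, 90))
  expect_true(is.infinite(lattice_energy(ovl, fx_atom, sg_p1, pot_exact)))
})

test_that("lattice energy matches the brute-force double-loop oracle", {
  set.seed(33)
  # random bent/P21 packings, shifted and unshifted
  for (i in 1:4) {
    st <- sample_random_start(bounds_bent_p21, sg_p21, 1L, fx_bent)
    for (shift in c(TRUE, FALSE)) {
      pot <- potential_config(cutoff = 6, shift = shift)
      expect_equal(lattice_energy(st, fx_bent, sg_p21, pot),
                   brute_lattice_energy(st, fx_bent, sg_p21, 6,
                                        shift = shift),
                   tolerance = 1e-9)
    }
  }
  # charged molecule exercises the Coulomb path
  molq <- fixture_molecule("bent_charged")
  stq <- sample_random_start(bounds_bent_p21, sg_p21, 1L, molq)
  potq <- potential_config(cutoff = 6, shift = TRUE)
  expect_equal(lattice_energy(stq, molq, sg_p21, potq),
               brute_lattice_energy(stq, molq, sg_p21, 6, shift = TRUE),
               tolerance = 1e-9)
})

test_that("fcc LJ crystal energy matches a triple-cutoff brute-force sum", {
  # primitive fcc cell (rhombohedral, 60 degree angles) at the LJ optimum
  a_nn <- 2^(1 / 6) * 3.4
  st <- packing_state(matrix(0, 1, 3), matrix(0, 1, 3),
                      c(a_nn, a_nn, a_nn, 60, 60, 60))
  rc <- 40
  e_pkg <- lattice_energy(st, fx_atom, sg_p1,
                          potential_config(cutoff = rc, shift = FALSE))
  e_brute <- brute_lattice_energy(st, fx_atom, sg_p1, 3 * rc)
  expect_lt(abs(e_pkg - e_brute) / abs(e_brute), 0.001)
  # closed-form fcc lattice sums give -8.3879 eps at this spacing; the
  # truncated sum sits slightly above it by the (positive-definite) LJ tail
  e_inf <- 2 * (12.131880 * 0.25 - 14.453921 * 0.5)
  expect_lt(e_pkg, e_inf + 0.3)
  expect_gt(e_pkg, e_inf - 0.05)
})

test_that("cutoff convergence: doubling the cutoff moves energy < 1%", {
  # LJ tail decays as rc^-3; from ~6 sigma on, doubling the cutoff changes
  # the lattice energy by well under a percent
  a_nn <- 2^(1 / 6) * 3.4
  st <- packing_state(matrix(0, 1, 3), matrix(0, 1, 3),
                      c(a_nn, a_nn, a_nn, 60, 60, 60))
  e1 <- lattice_energy(st, fx_atom, sg_p1,
                       potential_config(cutoff = 20, shift = FALSE))
  e2 <- lattice_energy(st, fx_atom, sg_p1,
                       potential_config(cutoff = 40, shift = FALSE))
  expect_lt(abs(e1 - e2) / abs(e2), 0.01)
})

test_that("harmonic penalty: zero at S, quadratic, wraps angles", {
  st <- packing_state(matrix(1:3, 1, 3), matrix(c(10, 20, 30), 1, 3),
                      c(8, 8, 8, 90, 90, 90))
  S <- as_ev_state(st)
  k <- coupling_spec(1000, 1000)
  expect_equal(harmonic_penalty(st, S, k), 0)
  # k_com = 2, one center displaced 1 A
  S2 <- ev_state(st$com + matrix(c(1, 0, 0), 1, 3), st$euler)
  expect_equal(harmonic_penalty(st, S2, coupling_spec(2, 0)), 1.0)
  # 350 degree difference equals -10 degrees
  Sa <- ev_state(st$com, st$euler + 350)
  Sb <- ev_state(st$com, st$euler - 10)
  expect_equal(harmonic_penalty(st, Sa, coupling_spec(0, 7)),
               harmonic_penalty(st, Sb, coupling_spec(0, 7)))
  expect_error(harmonic_penalty(st, ev_state(matrix(0, 2, 3),
                                             matrix(0, 2, 3)), k),
               "incompatible")
})

test_that("biased energy = lattice energy + penalty, exactly", {
  set.seed(5)
  st <- sample_random_start(bounds_bent_p21, sg_p21, 1L, fx_bent)
  S <- ev_state(st$com + 0.3, st$euler + 5)
  k <- coupling_spec(100, 10)
  be <- biased_energy(st, S, fx_bent, sg_p21, pot6, k)
  expect_equal(be$U_unb, lattice_energy(st, fx_bent, sg_p21, pot6))
  expect_equal(be$penalty, harmonic_penalty(st, S, k))
  expect_equal(be$U_biased, be$U_unb + be$penalty)
  expect_gte(be$U_biased, be$U_unb)
  # zero coupling and X = S both reduce to the unbiased energy
  expect_equal(biased_energy(st, S, fx_bent, sg_p21, pot6,
                             coupling_spec(0, 0))$U_biased, be$U_unb)
  expect_equal(biased_energy(st, as_ev_state(st), fx_bent, sg_p21, pot6,
                             k)$U_biased, be$U_unb)
})

test_that("lattice energy is invariant to lattice translations and symmetry", {
  ref <- bent_reference()
  st <- ref$state
  e0 <- lattice_energy(st, fx_bent, sg_p21, pot6)
  H <- cell_matrix(st$cell)
  st_t <- packing_state(st$com + matrix(colSums(H), 1, 3), st$euler,
                        st$cell, sg_p21)
  expect_equal(lattice_energy(st_t, fx_bent, sg_p21, pot6), e0,
               tolerance = 1e-9)
  # op-2 image of the asymmetric unit leaves the energy unchanged
  op <- sg_p21$ops[[2]]
  A <- t(H)
  f <- as.numeric(op$W %*% (solve(A) %*% t(st$com)) + op$t)
  Rc <- A %*% op$W %*% solve(A)
  st_s <- packing_state(matrix(as.numeric(A %*% f), 1, 3),
                        matrix(matrix_to_euler(
                          Rc %*% euler_to_matrix(st$euler[1, ])), 1, 3),
                        st$cell, sg_p21)
  expect_equal(lattice_energy(st_s, fx_bent, sg_p21, pot6), e0,
               tolerance = 1e-8)
})

test_that("surrogate surfaces expose their documented anchors", {
  q <- surrogate_surface("quadratic", list(d = 4, k = 50, center = 1))
  expect_equal(q$energy(rep(1, 4)), 0)
  expect_equal(q$facts$variance(300), rep(0.0083144621 * 300 / 50, 4))
  dw <- surrogate_surface("double_well", list(h = 3, a = 2))
  expect_equal(dw$facts$n_minima, 2L)
  expect_equal(dw$energy(c(2, 0, 0)), 0)
  expect_equal(dw$energy(c(0, 0, 0)), 3)
  r1 <- surrogate_surface("rough_quadratic", list(d = 2, seed = 9))
  r2 <- surrogate_surface("rough_quadratic", list(d = 2, seed = 9))
  x <- c(0.3, -0.7)
  expect_identical(r1$energy(x), r2$energy(x))
  gp <- surrogate_surface("gaussian_pair", list(d = 2))
  expect_lt(gp$energy(c(0, 0)), gp$energy_b(c(0, 0)))
  expect_error(surrogate_surface("nope"), "arg")
})
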