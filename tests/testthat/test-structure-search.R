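test_that("random starts respect the density window and are reproducible", {
  b <- bounds_bent_p21
  stream <- rng_stream(4)
  for (i in 1:50) {
    st <- with_stream(stream, function()
      sample_random_start(b, sg_p21, 1L, fx_bent))
    rho <- crystal_density(st, fx_bent, sg_p21)
    expect_gte(rho, b$rho_min)
    expect_lte(rho, b$rho_max)
    expect_equal(st$cell[c(4, 6)], c(90, 90))
  }
  s1 <- with_stream(rng_stream(9), function()
    sample_random_start(b, sg_p21, 1L, fx_bent))
  s2 <- with_stream(rng_stream(9), function()
    sample_random_start(b, sg_p21, 1L, fx_bent))
  expect_identical(s1, s2)
  # infeasible window errors after the rejection cap
  b_bad <- sampler_bounds(cell_min = 3, cell_max = 3.5, rho_min = 10,
                          rho_max = 11)
  expect_error(with_stream(rng_stream(1), function()
    sample_random_start(b_bad, sg_p21, 1L, fx_bent)), "bounds-infeasible")
})

test_that("cell-length marginal is uniform when the density window is wide", {
  # with no effective density rejection the per-parameter draws are plain
  # uniforms; KS against the exact uniform CDF
  b <- sampler_bounds(cell_min = 4, cell_max = 8, rho_min = 1e-6,
                      rho_max = 1e6)
  stream <- rng_stream(5)
  a_draws <- replicate(10000, with_stream(stream, function()
    sample_random_start(b, sg_p1, 1L, fx_atom))$cell[1])
  expect_gt(ks.test(a_draws, "punif", 4, 8)$p.value, 0.01)
})

test_that("local minimization decreases energy and fixes known minima", {
  ref <- bent_reference()
  # fixed point: re-minimizing the reference changes nothing measurable
  again <- local_minimize(ref$state, fx_bent, sg_p21, pot6,
                          bounds = bounds_bent_p21)
  expect_true(again$converged)
  expect_lt(abs(again$U_unb - ref$U_unb), 1e-4)
  expect_lt(rmsd_com(again$state, ref$state), 0.05)
  # never increases the (biased) objective
  stream <- rng_stream(12)
  for (i in 1:5) {
    st <- with_stream(stream, function()
      sample_random_start(bounds_bent_p21, sg_p21, 1L, fx_bent))
    e0 <- lattice_energy(st, fx_bent, sg_p21, pot6)
    rec <- local_minimize(st, fx_bent, sg_p21, pot6,
                          bounds = bounds_bent_p21)
    expect_lte(rec$U_unb, e0 + 1e-9)
    expect_equal(rec$U_biased, rec$U_unb + rec$penalty)
  }
  # k = 0 coupling is identical to the unbiased call
  st <- with_stream(rng_stream(8), function()
    sample_random_start(bounds_bent_p21, sg_p21, 1L, fx_bent))
  S <- ev_state(st$com + 1, st$euler + 20)
  r0 <- local_minimize(st, fx_bent, sg_p21, pot6, bounds = bounds_bent_p21)
  rk <- local_minimize(st, fx_bent, sg_p21, pot6, S = S,
                       coupling = coupling_spec(0, 0),
                       bounds = bounds_bent_p21)
  expect_equal(rk$U_unb, r0$U_unb)
  expect_equal(rk$state$cell, r0$state$cell)
  expect_error(local_minimize(st, fx_bent, sg_p21, pot6, S = S),
               "coupling")
})

test_that("prefilter matches a direct loop and handles edge cases", {
  stream <- rng_stream(31)
  states <- replicate(50, with_stream(stream, function()
    sample_random_start(bounds_bent_p21, sg_p21, 1L, fx_bent)),
    simplify = FALSE)
  thr <- 50
  flags <- vapply(states, function(s)
    prefilter(s, fx_bent, sg_p21, pot6, thr), FALSE)
  direct <- vapply(states, function(s) {
    u <- lattice_energy(s, fx_bent, sg_p21, pot6)
    is.finite(u) && u <= thr
  }, FALSE)
  expect_identical(flags, direct)
  expect_true(any(flags) && any(!flags))
  # infinite threshold accepts any non-overlapping state
  expect_true(prefilter(states[[1]], fx_bent, sg_p21, pot6, Inf))
  # overlap sentinel is always rejected
  ovl <- packing_state(rbind(c(0, 0, 0), c(0.05, 0, 0)), matrix(0, 2, 3),
                       c(70, 70, 70, 90, 90, 90))
  expect_false(prefilter(ovl, fx_atom, sg_p1, pot8, Inf))
})

test_that("duplicate detection is reflexive, translation-blind, energy-aware", {
  ref <- bent_reference()
  expect_true(is_duplicate(ref, ref, sg_p21))
  # copy with all centers shifted by a lattice vector
  H <- cell_matrix(ref$state$cell)
  shifted <- polymorph_record(
    packing_state(ref$state$com + matrix(H[1, ] + H[3, ], 1, 3),
                  ref$state$euler, ref$state$cell, sg_p21),
    ref$U_unb)
  expect_true(is_duplicate(ref, shifted, sg_p21))
  # same geometry, incompatible energy
  off <- polymorph_record(ref$state, ref$U_unb + 10 * duplicate_tol()$tol_E)
  expect_false(is_duplicate(ref, off, sg_p21))
  # same energy, different reduced cell
  cell2 <- ref$state$cell * c(1.25, 1, 1, 1, 1, 1)
  other <- polymorph_record(
    packing_state(ref$state$com, ref$state$euler, cell2, sg_p21), ref$U_unb)
  expect_false(is_duplicate(ref, other, sg_p21))
})

test_that("deduplication keeps lowest-energy representatives, idempotently", {
  set.seed(17)
  search <- pr_search(60, bounds_bent_p21, fx_bent, sg_p21, 1L, pot6,
                      seed = 23)
  d1 <- deduplicate(search$records, sg_p21)
  expect_lte(length(d1), length(search$records))
  u <- vapply(d1, function(r) r$U_unb, 0)
  expect_true(all(diff(u) >= 0))
  d2 <- deduplicate(d1, sg_p21)
  expect_equal(length(d2), length(d1))
  expect_equal(vapply(d2, function(r) r$U_unb, 0), u)
  # every original record matches one of the representatives
  for (r in search$records[seq(1, 60, by = 7)]) {
    if (!is.finite(r$U_unb)) next
    expect_true(any(vapply(d1, function(k)
      is_duplicate(k, r, sg_p21), FALSE)))
  }
})

test_that("pseudo-random search is seeded, complete, and grows N_distinct", {
  s5 <- pr_search(5, bounds_atom_p21, fx_atom, sg_p21, 1L, pot8, seed = 2)
  expect_length(s5$records, 5L)
  expect_true(all(vapply(s5$records, function(r) r$converged, FALSE)))
  s5b <- pr_search(5, bounds_atom_p21, fx_atom, sg_p21, 1L, pot8, seed = 2)
  expect_identical(record_energies(s5), record_energies(s5b))
  # N_distinct non-decreasing in N (same seed, nested prefixes)
  s60 <- pr_search(60, bounds_atom_p21, fx_atom, sg_p21, 1L, pot8, seed = 3)
  nd <- vapply(c(10, 30, 60), function(n)
    length(deduplicate(s60$records[seq_len(n)], sg_p21)), 0L)
  expect_true(all(diff(nd) >= 0))
})

test_that("post-processing relaxes biased records onto the unbiased surface", {
  ref <- bent_reference()
  S <- as_ev_state(ref$state)
  cfg <- evccp_config(coupling = coupling_spec(1000, 1000), M = 3L,
                      seed = 6L)
  mb <- mini_batch(S, cfg, fx_bent, sg_p21, bounds_bent_p21, pot6,
                   rng_stream(41))
  pp <- postprocess_records(mb$records, fx_bent, sg_p21, pot6,
                            bounds = bounds_bent_p21)
  expect_length(pp, length(mb$records))
  for (i in seq_along(pp)) {
    expect_lte(pp[[i]]$U_unb, mb$records[[i]]$U_unb + 1e-9)
    expect_equal(pp[[i]]$penalty, 0)
  }
})
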