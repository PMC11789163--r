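test_that("mini-batch selects the biased argmin and seeds X at S", {
  ref <- bent_reference()
  S <- as_ev_state(ref$state)
  cfg <- evccp_config(coupling = coupling_spec(1000, 1000), M = 6L,
                      seed = 3L)
  mb <- mini_batch(S, cfg, fx_bent, sg_p21, bounds_bent_p21, pot6,
                   rng_stream(11))
  ub <- vapply(mb$records, function(r) r$U_biased, 0)
  expect_equal(mb$U_min, min(ub))
  expect_true(all(mb$U_min <= ub))
  expect_equal(mb$U_cond, mb$U_min)
  # strong coupling keeps the selected packing at the reference EV
  expect_lt(rmsd_com(mb$X_min, S), 0.1)
})

test_that("M = 1, k = 0 mini-batch is one unbiased minimization", {
  ref <- bent_reference()
  S <- as_ev_state(ref$state)
  cfg <- evccp_config(coupling = coupling_spec(0, 0), M = 1L, seed = 3L)
  mb <- mini_batch(S, cfg, fx_bent, sg_p21, bounds_bent_p21, pot6,
                   rng_stream(19))
  # replay the same cell draw and minimize directly
  cell <- with_stream(rng_stream(19), function()
    evccp:::.sample_cell(bounds_bent_p21, sg_p21, 1L, fx_bent))
  direct <- local_minimize(packing_state(S$com, S$euler, cell, sg_p21),
                           fx_bent, sg_p21, pot6, bounds = bounds_bent_p21)
  expect_equal(mb$records[[1]]$U_unb, direct$U_unb)
  expect_equal(mb$records[[1]]$state$cell, direct$state$cell)
})

test_that("an infeasible threshold raises a step-infeasible error", {
  ref <- bent_reference()
  S <- as_ev_state(ref$state)
  cfg <- evccp_config(coupling = coupling_spec(1000, 1000), M = 2L,
                      E_threshold = -1e6, retry_cap = 3L, seed = 1L)
  expect_error(mini_batch(S, cfg, fx_bent, sg_p21, bounds_bent_p21, pot6,
                          rng_stream(2)), "step-infeasible")
})

test_that("Metropolis accepts downhill always and everything at huge T", {
  qs <- surrogate_surface("quadratic", list(d = 6, k = 1000))
  S <- ev_state(matrix(0, 1, 3), matrix(0, 1, 3))
  # downhill proposals: start far away, many trials
  cfg <- evccp_config(M = 1L, T = 1, step_com = 0.01, step_euler = 0.01,
                      seed = 1L)
  far <- ev_state(matrix(5, 1, 3), matrix(5, 1, 3))
  stream <- rng_stream(3)
  up <- metropolis_update(far, qs$energy(evccp:::.ev_flat(far)), cfg,
                          stream = stream, objective = qs$energy)
  expect_true(up$accepted)  # from 5 away, small steps are downhill
  # beta -> 0 limit
  cfg_hot <- evccp_config(M = 1L, T = 1e9, step_com = 0.5, step_euler = 0.5,
                          seed = 1L)
  stream <- rng_stream(4)
  n_acc <- 0L
  Su <- S; U <- qs$energy(evccp:::.ev_flat(Su))
  for (i in 1:200) {
    up <- metropolis_update(Su, U, cfg_hot, stream = stream,
                            objective = qs$energy)
    Su <- up$S; U <- up$U_cond
    n_acc <- n_acc + up$accepted
  }
  expect_equal(n_acc, 200L)
})

test_that("surrogate-mode acceptance matches the analytic expectation", {
  # 1-d effective: quadratic in the first component only; acceptance of a
  # uniform(-h, h) proposal from equilibrium has a closed double integral
  kB <- evccp_constants()$kB
  k1 <- 500; T1 <- 300; h <- 0.2
  qs <- surrogate_surface("quadratic",
                          list(d = 6, k = c(k1, 0, 0, 0, 0, 0)))
  cfg <- evccp_config(M = 1L, T = T1, step_com = h, step_euler = h,
                      n_steps = 20000L, seed = 8L)
  S0 <- ev_state(matrix(0, 1, 3), matrix(0, 1, 3))
  traj <- run_evccpmc(S0, cfg, objective = qs$energy)
  # oracle: E_{x ~ boltz, d ~ U(-h,h)} min(1, exp(-beta (U(x+d)-U(x))))
  beta <- 1 / (kB * T1)
  sd1 <- sqrt(1 / (beta * k1))
  set.seed(42)
  x <- rnorm(200000, 0, sd1)
  d <- runif(200000, -h, h)
  p_exp <- mean(pmin(1, exp(-beta * 0.5 * k1 * ((x + d)^2 - x^2))))
  se <- sd(pmin(1, exp(-beta * 0.5 * k1 * ((x + d)^2 - x^2)))) /
    sqrt(cfg$n_steps / 10)  # conservative: effective samples after mixing
  expect_lt(abs(traj$acceptance_rate - p_exp), 3 * max(se, 0.01))
})

test_that("trajectories are seeded, complete, and archive every polymorph", {
  ref <- bent_reference()
  S0 <- as_ev_state(ref$state)
  cfg <- evccp_config(coupling = coupling_spec(1000, 1000), M = 2L,
                      T = 300, n_steps = 4L, seed = 10L)
  t1 <- run_evccpmc(S0, cfg, fx_bent, sg_p21, bounds_bent_p21, pot6)
  t2 <- run_evccpmc(S0, cfg, fx_bent, sg_p21, bounds_bent_p21, pot6)
  expect_identical(vapply(t1$steps, function(s) s$accepted, NA),
                   vapply(t2$steps, function(s) s$accepted, NA))
  expect_identical(trajectory_energies(t1), trajectory_energies(t2))
  expect_length(t1$steps, 5L)
  expect_length(trajectory_records(t1), 5L * 2L)
  # zero steps: only the initial evaluation
  cfg0 <- evccp_config(coupling = coupling_spec(1000, 1000), M = 2L,
                       n_steps = 0L, seed = 10L)
  t0 <- run_evccpmc(S0, cfg0, fx_bent, sg_p21, bounds_bent_p21, pot6)
  expect_length(t0$steps, 1L)
})

test_that("detailed balance holds on the quadratic surrogate", {
  # forward/backward acceptance of logged pairs satisfies the Metropolis
  # identity a(x->y)/a(y->x) = exp(-beta dU)
  kB <- evccp_constants()$kB
  qs <- surrogate_surface("quadratic", list(d = 6, k = 200))
  beta <- 1 / (kB * 300)
  set.seed(13)
  for (i in 1:50) {
    x <- rnorm(6, 0, 0.3); y <- x + runif(6, -0.2, 0.2)
    du <- qs$energy(y) - qs$energy(x)
    a_f <- min(1, exp(-beta * du))
    a_b <- min(1, exp(beta * du))
    expect_equal(a_f / a_b, exp(-beta * du), tolerance = 1e-12)
  }
})

test_that("stationary EV distribution is the Boltzmann Gaussian", {
  kB <- evccp_constants()$kB
  k_eff <- 1000; T1 <- 300
  qs <- surrogate_surface("quadratic", list(d = 6, k = k_eff))
  step <- 1.2 * sqrt(kB * T1 / k_eff)
  cfg <- evccp_config(M = 1L, T = T1, step_com = step, step_euler = step,
                      n_steps = 20000L, seed = 2L)
  S0 <- ev_state(matrix(0, 1, 3), matrix(0, 1, 3))
  traj <- run_evccpmc(S0, cfg, objective = qs$energy)
  ev <- trajectory_ev(traj)
  x <- ev[seq(2001, nrow(ev), by = 20), 2]
  expect_gt(suppressWarnings(
    ks.test(x, "pnorm", 0, sqrt(kB * T1 / k_eff))$p.value), 0.01)
})
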