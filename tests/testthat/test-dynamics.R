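test_that("free drift: with zero friction and no noise motion is ballistic", {
  fib <- chromatin_fibre(c("euchromatin", "euchromatin"))
  # both beads share a velocity: internal forces cancel in the COM frame
  pos <- rbind(c(0, 0, 0), c(0.9651, 0, 0))   # FENE+WCA rest separation
  vel <- rbind(c(0.3, -0.2, 0.1), c(0.3, -0.2, 0.1))
  cfg <- sim_config(n_tf = 0, thermostat = thermostat_params(gamma = 0,
                                                            temperature = 0),
                    t_pushoff = 0, t_equil = 0, t_prod = 10,
                    sample_interval = 10)
  st <- system_state(pos, vel, logical(0))
  res <- run_simulation(fib, cfg, seed = 1, state = st)
  com0 <- colMeans(pos)
  com1 <- colMeans(res$final_state$positions)
  expect_equal(com1 - com0, c(0.3, -0.2, 0.1) * 10, tolerance = 1e-8)
})

test_that("determinism: same seed gives bit-identical activity records", {
  fib <- build_toy_fibre(M = 60, n_tu = 6, seed = 3)
  cfg <- sim_config(n_tf = 6, t_pushoff = 10, t_equil = 10, t_prod = 100,
                    sample_interval = 10)
  a <- run_simulation(fib, cfg, seed = 11)
  b <- run_simulation(fib, cfg, seed = 11)
  expect_identical(a$activity$samples, b$activity$samples)
  expect_identical(a$final_state$positions, b$final_state$positions)
  d <- run_simulation(fib, cfg, seed = 12)
  expect_false(identical(a$final_state$positions, d$final_state$positions))
})

test_that("zero production steps give an empty but valid record", {
  fib <- build_toy_fibre(M = 30, n_tu = 3, seed = 1)
  cfg <- sim_config(n_tf = 3, t_pushoff = 5, t_equil = 5, t_prod = 0)
  res <- run_simulation(fib, cfg, seed = 1)
  expect_equal(nrow(res$activity$samples), 0)
  expect_equal(res$activity$tu_indices, tu_indices(fib))
})

test_that("thermostat: equipartition, harmonic fluctuations, bending length", {
  th <- thermo_suite()
  # mean KE per particle should be (3/2) kBT
  expect_equal(th$ke_ratio, 1, tolerance = 0.02)
  # harmonic dimer: mean extension at the rest length, variance kBT/(2Kh)
  expect_equal(th$dimer_mean, 1.1, tolerance = 0.02)
  expect_equal(th$dimer_var, 1 / (2 * 100), tolerance = 0.15)
  # phantom chain: fitted tangent decorrelation length brackets lp = 3
  expect_gt(th$lp_fit, 2.4)
  expect_lt(th$lp_fit, 3.6)
})

test_that("TF switching is a stationary two-state Markov chain", {
  # toy rates: alpha_on = alpha_off -> stationary active fraction 0.5
  sw <- switching_params(alpha_off = 1e-5, attempt_interval = 100)
  n_tf <- 10000
  states <- rep(TRUE, n_tf)               # far from stationarity on purpose
  withr::with_seed(31, {
    for (k in 1:2500) states <- switch_tf_states(states, sw)
  })
  se <- sqrt(0.5 * 0.5 / n_tf)
  expect_lt(abs(mean(states) - 0.5), 3 * se + 0.01)

  # chromosome rates: alpha_on = alpha_off / 4 -> 20% active
  swc <- switching_params_chromosome(alpha_off = 1e-5)
  expect_equal(swc$stationary_active, 0.2)
  states <- rep(TRUE, n_tf)
  withr::with_seed(32, {
    for (k in 1:4000) states <- switch_tf_states(states, swc)
  })
  se <- sqrt(0.2 * 0.8 / n_tf)
  expect_lt(abs(mean(states) - 0.2), 3 * se + 0.01)

  # frozen rates never change states
  sw0 <- switching_params(alpha_off = 0, alpha_on = 0)
  expect_identical(switch_tf_states(rep(c(TRUE, FALSE), 5), sw0),
                   rep(c(TRUE, FALSE), 5))
  # invalid probability
  expect_error(switching_params(alpha_off = 0.2, attempt_interval = 100),
               "exceeds 1")
})

test_that("ellipsoidal confinement: wall force geometry and containment", {
  conf <- confinement("ellipsoid", semi_axes = c(8, 6, 5))
  expect_equal(confinement_force(c(0, 0, 0), conf), c(0, 0, 0))
  expect_equal(confinement_force(c(2, 1, -1), conf), c(0, 0, 0))
  f <- confinement_force(c(7.9, 0, 0), conf)
  expect_lt(f[1], 0)                       # pushes inward
  expect_equal(f[2:3], c(0, 0))
  # a confined short chain plus TF stays inside over a run
  fib <- build_toy_fibre(M = 20, n_tu = 2, seed = 1)
  cfg <- sim_config(n_tf = 2, conf = conf, t_pushoff = 20, t_equil = 50,
                    t_prod = 500, sample_interval = 50, traj_interval = 5)
  res <- run_simulation(fib, cfg, seed = 3)
  tr <- res$trajectory
  sr <- apply(tr, 3, function(p) max(scaled_radius(p, conf)))
  expect_lt(max(sr), 1.0)
  expect_gt(max(sr), 0.5)                  # the volume is actually explored
})

test_that("FENE overstretch aborts with bead indices in the diagnostic", {
  fib <- chromatin_fibre(c("euchromatin", "euchromatin"))
  pos <- rbind(c(0, 0, 0), c(1.7, 0, 0))   # beyond R0
  cfg <- sim_config(n_tf = 0, t_pushoff = 0, t_equil = 0, t_prod = 1,
                    sample_interval = 1)
  expect_error(run_simulation(fib, cfg, seed = 1,
                              state = system_state(pos, tf_active = logical(0))),
               "overstretched.*1.*2")
})

test_that("initial conformation is valid, seeded, and confined", {
  fib <- build_toy_fibre(M = 200, n_tu = 10, seed = 4)
  a <- initial_conformation(fib, n_tf = 5, seed = 7)
  b <- initial_conformation(fib, n_tf = 5, seed = 7)
  expect_identical(a, b)
  bonds <- sqrt(rowSums(diff(a[seq_len(200), ])^2))
  expect_lt(max(bonds), 1.6)               # all FENE bonds below R0
  conf <- confinement("ellipsoid", semi_axes = c(12, 10, 8))
  p <- initial_conformation(fib, n_tf = 5, conf = conf, seed = 7)
  expect_lt(max(scaled_radius(p, conf)), 1)
})
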