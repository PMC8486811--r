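test_that("WCA potential: cutoff, contact value, finite-difference force", {
  p <- interaction_params()
  rc <- 2^(1 / 6)
  expect_equal(wca_energy_force(rc, p)$energy, 0)
  expect_equal(wca_energy_force(rc + 1e-9, p)$force, 0)
  expect_equal(wca_energy_force(1, p)$energy, 1)           # 4(1-1+1/4) kBT
  # continuity at the cutoff
  expect_lt(abs(wca_energy_force(rc - 1e-8, p)$energy), 1e-6)
  for (r in c(0.85, 0.95, 1.05, 1.1)) {
    fd <- fd_force(function(x) wca_energy_force(x, p)$energy, r)
    expect_lt(abs(wca_energy_force(r, p)$force - fd) / abs(fd), 1e-6)
  }
  expect_error(wca_energy_force(0, p), "positive")
})

test_that("FENE spring: limit behaviour, reference values, overstretch abort", {
  p <- interaction_params()
  expect_lt(fene_energy_force(1e-8, p)$energy, 1e-10)
  expect_equal(fene_energy_force(1, p)$energy,
               -0.5 * 30 * 1.6^2 * log(1 - (1 / 1.6)^2), tolerance = 1e-12)
  expect_equal(fene_energy_force(1, p)$energy, 19.03, tolerance = 1e-3)
  expect_gt(fene_energy_force(1.59, p)$energy, 100)
  # monotone increasing energy
  rs <- seq(0.1, 1.55, by = 0.05)
  expect_true(all(diff(fene_energy_force(rs, p)$energy) > 0))
  for (r in c(0.5, 1.0, 1.4)) {
    fd <- fd_force(function(x) fene_energy_force(x, p)$energy, r)
    expect_lt(abs(fene_energy_force(r, p)$force - fd) / abs(fd), 1e-6)
  }
  expect_error(fene_energy_force(1.6, p), "overstretch")
  expect_error(fene_energy_force(1.7, p), "overstretch")
})

test_that("harmonic bond: minimum at Rbar, quadratic value, force", {
  expect_equal(harmonic_energy_force(1.1, 1.1)$energy, 0)
  expect_equal(harmonic_energy_force(1.2, 1.1, Kh = 100)$energy, 1)
  expect_equal(harmonic_energy_force(1.9, 1.8, Kh = 100)$energy, 1)
  r <- 1.27
  fd <- fd_force(function(x) harmonic_energy_force(x, 1.1, 100)$energy, r)
  expect_equal(harmonic_energy_force(r, 1.1, 100)$force, fd, tolerance = 1e-6)
  # defaults used for loop vs backbone bonds
  p <- interaction_params()
  expect_equal(p$Rbar_backbone, 1.1)
  expect_equal(p$Rbar_loop, 1.8)
})

test_that("Kratky-Porod bending: limits, net force/torque, finite differences", {
  p <- interaction_params()
  collinear <- kratky_porod_energy_forces(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), p)
  expect_equal(collinear$energy, 0)
  expect_equal(max(abs(collinear$forces)), 0)
  reversal <- kratky_porod_energy_forces(c(0, 0, 0), c(1, 0, 0),
                                         c(0, 1e-9, 0), p)
  expect_equal(reversal$energy, 2 * 3, tolerance = 1e-6)
  withr::with_seed(42, {
    for (rep in 1:5) {
      ri <- rnorm(3); rj <- ri + rnorm(3); rk <- rj + rnorm(3)
      kp <- kratky_porod_energy_forces(ri, rj, rk, p)
      # net force and net torque vanish
      expect_lt(max(abs(colSums(kp$forces))), 1e-10)
      torque <- colSums(rbind(cross3(ri, kp$forces["i", ]),
                              cross3(rj, kp$forces["j", ]),
                              cross3(rk, kp$forces["k", ])))
      expect_lt(max(abs(torque)), 1e-9)
      # finite differences on every coordinate
      h <- 1e-6
      for (part in 1:3) {
        for (dim in 1:3) {
          args <- list(ri, rj, rk)
          args[[part]][dim] <- args[[part]][dim] + h
          up <- do.call(kratky_porod_energy_forces, c(args, list(p)))$energy
          args[[part]][dim] <- args[[part]][dim] - 2 * h
          dn <- do.call(kratky_porod_energy_forces, c(args, list(p)))$energy
          fd <- -(up - dn) / (2 * h)
          expect_equal(unname(kp$forces[part, dim]), fd, tolerance = 1e-5)
        }
      }
    }
  })
  expect_error(kratky_porod_energy_forces(c(0, 0, 0), c(0, 0, 0),
                                          c(1, 0, 0), p), "coincident")
})

test_that("truncated-shifted LJ: zero at cutoff, well depth, WCA reduction", {
  p <- interaction_params()
  expect_equal(lj_trunc_shifted_energy_force(1.8, 8, 1.8, p)$energy, 0)
  expect_lt(abs(lj_trunc_shifted_energy_force(1.8 - 1e-8, 8, 1.8, p)$energy),
            1e-6)
  # minimum near 2^(1/6) sigma, depth 0.8858*eps below zero
  d0 <- 2^(1 / 6)
  e0 <- lj_trunc_shifted_energy_force(d0, 8, 1.8, p)$energy
  expect_equal(e0, -0.8858 * 8, tolerance = 1e-3)
  # with rc = 2^(1/6) the truncated-shifted LJ reduces to the WCA potential
  expect_equal(lj_trunc_shifted_energy_force(1.0, 1, d0, p)$energy,
               wca_energy_force(1.0, p)$energy, tolerance = 1e-12)
  for (d in c(1.0, 1.2, 1.5, 1.7)) {
    fd <- fd_force(function(x)
      lj_trunc_shifted_energy_force(x, 3, 1.8, p)$energy, d)
    expect_equal(lj_trunc_shifted_energy_force(d, 3, 1.8, p)$force, fd,
                 tolerance = 1e-5)
  }
})

test_that("pair rule maps bead class and TF state to interaction", {
  p <- interaction_params()
  expect_equal(pair_rule("TU", "active", p), list(eps = 8, rc = 1.8))
  expect_equal(pair_rule("euchromatin", "active", p), list(eps = 3, rc = 1.8))
  expect_equal(pair_rule("heterochromatin", "active", p),
               list(eps = 1, rc = 2^(1 / 6)))
  expect_equal(pair_rule("TU", "inactive", p), list(eps = 1, rc = 2^(1 / 6)))
  expect_error(pair_rule("centromere", "active", p))
})

test_that("cell-list forces match the brute-force O(N^2) oracle", {
  fib <- build_toy_fibre(M = 40, n_tu = 8, seed = 7)
  fib <- add_loops(fib, cbind(5L, 25L))
  for (seed in 1:3) {
    st <- random_test_state(fib, n_tf = 10, seed = seed)
    eng <- total_forces(st, fib)
    ora <- brute_force_total(st, fib)
    scale <- max(abs(ora$forces), 1)
    expect_lt(max(abs(eng$forces - ora$forces)) / scale, 1e-10)
    expect_equal(eng$energy, ora$energy, tolerance = 1e-10)
    # Newton's third law: internal forces sum to zero
    expect_lt(max(abs(colSums(eng$forces))), 1e-9)
  }
})

test_that("isolated particles beyond all cutoffs feel no force", {
  fib <- chromatin_fibre(c("TU", "euchromatin"))
  pos <- rbind(c(0, 0, 0), c(1.05, 0, 0), c(10, 10, 10))
  st <- system_state(pos, tf_active = TRUE)
  f <- total_forces(st, fib)
  expect_equal(f$forces[3, ], c(0, 0, 0))
})
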