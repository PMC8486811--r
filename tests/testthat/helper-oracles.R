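# Brute-force O(N^2) force/energy oracle built from the scalar potential
# functions, independent of the compiled cell-list engine.

brute_force_total <- function(state, fibre, params = interaction_params(),
                              conf = confinement("none")) {
  pos <- state$positions
  N <- nrow(pos)
  M <- fibre$n_beads
  F <- matrix(0, N, 3)
  U <- 0
  cls <- fibre$bead_class
  tfstate <- ifelse(state$tf_active, "active", "inactive")
  bonded <- matrix(FALSE, N, N)
  for (k in seq_len(nrow(fibre$bonds))) {
    bonded[fibre$bonds$i[k], fibre$bonds$j[k]] <- TRUE
    bonded[fibre$bonds$j[k], fibre$bonds$i[k]] <- TRUE
  }
  add_pair <- function(i, j, e, f) {
    dvec <- pos[i, ] - pos[j, ]
    r <- sqrt(sum(dvec^2))
    F[i, ] <<- F[i, ] + f * dvec / r
    F[j, ] <<- F[j, ] - f * dvec / r
    U <<- U + e
  }
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (bonded[i, j]) next   # bonded pairs handled below
      if (i <= M && j <= M) {
        ef <- wca_energy_force(r, params)
      } else if (i > M && j > M) {
        ef <- wca_energy_force(r, params)
      } else {
        bead <- if (i <= M) i else j
        tf <- if (i <= M) j else i
        rule <- pair_rule(cls[bead], tfstate[tf - M], params)
        ef <- lj_trunc_shifted_energy_force(r, rule$eps, rule$rc, params)
      }
      add_pair(i, j, ef$energy, ef$force)
    }
  }
  for (k in seq_len(nrow(fibre$bonds))) {
    i <- fibre$bonds$i[k]; j <- fibre$bonds$j[k]
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    kind <- fibre$bonds$kind[k]
    if (kind == "fene") {
      ef <- fene_energy_force(r, params)
      wf <- wca_energy_force(r, params)
      add_pair(i, j, ef$energy + wf$energy, ef$force + wf$force)
    } else {
      Rbar <- if (kind == "harmonic_backbone") params$Rbar_backbone
              else params$Rbar_loop
      ef <- harmonic_energy_force(r, Rbar, params$Kh)
      add_pair(i, j, ef$energy, ef$force)
    }
  }
  for (k in seq_len(nrow(fibre$angles))) {
    tri <- fibre$angles[k, ]
    kp <- kratky_porod_energy_forces(pos[tri$i, ], pos[tri$j, ], pos[tri$k, ],
                                     params)
    U <- U + kp$energy
    F[tri$i, ] <- F[tri$i, ] + kp$forces["i", ]
    F[tri$j, ] <- F[tri$j, ] + kp$forces["j", ]
    F[tri$k, ] <- F[tri$k, ] + kp$forces["k", ]
  }
  if (conf$kind == "ellipsoid") {
    for (i in seq_len(N))
      F[i, ] <- F[i, ] + confinement_force(pos[i, ], conf, params)
  }
  list(forces = F, energy = U)
}

# a well-separated random configuration: a coiled chain walk plus TFs placed
# with a minimum distance from everything
random_test_state <- function(fibre, n_tf, seed = 1, min_sep = 0.85) {
  withr::with_seed(seed, {
    M <- fibre$n_beads
    pos <- matrix(0, M + n_tf, 3)
    for (i in seq_len(M - 1)) {
      repeat {
        step <- stats::rnorm(3)
        cand <- pos[i, ] + 1.05 * step / sqrt(sum(step^2))
        prev <- pos[seq_len(max(1, i - 1)), , drop = FALSE]
        if (i == 1 || min(colSums((t(prev) - cand)^2)) > min_sep^2) break
      }
      pos[i + 1, ] <- cand
    }
    box <- apply(pos[seq_len(M), , drop = FALSE], 2, range)
    for (k in seq_len(n_tf)) {
      repeat {
        cand <- stats::runif(3, box[1, ] - 1, box[2, ] + 1)
        if (min(colSums((t(pos[seq_len(M + k - 1), , drop = FALSE]) -
                           cand)^2)) > min_sep^2) break
      }
      pos[M + k, ] <- cand
    }
    tf_active <- stats::runif(n_tf) < 0.5
    system_state(pos, tf_active = tf_active)
  })
}

# central finite-difference gradient of a scalar energy function of r
fd_force <- function(energy_fn, r, h = 1e-6) {
  -(energy_fn(r + h) - energy_fn(r - h)) / (2 * h)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
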