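#' Spherical container for chromatin-fragment simulations
#'
#' Fragment (toy-chain) runs use a spherical container holding the bead
#' volume fraction at a dilute value (default 2%, versus ~14% for a full
#' chromosome territory).  A bounded volume keeps the TF pool at a fixed
#' concentration; in an unbounded volume the unbound TFs would dilute away
#' over the run and transcription would die out.  The 2% default is
#' calibrated so the wild-type reference chain reproduces the model's
#' characteristic sub-saturating activity range (roughly 5-95% across
#' TUs); see the methods vignette.
#'
#' @param n_beads Number of chromatin beads.
#' @param volume_fraction Bead volume fraction in the container.
#' @return A [confinement()] of kind `"ellipsoid"` with equal semi-axes.
#' @export
toy_confinement <- function(n_beads = 1000, volume_fraction = 0.02) {
  confinement("ellipsoid",
              ellipsoid_for_territory(n_beads, volume_fraction, c(1, 1, 1)))
}

#' Confinement specification
#'
#' @param kind `"none"` or `"ellipsoid"`.
#' @param semi_axes Length-3 numeric (a, b, c), sigma units, a >= b >= c > 0.
#' @return A list of class `confinement`.
#' @export
confinement <- function(kind = c("none", "ellipsoid"), semi_axes = NULL) {
  kind <- match.arg(kind)
  if (kind == "ellipsoid") {
    stopifnot(length(semi_axes) == 3, all(semi_axes > 0),
              !is.unsorted(rev(semi_axes)))
  }
  structure(list(kind = kind, semi_axes = semi_axes), class = "confinement")
}

#' Scaled radius of positions within an ellipsoid
#'
#' `sqrt((x/a)^2 + (y/b)^2 + (z/c)^2)`; below 1 means inside.
#' @param positions N x 3 matrix.
#' @param conf A [confinement()] of kind `"ellipsoid"`.
#' @export
scaled_radius <- function(positions, conf) {
  stopifnot(conf$kind == "ellipsoid")
  ax <- conf$semi_axes
  sqrt((positions[, 1] / ax[1])^2 + (positions[, 2] / ax[2])^2 +
         (positions[, 3] / ax[3])^2)
}

#' Confinement force on a single position
#'
#' Zero strictly inside the shrunken ellipsoid (wall minus the repulsive
#' range); a WCA-like inward push near the wall, measured along the ray from
#' the centre.  This mirrors the engine's wall term for testing.
#' @param position Length-3 numeric.
#' @param conf A [confinement()] of kind `"ellipsoid"`.
#' @param params An [interaction_params()] object.
#' @return Length-3 force vector.
#' @export
confinement_force <- function(position, conf, params = interaction_params()) {
  stopifnot(conf$kind == "ellipsoid")
  r <- sqrt(sum(position^2))
  if (r < 1e-12) return(c(0, 0, 0))
  n <- position / r
  Rsurf <- 1 / sqrt(sum((n / conf$semi_axes)^2))
  h <- Rsurf - r
  if (h >= params$rc_rep) return(c(0, 0, 0))
  h <- max(h, 0.6)
  s6 <- (1 / h)^6
  fmag <- 4 * params$kBT * (12 * s6^2 - 6 * s6) / h
  -fmag * n
}

#' System state container
#'
#' @param positions (M + n_tf) x 3 matrix of coordinates (sigma units);
#'   chromatin beads first, then TF spheres.
#' @param velocities Matching matrix (defaults to zeros).
#' @param tf_active Logical vector, one flag per TF.
#' @param time Elapsed time in Brownian times.
#' @return A list of class `system_state`.
#' @export
system_state <- function(positions, velocities = NULL, tf_active = logical(0),
                         time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  stopifnot(identical(dim(velocities), dim(positions)))
  structure(list(positions = positions, velocities = velocities,
                 tf_active = tf_active, time = time),
            class = "system_state")
}

#' Stochastic TF state switching (one attempt)
#'
#' Each active TF deactivates with probability `alpha_off * attempt_interval`
#' and each inactive one activates with probability
#' `alpha_on * attempt_interval`; the stationary active fraction is
#' `alpha_on / (alpha_on + alpha_off)`.
#'
#' @param tf_states Logical vector (TRUE = active).
#' @param switching A [switching_params()] object.
#' @return Updated logical vector.
#' @export
switch_tf_states <- function(tf_states, switching) {
  n <- length(tf_states)
  if (n == 0) return(tf_states)
  u <- stats::runif(n)
  ifelse(tf_states, u >= switching$p_off, u < switching$p_on)
}

#' Initial conformation: biased self-avoiding walk plus free TFs
#'
#' Grows the chain as a random walk with bond length 1.1 sigma, biased away
#' from recent self-overlaps, inside the confinement (shrunken by one
#' repulsive range) or in a loose box for unconfined runs; TFs are placed
#' uniformly in the accessible volume.  Remaining overlaps are relaxed by the
#' capped-force push-off phase at the start of a run.
#'
#' @param fibre A `ChromatinFibre`.
#' @param n_tf Number of TF spheres.
#' @param conf A [confinement()] spec.
#' @param seed Integer seed.
#' @return An (M + n_tf) x 3 position matrix.
#' @export
initial_conformation <- function(fibre, n_tf, conf = confinement("none"),
                                 seed = 1L) {
  M <- fibre$n_beads
  withr::with_seed(seed, {
    bond <- 1.1
    if (conf$kind == "ellipsoid") {
      ax <- conf$semi_axes - 2^(1 / 6)
      if (any(ax <= bond)) stop("confinement too small for the chain")
      inside <- function(p) sum((p / ax)^2) < 1
      origin <- c(0, 0, 0)
    } else {
      # loose box sized for a dense-coil density of ~0.1
      L <- max(4, (M / 0.2)^(1 / 3))
      inside <- function(p) all(abs(p) < L / 2)
      origin <- c(0, 0, 0)
    }
    pos <- matrix(0, M + n_tf, 3)
    pos[1, ] <- origin
    window <- 15L  # beads checked for self-overlap while growing
    for (i in seq_len(M - 1L)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        d <- stats::rnorm(3)
        cand <- pos[i, ] + bond * d / sqrt(sum(d^2))
        if (!inside(cand)) next
        lo <- max(1L, i - window)
        d2 <- colSums((t(pos[lo:i, , drop = FALSE]) - cand)^2)
        # allow the bonded neighbour, reject overlap with earlier beads
        if (length(d2) > 1 && min(d2[-length(d2)]) < 0.64) next
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place bead ", i + 1L, " within the confinement")
      pos[i + 1L, ] <- cand
    }
    if (n_tf > 0) {
      if (conf$kind == "ellipsoid") {
        k <- 0L
        while (k < n_tf) {
          cand <- (2 * stats::runif(3) - 1) * ax
          if (inside(cand)) { k <- k + 1L; pos[M + k, ] <- cand }
        }
      } else {
        rng <- apply(pos[seq_len(M), ], 2, range)
        for (k in seq_len(n_tf))
          pos[M + k, ] <- stats::runif(3, rng[1, ], rng[2, ])
      }
    }
    pos
  })
}

#' Simulation configuration for a single condition
#'
#' Durations are in Brownian times and converted to steps with `dt`.
#' Defaults are the desk-scale protocol; full-scale runs
#' (1e5 tau_B production, hundreds to a thousand runs) use the same code.
#'
#' @param n_tf Total number of TF spheres (active + inactive).
#' @param params An [interaction_params()] object.
#' @param switching A [switching_params()] object.
#' @param conf A [confinement()] spec.
#' @param thermostat A [thermostat_params()] object (seed ignored here; the
#'   per-run seed is supplied to [run_simulation()]).
#' @param t_pushoff Capped-force push-off duration (tau_B).
#' @param t_equil Equilibration duration (tau_B), not recorded.
#' @param t_prod Production duration (tau_B).
#' @param sample_interval Transcription sampling interval (tau_B).
#' @param traj_interval Trajectory frame interval (tau_B); 0 disables frames.
#' @param record_all_beads Record the transcription read-out for every bead
#'   (whole-chromosome mode) instead of TUs only.
#' @param pushoff_dmax Maximum per-step particle displacement (sigma) during
#'   the push-off phase (velocity-limited integration).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tf = 20, params = interaction_params(),
                       switching = switching_params(),
                       conf = confinement("none"),
                       thermostat = thermostat_params(),
                       t_pushoff = 100, t_equil = 400, t_prod = 1000,
                       sample_interval = 100, traj_interval = 0,
                       record_all_beads = FALSE, pushoff_dmax = 0.05) {
  stopifnot(n_tf >= 0, t_pushoff >= 0, t_equil >= 0, t_prod >= 0,
            sample_interval > 0)
  structure(list(n_tf = as.integer(n_tf), params = params,
                 switching = switching, conf = conf, thermostat = thermostat,
                 t_pushoff = t_pushoff, t_equil = t_equil, t_prod = t_prod,
                 sample_interval = sample_interval,
                 traj_interval = traj_interval,
                 record_all_beads = record_all_beads, pushoff_dmax = pushoff_dmax),
            class = "sim_config")
}

#' Run one Langevin dynamics simulation
#'
#' Builds the initial state (seeded), runs capped-force push-off and
#' equilibration (not recorded), then production with stochastic TF switching
#' and transcription sampling.  Fully reproducible from (fibre, config,
#' seed): the same inputs give bit-identical records.
#'
#' @param fibre A `ChromatinFibre`.
#' @param config A [sim_config()].
#' @param seed Integer seed for this run (drives conformation, initial TF
#'   states, thermal noise and switching).
#' @param state Optional initial [system_state()]; by default one is built
#'   with [initial_conformation()].
#' @param run_id Identifier stored in the activity record.
#' @return A list of class `sim_result` with elements `activity`
#'   (an `activity_record`), `final_state`, `trajectory` (beads x 3 x frames
#'   array or NULL), `active_tf_count`, and `diagnostics`.
#' @export
run_simulation <- function(fibre, config, seed = 1L, state = NULL,
                           run_id = paste0("run", seed)) {
  validate_fibre(fibre)
  dt <- config$thermostat$dt
  sw <- config$switching
  switch_every <- as.integer(round(sw$attempt_interval / dt))
  if (abs(switch_every * dt - sw$attempt_interval) > 1e-9)
    stop("attempt_interval must be a multiple of dt")
  if (is.null(state)) {
    pos <- initial_conformation(fibre, config$n_tf, config$conf, seed = seed)
    f <- if (is.na(sw$stationary_active)) 0.5 else sw$stationary_active
    tf0 <- withr::with_seed(seed + 1L,
                            stats::runif(config$n_tf) < f)
    state <- system_state(pos, tf_active = tf0)
    init_vel <- TRUE
  } else {
    init_vel <- FALSE
  }
  record_idx <- if (config$record_all_beads) seq_len(fibre$n_beads)
                else tu_indices(fibre)
  code <- particle_codes(fibre, state$tf_active)
  res <- .run_sim_cpp(state$positions, state$velocities, code,
                      fibre$bonds$i, fibre$bonds$j,
                      bond_kind_code(fibre$bonds$kind),
                      fibre$n_beads, as.integer(record_idx),
                      unclass(config$params), config$conf,
                      dt, config$thermostat$gamma,
                      config$thermostat$temperature, as.integer(seed),
                      as.integer(round(config$t_pushoff / dt)),
                      as.integer(round(config$t_equil / dt)),
                      as.integer(round(config$t_prod / dt)),
                      as.integer(round(config$sample_interval / dt)),
                      switch_every, sw$p_on, sw$p_off,
                      if (config$traj_interval > 0)
                        as.integer(round(config$traj_interval / dt)) else 0L,
                      config$pushoff_dmax, init_vel)
  rec <- activity_record(res$samples, record_idx,
                         sample_interval = config$sample_interval,
                         run_id = run_id, seed = seed)
  final <- system_state(res$positions, res$velocities, res$tf_active,
                        time = state$time + config$t_pushoff +
                          config$t_equil + config$t_prod)
  structure(list(activity = rec, final_state = final,
                 trajectory = res$trajectory,
                 active_tf_count = res$active_tf_count,
                 diagnostics = list(n_rebuilds = res$n_rebuilds,
                                    mean_ke_per_particle = res$mean_ke_per_particle)),
            class = "sim_result")
}

#' Run an ensemble of replicate simulations
#'
#' Per-run seeds are `base_seed + run_index`, so paired conditions can share
#' seeds for variance reduction.
#'
#' @param fibre A `ChromatinFibre`.
#' @param config A [sim_config()].
#' @param n_runs Number of replicates.
#' @param base_seed Base seed.
#' @return A list of class `sim_ensemble`: `records` (list of activity
#'   records) plus the config and fibre used.
#' @export
simulate_ensemble <- function(fibre, config, n_runs = 10, base_seed = 1L) {
  records <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    records[[r]] <- run_simulation(fibre, config, seed = base_seed + r,
                                   run_id = paste0("run", r))$activity
  }
  structure(list(records = records, fibre = fibre, config = config,
                 base_seed = base_seed),
            class = "sim_ensemble")
}
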