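# Shared, lazily computed simulation ensembles reused across test files.
# Scales are desk-scale reductions of the published protocols (the methods
# vignette documents the choice); seeds are fixed so the suite is
# deterministic.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# reference desk-scale protocols.  The mature protocol gives the cluster
# pattern time to settle (the pattern matures over ~2500 tau_B) and is used
# for the activity-pattern and perturbation comparisons; the short protocol
# is for smoke-level checks.
mature_config <- function(...) {
  sim_config(n_tf = 20, t_pushoff = 100, t_equil = 1900, t_prod = 3000,
             sample_interval = 100, conf = toy_confinement(), ...)
}

ci_config <- function(t_prod = 2000, ...) {
  sim_config(n_tf = 20, t_pushoff = 100, t_equil = 400, t_prod = t_prod,
             sample_interval = 100, conf = toy_confinement(), ...)
}

wt_ensemble <- function() cached("wt", {
  simulate_ensemble(toy_reference_fibre(), mature_config(), n_runs = 12,
                    base_seed = 100)
})

het_ensemble <- function() cached("het", {
  simulate_ensemble(toy_het_island_fibre(), mature_config(), n_runs = 4,
                    base_seed = 100)
})

ko930_ensemble <- function() cached("ko930", {
  simulate_ensemble(knockout_tu(toy_reference_fibre(), 930L),
                    mature_config(), n_runs = 5, base_seed = 100)
})

# equipartition / harmonic dimer / persistence-length measurements
thermo_suite <- function() cached("thermo", {
  # kinetic temperature of an interacting chain
  chain <- build_toy_fibre(M = 200, n_tu = 0, seed = 1)
  cfg <- sim_config(n_tf = 0, t_pushoff = 20, t_equil = 30, t_prod = 1000,
                    sample_interval = 10)
  ke_ratio <- run_simulation(chain, cfg,
                             seed = 5)$diagnostics$mean_ke_per_particle / 1.5

  # harmonic dimer bond-extension fluctuations
  dimer <- chromatin_fibre(c("euchromatin", "euchromatin"),
                           backbone = "harmonic_backbone")
  dcfg <- sim_config(n_tf = 0, t_pushoff = 0, t_equil = 20, t_prod = 2000,
                     sample_interval = 100, traj_interval = 1)
  tr <- run_simulation(dimer, dcfg, seed = 9)$trajectory
  ext <- sqrt(colSums((tr[1, , ] - tr[2, , ])^2))

  # phantom chain (bonded + bending only) tangent decorrelation
  ph <- build_toy_fibre(M = 100, n_tu = 0, seed = 2)
  p <- interaction_params(); p$phantom <- TRUE
  pcfg <- sim_config(n_tf = 0, params = p, t_pushoff = 0, t_equil = 200,
                     t_prod = 2000, sample_interval = 100, traj_interval = 20)
  ptr <- run_simulation(ph, pcfg, seed = 21)$trajectory
  smax <- 7
  corr <- numeric(smax)
  for (s in seq_len(smax)) {
    acc <- c()
    for (f in seq_len(dim(ptr)[3])) {
      tang <- diff(ptr[, , f])
      tang <- tang / sqrt(rowSums(tang^2))
      n <- nrow(tang)
      acc <- c(acc, rowSums(tang[1:(n - s), , drop = FALSE] *
                              tang[(1 + s):n, , drop = FALSE]))
    }
    corr[s] <- mean(acc)
  }
  lp_fit <- -1 / unname(stats::coef(stats::lm(log(corr) ~ seq_len(smax)))[2])

  list(ke_ratio = ke_ratio, dimer_mean = mean(ext),
       dimer_var = stats::var(ext), lp_fit = lp_fit)
})

# paired binding vs non-binding ensembles for the clustering comparison:
# mean active-TF cluster size per run, shared seeds across arms
clustering_suite <- function() cached("clustering", {
  fib <- toy_reference_fibre()
  mk <- function(eps_strong, eps_weak) {
    sim_config(n_tf = 20,
               params = interaction_params(eps_strong = eps_strong,
                                           eps_weak = eps_weak),
               conf = toy_confinement(),
               t_pushoff = 100, t_equil = 200, t_prod = 500,
               sample_interval = 100, traj_interval = 100)
  }
  mean_cluster <- function(cfg, seed) {
    res <- run_simulation(fib, cfg, seed = seed)
    tr <- res$trajectory
    sizes <- c()
    for (f in seq(2, dim(tr)[3])) {
      st <- system_state(tr[, , f], tf_active = res$final_state$tf_active)
      sizes <- c(sizes, tf_cluster_sizes(st, fib))
    }
    mean(sizes)
  }
  binding <- control <- numeric(6)
  for (k in 1:6) {
    binding[k] <- mean_cluster(mk(8, 3), seed = 200 + k)
    control[k] <- mean_cluster(mk(0, 0), seed = 200 + k)
  }
  list(binding = binding, control = control)
})

# largest-component fraction at sub-saturating vs saturating TF numbers.
# At desk scale the network is built from the pooled binary transcription
# samples of all runs (within-run co-bursting): run-level correlations need
# hundreds of replicates before any edge can clear a significance test,
# while co-bursting discriminates the two regimes with a handful of runs.
percolation_suite <- function() cached("percolation", {
  fib <- toy_reference_fibre()
  frac <- function(n_tf, base_seed) {
    cfg <- sim_config(n_tf = n_tf, conf = toy_confinement(),
                      t_pushoff = 100, t_equil = 400,
                      t_prod = 1000, sample_interval = 100)
    ens <- simulate_ensemble(fib, cfg, n_runs = 7, base_seed = base_seed)
    pooled <- do.call(rbind, lapply(ens$records, function(r) r$samples))
    colnames(pooled) <- ens$records[[1]]$tu_indices
    corr <- suppressWarnings(correlation_matrix(pooled))
    net <- build_network(corr, r_min = 0.4, p_max = 1e-3)
    largest_component_fraction(net)
  }
  list(fraction_n10 = frac(20, 300), fraction_n60 = frac(120, 300))
})
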