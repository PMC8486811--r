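# chromatx

Polymer simulation of transcription and the regulatory networks that
emerge from 3D genome organisation.

## The problem

Most variation found by GWAS sits in non-coding regulatory elements, each
with a tiny effect on many genes — yet overexpressing a handful of
transcription factors can flip a cell state. `chromatx` implements a
fitting-free physical model that reconciles the two observations using
nothing but polymer physics: a chromatin fibre is a bead-and-spring chain
(one bead = 3 kbp = 30 nm = σ), some beads are transcription units (TUs),
and spheres representing transcription-factor/polymerase complexes ("TFs")
bind them multivalently while switching between active and inactive states.
Everything else — transcriptional heterogeneity, bursting, correlated
activity, in-silico eQTLs — emerges from the *bridging-induced attraction*:
a bound multivalent TF loops chromatin, concentrates binding sites, and
recruits more TFs, so bound TFs condense into transcription-factory-like
clusters that scarce TFs must be shared between.

It is aimed at chromatin biophysicists and regulatory genomicists who want
to predict transcriptional activity patterns from genome annotation alone,
or to probe how knockouts, loops, heterochromatin and deletions
redistribute activity.

## The model in brief

* Chromatin beads repel via Weeks–Chandler–Anderson (WCA);
  consecutive beads are FENE-bonded (Kremer–Grest chain,
  `Kf = 30 kBT/σ²`, `R0 = 1.6 σ`); bending is Kratky–Porod with
  `ℓp = 3 σ`. Looped chains use harmonic bonds (`Kh = 100 kBT/σ²`,
  rest lengths 1.1 σ backbone, 1.8 σ loops).
* Active TFs bind TUs with a truncated-shifted LJ well of `8 kBT`
  (cutoff 1.8 σ) and euchromatin with `3 kBT`; heterochromatin and
  inactive TFs are purely repulsive. TF states flip every 100 τ_B with
  rates `α = 1e-5 τ_B⁻¹`.
* Underdamped Langevin dynamics (velocity-Verlet with friction and noise
  in the half-kicks, `Δt = 0.01 τ_B`) in a compiled (Rcpp) engine with
  cell-list/Verlet neighbour search; fragment runs live in a spherical
  container at 2% bead volume fraction so the TF pool keeps a fixed,
  sub-saturating concentration.
* A TU is *transcribed* whenever an active TF centre is within 1.8 σ;
  activities, bursts, TF-cluster statistics, and run-to-run Pearson
  correlation networks are computed from the sampled binary series.

## Worked example

Twelve desk-scale replicate simulations of the reference 1000-bead chain
with 39 TUs and 20 switchable TFs (1900 τ_B equilibration so the cluster
pattern matures, 3000 τ_B production; a few minutes per run):

```r
library(chromatx)

fibre  <- toy_reference_fibre()
config <- sim_config(n_tf = 20, conf = toy_confinement(),
                     t_pushoff = 100, t_equil = 1900,
                     t_prod = 3000, sample_interval = 100)
ens    <- simulate_ensemble(fibre, config, n_runs = 12, base_seed = 100)

prof <- activity_profile(ens)
head(prof, 3)
#>   tu_index activity  class
#> 1       25     0.59 medium
#> 2       30     0.72   high
#> 3       33     0.73   high

nearest_tu_distance_correlation(prof$activity, prof$tu_index)$spearman
#> [1] -0.782
```

Although every TU binds TFs with identical affinity, activities span the
full range, and a TU's activity is set by its 1D isolation: closely spaced
TUs share TF clusters and are busy, isolated ones are starved (strongly
negative Spearman correlation with nearest-TU distance). A knockout
experiment:

```r
ko <- simulate_ensemble(knockout_tu(fibre, 930), config, n_runs = 5,
                        base_seed = 100)
da <- differential_activity(per_run_activity(ens)[1:5, ],
                            per_run_activity(ko))
subset(da$table, tu_index %in% c(930, 931))
#>    tu_index activity_a activity_b effect     t        p
#> 36      930      0.993      0.180 -0.813 -5.50 0.000576
#> 37      931      1.000      0.267 -0.733 -3.91 0.004458

mean(da$table$effect[abs(da$table$tu_index - 930) > 200])
#> [1] 0.049
```

The knocked-out TU loses almost all its activity (the residue is active
TFs passing within read-out range), its immediately adjacent partner TU
931 collapses with it (they shared a cluster), and distant TUs gain
activity on average because competition for the TF pool is released — the
model's reading of an eQTL.

Whole-chromosome mode classifies 3-kbp beads from DHS/H3K27ac (or
chromatin-state) tracks via `classify_beads_dhs()` /
`classify_beads_hmm()`, confines the chain in an ellipsoidal territory
(`ellipsoid_for_territory()`, 14% volume fraction), and compares simulated
activity with a signal track by rank quintiles
(`rank_quintile_compare()`) and Hi-C-like contact maps
(`contact_map_from_trajectories()`, `contact_decay_exponent()`).
`synthetic_annotation_fixture()` generates realistic stand-in tracks so the
whole pipeline runs offline.

A thin command-line wrapper (`inst/cli/chromatx`) exposes
`simulate | analyze | network | perturb | annotate | compare`
over flat `key = value` config files; full-scale (cluster) and desk-scale
protocol files ship under `inst/configs/`.

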