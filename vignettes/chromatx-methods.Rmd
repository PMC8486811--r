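---
title: "chromatx: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromatx: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`chromatx` simulates transcription as a purely structural, fitting-free
process.  A chromatin fibre is a bead-and-spring polymer: each bead spans
3 kbp (30 nm, one unit `sigma`).  A subset of beads are transcription units
(TUs) -- promoter/enhancer proxies carrying high-affinity binding sites.
Separate spheres represent complexes of transcription factors and
polymerase ("TFs").  A TF switches stochastically between an *active*
(binding) and *inactive* (inert) state; when active it binds TUs strongly
(8 kBT), other euchromatin beads weakly (3 kBT), and heterochromatin not at
all.  A TU is scored as *transcribed* at a sample time if at least one
active TF centre lies within 1.8 sigma of it.

Everything downstream emerges from one physical mechanism, the
bridging-induced attraction: a multivalent binder that bridges two chromatin
segments locally concentrates binding sites, which recruits more binders.
Bound TFs therefore condense into clusters resembling transcription
factories, without any TF-TF attraction.  Because TFs are scarce
(sub-saturating), TUs compete for them: TUs with close 1D neighbours share
clusters and are transcribed often; isolated TUs are not.  This produces
heterogeneous activity, bursting, and correlated activity patterns that we
read out as a regulatory network.

### Interactions

* Chromatin-chromatin and TF-TF pairs: Weeks-Chandler-Anderson repulsion
  (`wca_energy_force()`), i.e. a 12-6 Lennard-Jones truncated at
  `2^(1/6) sigma` and shifted to zero.
* Chain connectivity: FENE springs (`fene_energy_force()`, `Kf = 30
  kBT/sigma^2`, `R0 = 1.6 sigma`) combined with the WCA core, the standard
  Kremer-Grest bead-spring chain.  The paper-level protocol for chains with
  permanent loops replaces FENE by stiff harmonic springs (`Kh = 100
  kBT/sigma^2`, rest length 1.1 sigma for backbone, 1.8 sigma for loop
  bonds); `add_loops()` performs this conversion automatically.
* Bending stiffness: a Kratky-Porod term `(kBT lp/sigma)(1 - cos theta)` on
  every consecutive bead triplet with `lp = 3 sigma`.  For the discrete
  chain this yields a correlation-length persistence of about
  `-1/log(coth(3) - 1/3) ~ 2.5` bead lengths, within the accepted range for
  chromatin; the test suite checks the fitted value against this band.
* TF-chromatin: truncated-and-shifted LJ (`lj_trunc_shifted_energy_force()`)
  with `(eps, rc)` chosen by `pair_rule()` from the bead class and TF state.
  Inactive TFs are purely repulsive towards everything.

### Dynamics

Langevin dynamics in reduced units (`sigma = kBT = m = gamma = 1`, so the
LJ and Brownian times coincide; one Brownian time `tau_B` maps to roughly
0.6-6 ms depending on the assumed nucleoplasmic viscosity).  The
integrator is velocity-Verlet with `dt = 0.01 tau_B`, with the Langevin
friction `-gamma v` and a Gaussian random force entering both half-kicks
-- the splitting used by mainstream MD engines.  The random force is
redrawn at every force evaluation with variance `2 kBT gamma / dt` per
component, the discrete realisation of delta-correlated noise.  A BAOAB
splitting was evaluated as an alternative: its configurational averages
are excellent, but on the stiff FENE+WCA bonds (omega x dt ~ 0.4) it
depresses the kinetic temperature by about 2.5%, outside the package's 2%
equipartition gate, whereas the half-kick scheme stays within a fraction
of a percent while keeping the harmonic bond-length variance within a few
percent of `kBT/(2 Kh)`.  The equipartition, harmonic-variance and
persistence-length tests are the acceptance gates for this choice.

TF switching is attempted every 100 tau_B (10,000 steps): each active TF
switches off with probability `alpha_off * 100` and each inactive one on
with probability `alpha_on * 100`.  Toy-chain runs use
`alpha_on = alpha_off = 1e-5 / tau_B` (half the TFs active at steady
state); whole-chromosome runs use `alpha_on = alpha_off / 4` (20% active).
Initial TF states are drawn from the stationary distribution.

### Simulation volume

Fragment (toy-chain) runs are confined in a spherical container sized by
`toy_confinement()` -- dilute compared with the ~14% of a chromosome
territory, but bounded.  The bound matters: an inactive TF stays inactive
for ~1e5 tau_B on average, and in an unbounded volume the unbound TF pool
would dilute towards zero concentration over a production run,
extinguishing transcription -- inconsistent with the sustained 10-90%
activities this model produces over long runs.  The container size sets
the TF concentration and is the one fragment-protocol parameter with no
published value, so it is calibrated against a published observable that
is independent of the quantities this package reports: the wild-type
activity distribution, which should span roughly 10-90% across TUs and
remain sub-saturating at the top (the sub-saturating regime is what the
whole phenomenology depends on).  A bead volume fraction of 2% reproduces
that range on the reference chain (activities ~0.04-0.95, median ~0.4);
at 5% the most active TUs saturate above 0.95, and at 1% the low tail
collapses to zero.  The default is therefore `volume_fraction = 0.02`,
fixed once and exposed as a parameter.

### Initialisation and warm-up

Initial conformations are self-avoidance-biased random walks (bond length
1.1 sigma, overlap rejection within a 15-bead window), with TFs placed
uniformly in the accessible volume.  Residual overlaps are removed by a
push-off phase in which all non-bonded pairs interact through a bounded
soft-cosine potential whose amplitude ramps from 1 to 100 kBT while
per-step displacements are capped at 0.05 sigma; bonded and bending terms
stay at full strength, so bonds cannot overstretch during push-off.  An
unrecorded equilibration phase with the full potential follows.  FENE
overstretch or non-finite coordinates abort the run with the offending
bead indices; nothing is silently clamped during recorded dynamics.

### Neighbour search

Forces are accumulated from Verlet pair lists built with a cell grid.
Cells are sized for the chromatin-chromatin list; rows for TF spheres
scan a proportionally wider stencil so the attractive 1.8-sigma range is
covered.  The chromatin-chromatin list carries a 0.45-sigma skin and the
TF lists a 0.6-sigma skin; both are rebuilt together when the two largest
displacements since the last build could jointly close the smaller skin
gap.  (The skins are pure performance tuning -- the suite cross-checks
the resulting forces against a brute-force O(N^2) oracle written in R at
tolerance 1e-10.)

### Confinement

Whole-chromosome runs confine all particles in an ellipsoid sized by
`ellipsoid_for_territory()` so the bead volume fraction matches the
territory value (default 14%, prolate 2:1:1 axes; both are configuration
parameters since only the ellipsoidal shape itself is prescribed).  The
wall force is a WCA-like inward push applied along the ray from the
centre, using the radial gap to the surface; it vanishes strictly inside
the shrunken ellipsoid.  This ray-cast gap is exact for a sphere and a
very good approximation for the mild eccentricities used here; the wall
stiffness is capped at a gap of 0.6 sigma to keep the integrator stable.

## Transcription read-out and analytics

Transcription is sampled every 100 tau_B, aligned with switching attempts
(the source protocol states only "regular time intervals"; we fixed the
interval at the switching period so that read-out and TF-state dynamics are
commensurate).  Only *active* TFs within 1.8 sigma count: inactive TFs are
non-binding, and associating transcription with them would score encounters
that the model's own energetics treat as inert.  Per-TU activity is the
mean of the binary series; the high/medium/low labels use the 70% / 20%
thresholds.  Bursts are maximal runs of transcribed samples.

Activity-activity networks use the Pearson correlation across *replicate
runs* (one mean activity per run per TU).  We adopted the run as the
sampling unit because the published edge rules -- |r| > 0.15 at p < 1e-6
with about 1000 runs, and r > 0.12 at p = 7e-4 with 800 runs -- are exactly
reproduced by the Student t-test with n equal to the number of runs
(`corr_pvalue(0.12, 800) = 7e-4`), and are inconsistent with within-run
sample counts.  Constant activity columns give missing correlations and are
excluded from graphs rather than imputed as zero.  Edge thresholds are
always explicit parameters of `build_network()`: at desk scale (tens of
runs) the full-scale thresholds are unreachable by construction, so
scaled-down analyses use correspondingly coarser (r_min, p_max) pairs,
stated wherever they appear.  The desk-scale percolation comparison goes
one step further: with a handful of replicates no run-level correlation
can clear any sensible significance bar, so the suite builds its networks
from the pooled binary transcription samples of all runs (within-run
co-bursting), which separates the sub-saturated and saturated TF regimes
with the same largest-component statistic.

Small-world statistics compare the largest component's clustering
coefficient and mean shortest path against degree-preserving rewirings.
The exact small-world quantification used by the source's supplement is not
public; we use the standard coefficient `s = (C/C_rand)/(L/L_rand)` and
flag it as such.  The degree distribution's decay is summarised by a
maximum-likelihood exponential rate on degrees >= 1 with a KS
goodness-of-fit statistic, since no fit procedure is prescribed.

## Perturbations

Knockouts reclassify one TU as non-binding while keeping its identity for
reporting.  Differential activity between two conditions is a per-TU
two-sample Student t-test (equal variances, two-sided) on per-run
activities, with *no* hidden multiplicity correction: the quoted
significance cut-offs in the source (p = 0.046, p = 0.003) have an
unstated derivation, so the threshold is exposed as a report-time
parameter.  The global "transcriptional difference" is the Euclidean
distance between mean activity vectors; the mutated TU is excluded by
default (its activity drops to ~0 trivially, and excluding it isolates the
trans-effects), with `exclude_index` exposed because the supplementary
formula is unavailable.  QQ plots compare observed -log10 p against
uniform order-statistic quantiles, the minimal reading of a normal-theory
null for activity differences.

Deletions cut a bead range, re-join the backbone with the same bond kind
(the junction is not special-cased), re-index loops and keep genomic
coordinates of the survivors, so the 852-bead cut of the 17,102-bead
chromosome-22 chain leaves 16,250 beads with a visible coordinate gap.

## Whole-chromosome mode

`classify_beads_dhs()` implements the "DHS model": a 3-kbp bin with any
(>= 1 bp) DNase-hypersensitive-site overlap is a TU; otherwise H3K27ac
makes it euchromatin; all else is heterochromatin.  The 1-bp rule is the
least-commitment reading of "has a DHS"; no overlap threshold is given in
the source.  `classify_beads_hmm()` is the "HMM model": majority-overlap
chromatin state per bin, mapped to classes through a user-supplied state
map (the supplement's exact mapping is not public, so it is a required
argument), ties broken toward the lower-coordinate interval.

Simulated activity is compared to experimental signal by Spearman rank
correlation and 5x5 rank-quintile heat maps, optionally after averaging
within contiguous all-TU / all-euchromatin patches.  Contact maps count
bead pairs within 3.5 sigma (a configuration parameter; the capture
criterion of the reference maps is unstated) in 30-kbp bins, optionally
restricted to TU-containing anchors, and `contact_decay_exponent()` fits
the log-log slope of contact probability versus genomic separation
between 30 kbp and 1.5 Mbp.

All genomic interval handling is 0-based half-open at the parser boundary
(BED convention); 1-based inclusive coordinates in prose (e.g. the
chromosome-22 deletion chr22:18,912,231-21,465,672, hg19) are converted at
input.

## Synthetic data

`synthetic_annotation_fixture()` emulates the annotation inputs so the
whole pipeline runs without downloads: open/closed chromatin is a two-state
Markov chain (mean patch length 10 bins, 40% open by default -- values
chosen to give visually realistic clustered tracks at the toy chain's TU
density of 39/1000), DHS intervals sit inside TU bins, H3K27ac inside
euchromatin (and a third of TU bins, exercising the precedence rule), and
the signal track is generated through a Gaussian copula calibrated with
`rho = 2 sin(pi rho_s / 6)` so its Spearman correlation with a supplied
activity vector hits the requested value exactly in expectation.  The
generator reproduces interval clustering and rank correlation; it does not
emulate read-depth noise, mappability artefacts, or inter-chromosomal
context, so passing tests demonstrate the pipeline's correctness, not
concordance with any real cell type.

## Reference fixtures

The source's random TU placement is not published.  The package freezes
one: `toy_reference_fibre()` pins eight TUs at the positions named in the
source's perturbation experiments (33, 396, 404, 886, 905, 907, 930, 931,
with the heterochromatin island spanning beads 901-940 containing exactly
its four embedded TUs) and draws the remaining 31 from a fixed seed.  Any
random placement shows the same qualitative behaviour; pinning the named
anchors lets the documented experiments (knockout of bead 930, loops d and
h) address real TUs.  The loop preset is eight non-overlapping loops of
32-90 beads covering TU-dense stretches.

## Problem sizes

Published protocols are cluster-scale (1000 runs of 1e5 tau_B for the toy
chain; 244 runs of a 35,784-bead chromosome).  The package ships those
protocols as config files, but its tested path is desk-scale: the test
suite uses 1000-bead chains with runs of 500-3000 tau_B production and
4-12 replicates per condition (warm-up: 100 tau_B push-off plus 200-1900
tau_B equilibration; the longer warm-up is used wherever the comparison
needs the matured cluster pattern), and the reproduction script uses 10
replicates of 1e4 tau_B.  These sizes are the smallest at which the emergent effects --
bridging-induced clustering, heterogeneous activity, nearest-neighbour
anticorrelation, competition release -- are statistically unambiguous.

Two desk-scale caveats are worth stating plainly.  First, per-run
activities vary enormously between replicates (the model's own
cell-to-cell variability): with 10 replicates the per-TU mean activity
still carries substantial sampling noise, which attenuates rank
correlations; split-half analyses of the reference ensembles put the
noise-free distance-activity correlation near -0.9 while the 10-run
estimate sits around -0.72 to -0.75.  Second, the cluster pattern of a
run matures over the first few thousand tau_B, so correlations computed
from early samples are weaker than from late ones; the desk-scale
warm-up deliberately trades some of this maturation for runtime, and the
shipped full-scale configs restore the long (1e4 tau_B) equilibration of
the cluster-scale protocol.

## Known limitations

* One TF species and a homogeneous fibre; multiple factors and
  heteromorphic chromatin are out of scope.
* Permanent loops only; no loop extrusion dynamics.
* No hydrodynamics, electrostatics, or explicit RNA kinetics.
* The physical time mapping of the switching rate is reported as a range
  (0.6-6 ms per tau_B), inherited from the scale-dependent nucleoplasm
  viscosity; the package works in tau_B units throughout and does not
  resolve the mapping.
* Desk-scale network analyses are qualitative: with tens of runs the
  full-scale edge-significance thresholds cannot be met, and the
  scaled-down thresholds trade specificity for power.
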