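#' Weeks-Chandler-Anderson (purely repulsive LJ) energy and radial force
#'
#' \eqn{U(r) = 4 k_B T [(\sigma/r)^{12} - (\sigma/r)^6 + 1/4]} for
#' \eqn{r < 2^{1/6}\sigma}, zero beyond.  The radial force is \eqn{-dU/dr}
#' (positive = repulsive).
#'
#' @param r Separation(s), sigma units. Must be positive.
#' @param params An [interaction_params()] object.
#' @return A list with vectors `energy` and `force`.
#' @export
wca_energy_force <- function(r, params = interaction_params()) {
  if (any(r <= 0)) stop("invalid geometry: separation must be positive")
  eps <- params$kBT
  rc <- params$rc_rep
  s6 <- (params$sigma / r)^6
  e <- ifelse(r < rc, 4 * eps * (s6^2 - s6) + eps, 0)
  f <- ifelse(r < rc, 4 * eps * (12 * s6^2 - 6 * s6) / r, 0)
  list(energy = e, force = f)
}

#' FENE bond energy and radial force
#'
#' \eqn{U(r) = -\tfrac12 K_f R_0^2 \ln[1 - (r/R_0)^2]}. Diverges as
#' \eqn{r \to R_0}; a separation at or beyond `R0` is an overstretch and
#' aborts with a diagnostic rather than being clamped.
#'
#' @inheritParams wca_energy_force
#' @export
fene_energy_force <- function(r, params = interaction_params()) {
  if (any(r <= 0)) stop("invalid geometry: separation must be positive")
  if (any(r >= params$R0))
    stop(sprintf("FENE bond overstretched: r = %.4f >= R0 = %.4f",
                 max(r), params$R0))
  frac <- (r / params$R0)^2
  e <- -0.5 * params$Kf * params$R0^2 * log(1 - frac)
  f <- -params$Kf * r / (1 - frac)   # attractive (negative radial force)
  list(energy = e, force = f)
}

#' Harmonic bond energy and radial force
#'
#' \eqn{U(r) = K_h (r - \bar R)^2}, minimum exactly at `Rbar`.
#'
#' @inheritParams wca_energy_force
#' @param Rbar Rest length (1.1 sigma for backbone, 1.8 sigma for loop bonds).
#' @param Kh Spring constant.
#' @export
harmonic_energy_force <- function(r, Rbar, Kh = 100) {
  if (any(r <= 0)) stop("invalid geometry: separation must be positive")
  list(energy = Kh * (r - Rbar)^2, force = -2 * Kh * (r - Rbar))
}

#' Kratky-Porod bending energy and forces for a bead triplet
#'
#' \eqn{U = (k_B T\, \ell_p/\sigma)(1 - \cos\theta)} with \eqn{\theta} the
#' angle between successive tangents; zero when collinear and maximal
#' (\eqn{2 k_B T \ell_p/\sigma}) at a chain reversal.
#'
#' @param r_i,r_j,r_k Positions (length-3 vectors) of three consecutive beads.
#' @param params An [interaction_params()] object.
#' @return A list with `energy` and a 3x3 matrix `forces` (rows: i, j, k).
#' @export
kratky_porod_energy_forces <- function(r_i, r_j, r_k,
                                       params = interaction_params()) {
  a <- r_j - r_i
  b <- r_k - r_j
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12)
    stop("invalid geometry: coincident beads in angle triplet")
  K <- params$kBT * params$lp / params$sigma
  cth <- sum(a * b) / (na * nb)
  ga <- K * (b / (na * nb) - cth * a / na^2)   # K * d(cos)/da
  gb <- K * (a / (na * nb) - cth * b / nb^2)
  f <- rbind(i = -ga, j = ga - gb, k = gb)
  list(energy = K * (1 - cth), forces = f)
}

#' Truncated and shifted Lennard-Jones energy and radial force
#'
#' \eqn{U(d) = 4\epsilon[(\sigma/d)^{12} - (\sigma/d)^6 - (\sigma/r_c)^{12} +
#' (\sigma/r_c)^6]} for \eqn{d < r_c}, zero beyond; the shift makes the
#' potential continuous (exactly zero) at the cutoff.  With
#' \eqn{r_c = 2^{1/6}\sigma} this reduces to the WCA repulsion.
#'
#' @param d TF--bead centre distance(s).
#' @param eps Well depth (kBT units).
#' @param rc Cutoff.
#' @param params An [interaction_params()] object (for sigma).
#' @export
lj_trunc_shifted_energy_force <- function(d, eps, rc,
                                          params = interaction_params()) {
  if (any(d <= 0)) stop("invalid geometry: distance must be positive")
  s6 <- (params$sigma / d)^6
  c6 <- (params$sigma / rc)^6
  e <- ifelse(d < rc, 4 * eps * (s6^2 - s6 - c6^2 + c6), 0)
  f <- ifelse(d < rc, 4 * eps * (12 * s6^2 - 6 * s6) / d, 0)
  list(energy = e, force = f)
}

#' Total forces on every particle of a system state
#'
#' Accumulates all pair, bond, angle and confinement forces with the compiled
#' cell-list engine.  TF-TF pairs repel via WCA; bonded pairs are excluded
#' from the non-bonded sum (FENE bonds carry their own WCA core).
#'
#' @param state A [system_state()] (positions, tf states).
#' @param fibre A [ChromatinFibre][build_toy_fibre()].
#' @param params An [interaction_params()] object.
#' @param conf A [confinement()] spec.
#' @return A list with `forces` (N x 3 matrix) and total potential `energy`.
#' @export
total_forces <- function(state, fibre, params = interaction_params(),
                         conf = confinement("none")) {
  code <- particle_codes(fibre, state$tf_active)
  .total_forces_cpp(state$positions, code,
                    fibre$bonds$i, fibre$bonds$j,
                    bond_kind_code(fibre$bonds$kind),
                    fibre$n_beads, unclass(params), conf)
}

# map bond kind strings to engine codes
bond_kind_code <- function(kind) {
  m <- c(fene = 0L, harmonic_backbone = 1L, harmonic_loop = 2L)
  out <- m[kind]
  if (anyNA(out)) stop("unknown bond kind: ", paste(setdiff(kind, names(m)), collapse = ", "))
  unname(out)
}

# engine particle codes: 0 eu, 1 TU, 2 het, 3 inactive TF, 4 active TF
particle_codes <- function(fibre, tf_active) {
  cls <- c(euchromatin = 0L, TU = 1L, heterochromatin = 2L)[fibre$bead_class]
  if (anyNA(cls)) stop("unknown bead class")
  c(unname(cls), ifelse(tf_active, 4L, 3L))
}
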