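#' Interaction parameters in reduced units
#'
#' All simulations work in reduced Lennard-Jones units: the bead diameter
#' \eqn{\sigma} is the length unit (mapping to 30 nm, i.e. 3 kbp of chromatin),
#' \eqn{k_B T} the energy unit, and bead mass and friction are 1, so the
#' Brownian time \eqn{\tau_B = \sigma^2/D} equals the LJ time and maps to
#' roughly 0.6--6 ms depending on the assumed nucleoplasm viscosity.
#'
#' @param sigma Bead diameter (length unit). Must be 1 in the engine.
#' @param kBT Thermal energy (energy unit).
#' @param eps_strong Well depth for active TF binding a TU bead, in kBT.
#'   Set to 0 for a purely repulsive (non-binding) control.
#' @param eps_weak Well depth for active TF binding a euchromatin bead.
#' @param rc_attr Attractive cutoff for TF--chromatin binding (also the
#'   transcription read-out range).
#' @param Kf FENE spring constant (kBT/sigma^2).
#' @param R0 FENE maximum extension.
#' @param Kh Harmonic spring constant (kBT/sigma^2).
#' @param Rbar_backbone Rest length of harmonic backbone bonds.
#' @param Rbar_loop Rest length of harmonic loop bonds.
#' @param lp Bending parameter of the Kratky-Porod term (sigma units); the
#'   resulting persistence length of the discrete chain is slightly below lp.
#'
#' @return An object of class `interaction_params` (a named list).
#' @export
interaction_params <- function(sigma = 1, kBT = 1, eps_strong = 8,
                               eps_weak = 3, rc_attr = 1.8,
                               Kf = 30, R0 = 1.6, Kh = 100,
                               Rbar_backbone = 1.1, Rbar_loop = 1.8,
                               lp = 3) {
  stopifnot(sigma > 0, kBT > 0, rc_attr > 0, Kf > 0, R0 > sigma,
            Kh > 0, Rbar_backbone > 0, Rbar_loop > 0, lp >= 0,
            eps_strong >= eps_weak || eps_strong == 0, eps_weak >= 0)
  if (sigma != 1)
    stop("the engine works in reduced units with sigma = 1; rescale lengths instead")
  p <- list(sigma = sigma, kBT = kBT, eps_strong = eps_strong,
            eps_weak = eps_weak, rc_attr = rc_attr,
            rc_rep = 2^(1 / 6) * sigma, Kf = Kf, R0 = R0, Kh = Kh,
            Rbar_backbone = Rbar_backbone, Rbar_loop = Rbar_loop, lp = lp)
  class(p) <- "interaction_params"
  p
}

#' Thermostat parameters
#'
#' @param dt Integration time step in Brownian times.
#' @param gamma Friction coefficient (1 in reduced units).
#' @param temperature Thermal energy kBT.
#' @param seed Integer seed for the run's random stream.
#' @return A named list of class `thermostat_params`.
#' @export
thermostat_params <- function(dt = 0.01, gamma = 1, temperature = 1,
                              seed = 1L) {
  stopifnot(dt > 0, gamma >= 0, temperature >= 0)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 seed = as.integer(seed)),
            class = "thermostat_params")
}

#' TF switching parameters
#'
#' TFs attempt to change state every `attempt_interval` Brownian times; an
#' active TF deactivates with probability `alpha_off * attempt_interval` and
#' an inactive one activates with probability `alpha_on * attempt_interval`,
#' so the stationary active fraction is `alpha_on / (alpha_on + alpha_off)`.
#' The default rates give a half-active TF population ("toy" mode); whole
#' chromosome runs use `alpha_on = alpha_off / 4` (20% active).
#'
#' @param alpha_off Switch-off rate per Brownian time.
#' @param alpha_on Switch-on rate per Brownian time.
#' @param attempt_interval Time between switching attempts (Brownian times).
#' @return A named list of class `switching_params`.
#' @export
switching_params <- function(alpha_off = 1e-5, alpha_on = alpha_off,
                             attempt_interval = 100) {
  stopifnot(alpha_off >= 0, alpha_on >= 0, attempt_interval > 0)
  p_off <- alpha_off * attempt_interval
  p_on <- alpha_on * attempt_interval
  if (p_off > 1 || p_on > 1)
    stop("switching probability per attempt exceeds 1; reduce rates or interval")
  structure(list(alpha_off = alpha_off, alpha_on = alpha_on,
                 attempt_interval = attempt_interval,
                 p_off = p_off, p_on = p_on,
                 stationary_active = if (alpha_on + alpha_off > 0)
                   alpha_on / (alpha_on + alpha_off) else NA_real_),
            class = "switching_params")
}

#' Chromosome-mode switching rates (20% of TFs active at steady state)
#' @inheritParams switching_params
#' @export
switching_params_chromosome <- function(alpha_off = 1e-5,
                                        attempt_interval = 100) {
  switching_params(alpha_off = alpha_off, alpha_on = alpha_off / 4,
                   attempt_interval = attempt_interval)
}

#' Interaction rule for a TF--chromatin pair
#'
#' Active TFs bind TU beads strongly and euchromatin weakly (attractive
#' truncated-shifted LJ with cutoff `rc_attr`); heterochromatin never binds,
#' and inactive TFs interact purely repulsively with everything.
#'
#' @param bead_class One of `"TU"`, `"euchromatin"`, `"heterochromatin"`.
#' @param tf_state One of `"active"`, `"inactive"`.
#' @param params An [interaction_params()] object.
#' @return A list with elements `eps` and `rc`.
#' @export
pair_rule <- function(bead_class, tf_state, params = interaction_params()) {
  bead_class <- match.arg(bead_class, c("TU", "euchromatin", "heterochromatin"))
  tf_state <- match.arg(tf_state, c("active", "inactive"))
  if (tf_state == "active" && bead_class == "TU" && params$eps_strong > 0)
    return(list(eps = params$eps_strong, rc = params$rc_attr))
  if (tf_state == "active" && bead_class == "euchromatin" && params$eps_weak > 0)
    return(list(eps = params$eps_weak, rc = params$rc_attr))
  list(eps = params$kBT, rc = params$rc_rep)
}
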