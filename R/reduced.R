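# Closed-form companion models: the two-filament torque ratchet driven by
# ordered crosslinker detachment, the crosslinker-number master equation and
# effective binding energy, rigidity-validity angles, the membrane-work
# estimate, and the coupled two-particle spring toy model.

#' Torque-balanced initial angle of the crosslinker ladder
#'
#' With crosslinkers on every other subunit of a parallel filament pair the
#' i-th binding angle is `theta_i = theta_1 + (i - 1) * 2 pi / 13`; torque
#' balance `sum(theta_i) = 0` fixes `theta_1 = -(n - 1) pi / 13`.
#'
#' @param n number of attached crosslinkers (>= 1).
#' @return `theta_1` in radians.
#' @export
torque_balance_initial_angle <- function(n) {
  stopifnot(n >= 1)
  -(n - 1) * pi / 13
}

#' Angles of the default every-other-subunit crosslinker ladder
#'
#' @param n number of crosslinkers.
#' @param theta1 angle of the first crosslinker; defaults to the
#'   torque-balanced value of [torque_balance_initial_angle()].
#' @return numeric vector of `n` angles (rad).
#' @export
ratchet_angles <- function(n, theta1 = torque_balance_initial_angle(n)) {
  theta1 + (seq_len(n) - 1) * 2 * pi / 13
}

#' Filament rotation sequence under ordered crosslinker detachment
#'
#' Crosslinkers (ordered by distance from the pointed end, angles `theta`)
#' detach one by one from the pointed end. After the i-th detachment the
#' remaining `n - i` torsional springs rebalance, rotating the filament by
#' `dphi_i = (theta_i + sum_{j<i} dphi_j) / (n - i)`. For the default
#' every-other-subunit ladder every increment is `-pi/13`. Sustained
#' directional rotation requires all consecutive angle differences to share
#' one sign and their total to stay below `2 pi`; both predicates are
#' returned.
#'
#' @param theta numeric vector of crosslinker angles (rad), pointed to
#'   barbed order, or a single integer `n >= 2` for the default balanced
#'   ladder of [ratchet_angles()].
#' @return a list: `dphi` (the `n - 1` rotation increments, rad), `theta`,
#'   `directional` (all increments share a sign), `same_sign_steps` and
#'   `total_angle_below_2pi` (the two stated conditions on the angle ladder).
#' @export
detachment_rotation_sequence <- function(theta) {
  if (length(theta) == 1L && theta >= 2 && theta == round(theta)) {
    theta <- ratchet_angles(as.integer(theta))
  }
  n <- length(theta)
  if (n < 2L) stop("need at least 2 crosslinkers")
  dphi <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    dphi[i] <- (theta[i] + sum(dphi[seq_len(i - 1L)])) / (n - i)
  }
  diffs <- diff(theta)
  list(dphi = dphi, theta = theta,
       directional = all(dphi > 0) || all(dphi < 0),
       same_sign_steps = all(diffs > 0) || all(diffs < 0),
       total_angle_below_2pi = sum(abs(diffs)) < 2 * pi)
}

#' Ratchet signal-to-noise ratio
#'
#' Ratio of the torsional energy held by the first crosslinker to the
#' thermal energy, `kappa_tor * theta_1^2 / (2 kBT)`; directed rotation
#' requires this to be much larger than 1.
#'
#' @param kappa_tor torsional stiffness (pN nm / rad).
#' @param theta1 initial angle (rad).
#' @param kBT thermal energy (pN nm).
#' @return dimensionless ratio.
#' @export
ratchet_fluctuation_check <- function(kappa_tor, theta1, kBT) {
  stopifnot(kappa_tor >= 0, kBT > 0)
  0.5 * kappa_tor * theta1^2 / kBT
}

#' Steady-state distribution of the crosslinker number
#'
#' For the birth-death master equation with attachment rate
#' `kf * Phi(n+1|n)` and per-bond slip detachment `n * kb0 * exp(E_n/Ec)`,
#' the steady state is
#' `P(n) = P(0) (kf/kb0)^n Gamma(n) exp(-sum_{i<=n} E_i / Ec)`,
#' where `Gamma(n)` counts the ways of building `n` crosslinkers. Energies
#' `E` and `Ec` must share units (conventionally kBT).
#'
#' @param kf,kb0 attachment/detachment rate constants (1/s).
#' @param Ec critical energy.
#' @param Gamma numeric vector `Gamma(0..n_max)` with `Gamma[1] == 1`.
#' @param E numeric vector `E_1..E_n_max` of per-crosslinker energies at
#'   each occupancy (`E[n]` applies while `n` bonds are present).
#' @return a list: `n` (0..n_max), `P` (normalized steady state), and
#'   `ratio` (`P(n+1)/P(n)`, equal to
#'   `exp(-(E_{n+1} - mu_eff(n))/Ec)` with
#'   `mu_eff` from [effective_binding_energy()]).
#' @export
occupancy_distribution <- function(kf, kb0, Ec, Gamma, E) {
  stopifnot(kf > 0, kb0 > 0, Ec > 0)
  n_max <- length(Gamma) - 1L
  if (length(E) != n_max) stop("E must have length(Gamma) - 1 entries")
  if (abs(Gamma[1] - 1) > 1e-12) stop("Gamma(0) must be 1")
  if (any(Gamma <= 0)) stop("Gamma must be positive")
  n <- 0:n_max
  logw <- n * log(kf / kb0) + log(Gamma) - cumsum(c(0, E)) / Ec
  logw <- logw - max(logw)
  P <- exp(logw) / sum(exp(logw))
  if (!all(is.finite(P))) stop("non-normalizable occupancy weights")
  list(n = n, P = P, ratio = P[-1] / P[-length(P)])
}

#' Effective chemical binding energy of a crosslinker
#'
#' `mu_eff = Ec * (ln(kf/kb0) + ln(Gamma(n+1)/Gamma(n)))`: the chemical
#' drive for adding one crosslinker, including the entropic term from the
#' number of available pairings. With `Gamma(1)/Gamma(0) = N` (one partner
#' subunit in range for each of N subunits) this is `Ec ln(N kf / kb0)`.
#'
#' @param kf,kb0 rate constants (1/s).
#' @param Ec critical energy (units set the output units; use kBT to get
#'   `mu_eff` in kBT).
#' @param Gamma_ratio `Gamma(n+1)/Gamma(n)` (> 0).
#' @return `mu_eff` in the units of `Ec`.
#' @examples
#' effective_binding_energy(kf = 1, kb0 = 10, Ec = 10, Gamma_ratio = 50)
#' # ~16 kBT for the first crosslink between two 50-subunit filaments
#' @export
effective_binding_energy <- function(kf, kb0, Ec, Gamma_ratio) {
  stopifnot(kf > 0, kb0 > 0, Gamma_ratio > 0)
  Ec * (log(kf / kb0) + log(Gamma_ratio))
}

#' Information cost of one ordered detachment sequence
#'
#' Selecting one specific detachment order among the `n!` possible orders of
#' `n` crosslinkers costs at least `kBT ln(n!)`: ~15 kBT for n = 10, a small
#' fraction of the ~1250 kBT released by treadmilling two 50-subunit
#' filaments.
#'
#' @param n number of crosslinkers.
#' @return free-energy cost in kBT.
#' @export
ordered_detachment_information <- function(n) {
  stopifnot(n >= 1)
  lfactorial(n)
}

#' Per-subunit deformation angles of a nearly rigid filament
#'
#' A posteriori check of the rigid-rod assumption for a filament of length
#' `L` and persistence length `Lp` made of `N = round(L/delta)` subunits:
#' the per-subunit angular change due to thermal bending
#' `arccos(exp(-L/Lp))/N`, due to a midpoint force `f` with clamped ends
#' `arctan(f L^2 / (48 Lp kBT))/N`, and due to a torque `T`
#' `(T L / (Lp kBT))/N`, all in degrees.
#'
#' @param L filament length (nm).
#' @param Lp persistence length (nm; ~1e4 for actin).
#' @param f test force (pN).
#' @param torque test torque (pN nm).
#' @param delta subunit rise (nm).
#' @param kBT thermal energy (pN nm).
#' @return `list(N, theta_thermal, theta_bend, theta_twist)` in degrees per
#'   subunit.
#' @examples
#' rigidity_angles(L = 200, Lp = 1e4, f = 10, torque = 100)
#' @export
rigidity_angles <- function(L, Lp, f, torque, delta = 2.7, kBT = 4.1) {
  stopifnot(L > 0, Lp > 0, f >= 0, torque >= 0, delta > 0, kBT > 0)
  N <- round(L / delta)
  deg <- 180 / pi
  list(N = N,
       theta_thermal = acos(exp(-L / Lp)) / N * deg,
       theta_bend = atan(f * L^2 / (48 * Lp * kBT)) / N * deg,
       theta_twist = (torque * L / (Lp * kBT)) / N * deg)
}

#' Work to form a membrane invagination against turgor pressure
#'
#' `W = P pi R^2 D / kBT` for a cylindrical invagination of radius `R` and
#' depth `D` against pressure `P`; ~5.4e4 kBT for the endocytic geometry in
#' yeast (P = 0.8 MPa, R = 25 nm, D = 140 nm).
#'
#' @param P turgor pressure (Pa; converted internally to pN/nm^2).
#' @param R invagination radius (nm).
#' @param D invagination depth (nm).
#' @param kBT thermal energy (pN nm).
#' @return work in kBT.
#' @export
membrane_work <- function(P, R, D, kBT = 4.1) {
  stopifnot(P >= 0, R > 0, D > 0, kBT > 0)
  (P * 1e-6) * pi * R^2 * D / kBT
}

#' Coupled two-particle spring toy model
#'
#' Two particles each held by a spring of stiffness `kappa` anchored at 0.
#' Uncoupled, each position follows the Gaussian Boltzmann density
#' `g(x) = sqrt(kappa / 2 pi kBT) exp(-kappa x^2 / 2 kBT)`. Rigidly coupled
#' by the constraint `x1 - x2 = 2 x0`, particle 1 instead follows
#' `p(x1) = C g(x1) g(x1 - 2 x0)`: a Gaussian displaced to mean `x0` with
#' halved variance `kBT / (2 kappa)` — the 1D analogue of crosslinker
#' frustration shifting strains away from rest.
#'
#' @param kappa spring stiffness (pN/nm).
#' @param x0 half the enforced separation (nm).
#' @param kBT thermal energy (pN nm).
#' @return a list: `coupled` and `uncoupled` (vectorized densities of x1),
#'   `mean` (= `x0`), `var` (= `kBT/(2 kappa)`).
#' @export
coupled_spring_density <- function(kappa, x0, kBT = 4.1) {
  stopifnot(kappa > 0, kBT > 0)
  g <- function(x) sqrt(kappa / (2 * pi * kBT)) * exp(-kappa * x^2 / (2 * kBT))
  v <- kBT / (2 * kappa)
  list(coupled = function(x1) exp(-(x1 - x0)^2 / (2 * v)) / sqrt(2 * pi * v),
       uncoupled = g,
       mean = x0,
       var = v)
}
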