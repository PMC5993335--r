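# Filament friction, crosslinker elasticity, deterministic and stochastic
# forces/torques.
#
# Crosslinker energy: E = 1/2 kappa_ext (l_c - l0)^2
#                       + 1/2 kappa_tor (theta_i^2 + theta_j^2)
# with l_c the distance between the two bound subunit centers and theta_i,
# theta_j the angles between each subunit's binding-surface normal and the
# crosslinker axis pointing away from that subunit.

#' Anisotropic slender-body friction coefficients
#'
#' Translational and rotational drag of a rigid rod of length `L` and
#' diameter `b` in a medium of viscosity `eta`:
#' `xi_par_t  = 2 pi eta L / (ln(L/b) - 0.2)`,
#' `xi_perp_t = 4 pi eta L / (ln(L/b) + 0.84)`,
#' `xi_par_r  = pi eta b^2 L`,
#' `xi_perp_r = pi eta L^3 / (3 (ln(L/b) - 0.66))`.
#'
#' @param L rod length (nm).
#' @param b rod diameter (nm); requires `log(L/b) > 0.66`.
#' @param eta viscosity (pN s / nm^2).
#' @return list with the four scalar coefficients (`xi_par_t`, `xi_perp_t`
#'   in pN s/nm; `xi_par_r`, `xi_perp_r` in pN nm s).
#' @export
friction_coefficients <- function(L, b, eta) {
  if (L <= 0 || b <= 0 || eta <= 0) stop("L, b, eta must be positive")
  lg <- log(L / b)
  if (lg <= 0.66) stop("slender-body friction requires log(L/b) > 0.66")
  list(xi_par_t  = 2 * pi * eta * L / (lg - 0.2),
       xi_perp_t = 4 * pi * eta * L / (lg + 0.84),
       xi_par_r  = pi * eta * b^2 * L,
       xi_perp_r = pi * eta * L^3 / (3 * (lg - 0.66)))
}

#' Friction matrices of a filament
#'
#' Assembles the lab-frame 3 x 3 friction matrices
#' `Xi = xi_par N (x) N + xi_perp (I - N (x) N)` for translation and
#' rotation, with `N` the filament axis. `N` is an eigenvector with
#' eigenvalue `xi_par`; any perpendicular vector has eigenvalue `xi_perp`.
#'
#' @inheritParams friction_coefficients
#' @param N unit orientation 3-vector.
#' @return a `cn_friction` list: the four scalars of
#'   [friction_coefficients()] plus matrices `Xi_t`, `Xi_r` and the axis `N`.
#' @export
friction_set <- function(L, b, eta, N) {
  fr <- friction_coefficients(L, b, eta)
  P <- outer(N, N)
  I3 <- diag(3)
  fr$Xi_t <- fr$xi_par_t * P + fr$xi_perp_t * (I3 - P)
  fr$Xi_r <- fr$xi_par_r * P + fr$xi_perp_r * (I3 - P)
  fr$N <- N
  class(fr) <- "cn_friction"
  fr
}

#' Crosslinker geometry
#'
#' Length, axis and binding angles of one attached crosslinker. The axis
#' points from subunit `i` (on `fil_a`) to subunit `j` (on `fil_b`);
#' `theta_i` is the angle between `O_i` and the axis, `theta_j` between
#' `O_j` and the reversed axis, both in `[0, pi]`.
#'
#' @param state a [cn_state()] object.
#' @param k crosslinker row index in `state$xl`.
#' @return `list(l_c, axis, theta_i, theta_j)`.
#' @export
crosslinker_geometry <- function(state, k) {
  x <- state$xl[k, ]
  p_i <- subunit_position(state, x[["fil_a"]], x[["sub_i"]])
  p_j <- subunit_position(state, x[["fil_b"]], x[["sub_j"]])
  d <- p_j - p_i
  l_c <- sqrt(sum(d^2))
  if (l_c == 0) stop("coincident subunit centers: crosslinker length is zero")
  axis <- d / l_c
  O_i <- subunit_orientation(state, x[["fil_a"]], x[["sub_i"]])
  O_j <- subunit_orientation(state, x[["fil_b"]], x[["sub_j"]])
  list(l_c = l_c, axis = axis,
       theta_i = acos(clamp1(sum(O_i * axis))),
       theta_j = acos(clamp1(-sum(O_j * axis))))
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Crosslinker elastic energy
#'
#' @param l_c crosslinker length (nm).
#' @param theta_i,theta_j binding angles (rad).
#' @param params a [cn_params()] object.
#' @return `list(E_ext, E_tor, E)` in pN nm (vectorized over inputs).
#' @export
crosslinker_energy <- function(l_c, theta_i, theta_j, params) {
  E_ext <- 0.5 * params$kappa_ext * (l_c - params$l0)^2
  E_tor <- 0.5 * params$kappa_tor * (theta_i^2 + theta_j^2)
  list(E_ext = E_ext, E_tor = E_tor, E = E_ext + E_tor)
}

#' Geometry and energy table for all crosslinkers
#'
#' Vectorized evaluation of [crosslinker_geometry()] and
#' [crosslinker_energy()] over the whole crosslinker set; the workhorse for
#' the kinetics sweep and the strain statistics.
#'
#' @param state a [cn_state()] object.
#' @return a data frame with one row per crosslinker: `fil_a`, `sub_i`,
#'   `fil_b`, `sub_j`, `l_c`, `strain` (`(l_c - l0)/l0`), `theta_i`,
#'   `theta_j`, `E_ext`, `E_tor`, `E`.
#' @export
crosslinker_table <- function(state) {
  xl <- state$xl
  p <- state$params
  if (nrow(xl) == 0L) {
    return(data.frame(fil_a = integer(0), sub_i = integer(0),
                      fil_b = integer(0), sub_j = integer(0),
                      l_c = numeric(0), strain = numeric(0),
                      theta_i = numeric(0), theta_j = numeric(0),
                      E_ext = numeric(0), E_tor = numeric(0), E = numeric(0)))
  }
  a <- xl[, "fil_a"]; b <- xl[, "fil_b"]
  i <- xl[, "sub_i"]; j <- xl[, "sub_j"]
  s_i <- (i - (state$n_mon[a] + 1) / 2) * p$delta
  s_j <- (j - (state$n_mon[b] + 1) / 2) * p$delta
  P_i <- state$C[a, , drop = FALSE] + s_i * state$N[a, , drop = FALSE]
  P_j <- state$C[b, , drop = FALSE] + s_j * state$N[b, , drop = FALSE]
  D <- P_j - P_i
  l_c <- sqrt(rowSums(D^2))
  U <- D / l_c
  NMa <- row_cross(state$N, state$M)
  phi_i <- (i - 1) * HELIX_ANGLE
  phi_j <- (j - 1) * HELIX_ANGLE
  O_i <- cos(phi_i) * state$M[a, , drop = FALSE] +
    sin(phi_i) * NMa[a, , drop = FALSE]
  O_j <- cos(phi_j) * state$M[b, , drop = FALSE] +
    sin(phi_j) * NMa[b, , drop = FALSE]
  theta_i <- acos(clamp1(rowSums(O_i * U)))
  theta_j <- acos(clamp1(-rowSums(O_j * U)))
  en <- crosslinker_energy(l_c, theta_i, theta_j, p)
  data.frame(fil_a = a, sub_i = i, fil_b = b, sub_j = j,
             l_c = l_c, strain = (l_c - p$l0) / p$l0,
             theta_i = theta_i, theta_j = theta_j,
             E_ext = en$E_ext, E_tor = en$E_tor, E = en$E)
}

row_cross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

#' Crosslinker force and torque on both filaments
#'
#' Forces are the negative gradient of the crosslinker energy with respect to
#' each filament's center of mass; torques follow from the energy change
#' under virtual infinitesimal rotations of one filament about three
#' orthonormal axes. `method = "analytic"` uses the closed-form gradient
#' (what the simulation engine evaluates); `method = "fd"` implements the
#' virtual-rotation construction literally with central finite differences of
#' step `h` (rad for rotations, nm for displacements).
#'
#' By translation invariance the two forces are exactly opposite.
#'
#' @param state a [cn_state()] object.
#' @param k crosslinker row index.
#' @param method `"analytic"` or `"fd"`.
#' @param h finite-difference step for `method = "fd"`.
#' @return `list(F_a, T_a, F_b, T_b)`: force (pN) and torque (pN nm)
#'   3-vectors on `fil_a` and `fil_b`.
#' @export
crosslinker_force_torque <- function(state, k,
                                     method = c("analytic", "fd"),
                                     h = 1e-6) {
  method <- match.arg(method)
  if (method == "fd") return(xl_ft_fd(state, k, h))
  x <- state$xl[k, ]
  p <- state$params
  a <- x[["fil_a"]]; b <- x[["fil_b"]]
  i <- x[["sub_i"]]; j <- x[["sub_j"]]
  p_i <- subunit_position(state, a, i)
  p_j <- subunit_position(state, b, j)
  O_i <- subunit_orientation(state, a, i)
  O_j <- subunit_orientation(state, b, j)
  d <- p_j - p_i
  l_c <- sqrt(sum(d^2))
  if (l_c == 0) stop("coincident subunit centers: crosslinker length is zero")
  u <- d / l_c
  c_i <- clamp1(sum(O_i * u)); th_i <- acos(c_i)
  c_j <- clamp1(-sum(O_j * u)); th_j <- acos(c_j)
  # dE/dd: extension along u plus the torsional terms through the axis
  dEdd <- p$kappa_ext * (l_c - p$l0) * u -
    p$kappa_tor * sinc_ratio(th_i) * (O_i - c_i * u) / l_c -
    p$kappa_tor * sinc_ratio(th_j) * (-O_j - c_j * u) / l_c
  g_i <- -p$kappa_tor * sinc_ratio(th_i) * u   # dE/dO_i
  g_j <-  p$kappa_tor * sinc_ratio(th_j) * u   # dE/dO_j
  r_i <- p_i - state$C[a, ]
  r_j <- p_j - state$C[b, ]
  list(F_a = dEdd,
       T_a = cross3(r_i, dEdd) - cross3(O_i, g_i),
       F_b = -dEdd,
       T_b = -cross3(r_j, dEdd) - cross3(O_j, g_j))
}

# theta / sin(theta), continuous at 0; zero at the degenerate antipode where
# the gradient direction is undefined (measure-zero configuration)
sinc_ratio <- function(th) {
  s <- sin(th)
  if (th < 1e-8) 1 else if (s < 1e-12) 0 else th / s
}

xl_energy_of <- function(state, k) {
  g <- crosslinker_geometry(state, k)
  crosslinker_energy(g$l_c, g$theta_i, g$theta_j, state$params)$E
}

xl_ft_fd <- function(state, k, h = 1e-6) {
  ft <- list()
  for (side in c("a", "b")) {
    fil <- state$xl[k, if (side == "a") "fil_a" else "fil_b"]
    Fv <- Tv <- numeric(3)
    for (ax in 1:3) {
      e <- numeric(3); e[ax] <- 1
      sp <- sm <- state
      sp$C[fil, ] <- sp$C[fil, ] + h * e
      sm$C[fil, ] <- sm$C[fil, ] - h * e
      Fv[ax] <- -(xl_energy_of(sp, k) - xl_energy_of(sm, k)) / (2 * h)
      sp <- sm <- state
      fp <- rotate_frame(state$N[fil, ], state$M[fil, ], h * e)
      fm <- rotate_frame(state$N[fil, ], state$M[fil, ], -h * e)
      sp$N[fil, ] <- fp$N; sp$M[fil, ] <- fp$M
      sm$N[fil, ] <- fm$N; sm$M[fil, ] <- fm$M
      Tv[ax] <- -(xl_energy_of(sp, k) - xl_energy_of(sm, k)) / (2 * h)
    }
    ft[[paste0("F_", side)]] <- Fv
    ft[[paste0("T_", side)]] <- Tv
  }
  ft[c("F_a", "T_a", "F_b", "T_b")]
}

#' Steric repulsion between two filaments
#'
#' If the minimum axis-to-axis distance is below the filament diameter `b`, a
#' constant force of magnitude `fst` pushes the filaments apart along the
#' line connecting the two nearest points; the force acts at the nearest
#' point of each filament and therefore also exerts a torque about the center
#' of mass (switchable with `torque`). If the axes intersect exactly, the
#' direction falls back to the normalized cross product of the two axes (or a
#' lab axis orthogonalized against the first filament when parallel).
#'
#' @param state a [cn_state()] object.
#' @param a,b filament indices.
#' @param torque apply the induced torque (default `TRUE`).
#' @return `list(F_a, T_a, F_b, T_b)`; all zero when `r_min >= b`.
#' @export
steric_force <- function(state, a, b, torque = TRUE) {
  p <- state$params
  zero <- list(F_a = numeric(3), T_a = numeric(3),
               F_b = numeric(3), T_b = numeric(3))
  sd <- segment_min_distance(state, a, b)
  if (sd$r_min >= p$b) return(zero)
  if (sd$r_min > 1e-12) {
    n <- (sd$p_a - sd$p_b) / sd$r_min
  } else {
    n <- cross3(state$N[a, ], state$N[b, ])
    if (sqrt(sum(n^2)) < 1e-9) {
      ref <- if (abs(state$N[a, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      n <- ref - sum(ref * state$N[a, ]) * state$N[a, ]
    }
    n <- unit(n)
  }
  F_a <- p$fst * n
  out <- list(F_a = F_a, T_a = numeric(3), F_b = -F_a, T_b = numeric(3))
  if (torque) {
    out$T_a <- cross3(sd$p_a - state$C[a, ], F_a)
    out$T_b <- cross3(sd$p_b - state$C[b, ], -F_a)
  }
  out
}

#' Stochastic force and torque draws
#'
#' Discrete-time white-noise kicks satisfying the fluctuation-dissipation
#' relation for an Euler-Maruyama step: per step, the force is Gaussian with
#' covariance `2 kBT Xi_t / dt` (one component along the filament axis with
#' variance `2 kBT xi_par_t / dt`, two perpendicular with
#' `2 kBT xi_perp_t / dt`), and likewise for the torque with `Xi_r`.
#' Draws come from R's RNG.
#'
#' @param fr a [friction_set()] object.
#' @param kBT thermal energy (pN nm); `0` gives zero noise.
#' @param dt time step (s).
#' @param n number of independent draws.
#' @return `list(F = , T = )`, each an `n` x 3 matrix (dropped to vectors
#'   when `n = 1`).
#' @export
stochastic_force_torque <- function(fr, kBT, dt, n = 1) {
  stopifnot(inherits(fr, "cn_friction"), dt > 0)
  if (kBT == 0) {
    Fm <- Tm <- matrix(0, n, 3)
  } else {
    bas <- perp_basis(fr$N)
    draw <- function(xi_par, xi_perp) {
      z <- matrix(rnorm(3 * n), n, 3)
      sqrt(2 * kBT * xi_par / dt) * z[, 1] %o% fr$N +
        sqrt(2 * kBT * xi_perp / dt) *
        (z[, 2] %o% bas$e1 + z[, 3] %o% bas$e2)
    }
    Fm <- draw(fr$xi_par_t, fr$xi_perp_t)
    Tm <- draw(fr$xi_par_r, fr$xi_perp_r)
  }
  if (n == 1L) list(F = drop(Fm), T = drop(Tm)) else list(F = Fm, T = Tm)
}
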