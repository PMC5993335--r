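# Rigid-filament data model and geometric primitives.
#
# A filament is a rigid rod: center of mass C, unit orientation N (pointed ->
# barbed), and a rotational reference vector M = O_1 (the binding-surface
# normal of subunit 1), with N.M = 0. Subunit centers sit on the axis, evenly
# spaced by delta and symmetric about C; subunit normals O_i are M rotated
# about N by (i-1)*14*pi/13 (right-handed), encoding the actin helical pitch.

HELIX_ANGLE <- 14 * pi / 13

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# any orthonormal pair spanning the plane perpendicular to unit vector n
perp_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * n) * n)
  list(e1 = e1, e2 = cross3(n, e1))
}

#' Construct a simulation state
#'
#' A state bundles the parameter set, per-filament rigid-body coordinates,
#' the crosslinker table and the elapsed time. Orthonormality of each
#' filament frame, crosslinker slot uniqueness and the per-filament occupancy
#' cap are validated on construction.
#'
#' @param params a [cn_params()] object.
#' @param C numeric n x 3 matrix of centers of mass (nm).
#' @param N numeric n x 3 matrix of unit orientation vectors.
#' @param M numeric n x 3 matrix of unit rotational reference vectors,
#'   each perpendicular to the matching row of `N`.
#' @param n_mon integer vector of subunit counts (default: `params$N_mon`
#'   for every filament).
#' @param crosslinkers integer matrix with columns `fil_a`, `sub_i`, `fil_b`,
#'   `sub_j` (1-based indices), or `NULL` for none.
#' @param t elapsed simulation time (s).
#' @param rng_state opaque serialized engine RNG state (or `NULL`).
#' @return an object of class `cn_state`.
#' @export
cn_state <- function(params, C, N, M, n_mon = NULL, crosslinkers = NULL,
                     t = 0, rng_state = NULL) {
  stopifnot(inherits(params, "cn_params"))
  C <- unname(as.matrix(C)); N <- unname(as.matrix(N)); M <- unname(as.matrix(M))
  nf <- nrow(C)
  if (nf < 1L) stop("a state needs at least one filament")
  if (!all(dim(N) == c(nf, 3)) || !all(dim(M) == c(nf, 3)) || ncol(C) != 3)
    stop("C, N, M must all be n x 3 matrices")
  if (is.null(n_mon)) n_mon <- rep(params$N_mon, nf)
  n_mon <- as.integer(n_mon)
  if (length(n_mon) != nf || any(n_mon < 2L))
    stop("n_mon must give >= 2 subunits for each filament")
  if (any(abs(rowSums(N^2) - 1) > 1e-8) || any(abs(rowSums(M^2) - 1) > 1e-8))
    stop("rows of N and M must be unit vectors")
  if (any(abs(rowSums(N * M)) > 1e-8))
    stop("each M must be perpendicular to the matching N")
  xl <- normalize_xl(crosslinkers)
  validate_xl(xl, nf, n_mon, params$g_max)
  structure(list(params = params, C = C, N = N, M = M, n_mon = n_mon,
                 xl = xl, t = t, rng_state = rng_state),
            class = "cn_state")
}

normalize_xl <- function(xl) {
  cols <- c("fil_a", "sub_i", "fil_b", "sub_j")
  if (is.null(xl) || NROW(xl) == 0L) {
    m <- matrix(integer(0), ncol = 4, dimnames = list(NULL, cols))
    return(m)
  }
  if (is.data.frame(xl)) xl <- as.matrix(xl[, cols])
  storage.mode(xl) <- "integer"
  colnames(xl) <- cols
  xl
}

validate_xl <- function(xl, nf, n_mon, g_max) {
  if (nrow(xl) == 0L) return(invisible(TRUE))
  if (any(xl[, "fil_a"] < 1L) || any(xl[, "fil_a"] > nf) ||
      any(xl[, "fil_b"] < 1L) || any(xl[, "fil_b"] > nf))
    stop("crosslinker filament index out of range")
  if (any(xl[, "fil_a"] == xl[, "fil_b"]))
    stop("crosslinkers must bridge two different filaments")
  if (any(xl[, "sub_i"] < 1L) || any(xl[, "sub_i"] > n_mon[xl[, "fil_a"]]) ||
      any(xl[, "sub_j"] < 1L) || any(xl[, "sub_j"] > n_mon[xl[, "fil_b"]]))
    stop("crosslinker subunit index out of range")
  slots <- c(paste(xl[, "fil_a"], xl[, "sub_i"]),
             paste(xl[, "fil_b"], xl[, "sub_j"]))
  if (anyDuplicated(slots))
    stop("at most one crosslinker per (filament, subunit) slot")
  occ <- tabulate(c(xl[, "fil_a"], xl[, "fil_b"]), nbins = nf)
  cap <- floor(g_max * n_mon + 1e-9)
  if (any(occ > cap))
    stop("per-filament occupancy exceeds the g_max cap")
  invisible(TRUE)
}

#' @export
print.cn_state <- function(x, ...) {
  cat(sprintf("<cn_state> %d filaments, %d crosslinkers, t = %g s\n",
              nrow(x$C), nrow(x$xl), x$t))
  invisible(x)
}

#' Number of attached crosslinkers in a state
#' @param state a [cn_state()] object.
#' @return integer count.
#' @export
n_attached <- function(state) nrow(state$xl)

#' Subunit center position
#'
#' Subunit centers are evenly spaced by the axial rise `delta` along the
#' filament axis and symmetric about the center of mass; subunit 1 is nearest
#' the pointed end, subunit `n_mon` nearest the barbed end.
#'
#' @param state a [cn_state()] object.
#' @param fil filament index.
#' @param i subunit index (1-based; vectorized).
#' @return a length-3 position (nm), or an `length(i)` x 3 matrix.
#' @export
subunit_position <- function(state, fil, i) {
  nm <- state$n_mon[fil]
  if (any(i < 1L) || any(i > nm)) stop("subunit index out of range")
  s <- (i - (nm + 1) / 2) * state$params$delta
  out <- rep(state$C[fil, ], each = length(i)) +
    outer(s, state$N[fil, ])
  if (length(i) == 1L) drop(out) else out
}

#' Subunit binding-surface normal
#'
#' `O_i` is the rotational reference vector `M` rotated about the filament
#' axis `N` by `(i - 1) * 14 * pi / 13` (right-handed), so `O_1 = M` and
#' same-strand neighbors (`i`, `i + 2`) differ by `2 * pi / 13` (~28 deg).
#'
#' @inheritParams subunit_position
#' @return a unit 3-vector, or an `length(i)` x 3 matrix.
#' @export
subunit_orientation <- function(state, fil, i) {
  nm <- state$n_mon[fil]
  if (any(i < 1L) || any(i > nm)) stop("subunit index out of range")
  phi <- (i - 1) * HELIX_ANGLE
  Nv <- state$N[fil, ]; Mv <- state$M[fil, ]
  NM <- cross3(Nv, Mv)
  out <- outer(cos(phi), Mv) + outer(sin(phi), NM)
  if (length(i) == 1L) drop(out) else out
}

#' Rotate a filament frame by a rotation vector
#'
#' Applies the exact Rodrigues rotation by angle `|omega|` about axis
#' `omega/|omega|` to both frame vectors, then re-orthonormalizes (`N`
#' normalized, `M` Gram-Schmidt-projected against `N`) to prevent numerical
#' drift over long runs.
#'
#' @param N,M unit 3-vectors with `N . M = 0`.
#' @param omega rotation vector (rad); `c(0,0,0)` is the identity.
#' @return `list(N = , M = )` with the rotated orthonormal pair.
#' @export
rotate_frame <- function(N, M, omega) {
  ang <- sqrt(sum(omega^2))
  if (ang > 0) {
    axis <- omega / ang
    N <- rodrigues(N, axis, ang)
    M <- rodrigues(M, axis, ang)
  }
  N <- unit(N)
  M <- unit(M - sum(M * N) * N)
  list(N = N, M = M)
}

rodrigues <- function(v, axis, ang) {
  v * cos(ang) + cross3(axis, v) * sin(ang) +
    axis * sum(axis * v) * (1 - cos(ang))
}

#' Minimum distance between two filament segments
#'
#' Treats each filament as the finite axial segment of length
#' `(n_mon - 1) * delta` (the subunit center-to-center span) centered on `C`,
#' and returns the closest-point pair by the standard clamped
#' segment-segment algorithm.
#'
#' @param state a [cn_state()] object.
#' @param a,b filament indices.
#' @return `list(r_min = , p_a = , p_b = )` with the distance (nm) and the
#'   realizing points on each axis.
#' @export
segment_min_distance <- function(state, a, b) {
  delta <- state$params$delta
  seg_closest(state$C[a, ], state$N[a, ], (state$n_mon[a] - 1) * delta,
              state$C[b, ], state$N[b, ], (state$n_mon[b] - 1) * delta)
}

# closest points of two segments given center, unit direction and length
seg_closest <- function(C1, N1, len1, C2, N2, len2) {
  p1 <- C1 - (len1 / 2) * N1; q1 <- C1 + (len1 / 2) * N1
  p2 <- C2 - (len2 / 2) * N2; q2 <- C2 + (len2 / 2) * N2
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2)
  f <- sum(d2 * r); cc <- sum(d1 * r); bb <- sum(d1 * d2)
  denom <- a * e - bb * bb
  s <- if (denom > 1e-14 * a * e) clamp01((bb * f - cc * e) / denom) else 0
  t <- (bb * s + f) / e
  if (t < 0) {
    t <- 0; s <- clamp01(-cc / a)
  } else if (t > 1) {
    t <- 1; s <- clamp01((bb - cc) / a)
  }
  pa <- p1 + s * d1; pb <- p2 + t * d2
  list(r_min = sqrt(sum((pa - pb)^2)), p_a = pa, p_b = pb)
}

clamp01 <- function(x) min(1, max(0, x))
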