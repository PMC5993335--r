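# Independent oracles, written from scratch (not via package internals) so
# they stay independent of the code paths they validate.

# --- rotation matrix from a rotation vector (for FD oracle rotations) ---
oracle_rotmat <- function(w) {
  th <- sqrt(sum(w^2))
  if (th == 0) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# --- crosslinker energy recomputed from raw state fields ---
oracle_xl_energy <- function(st, k) {
  p <- st$params
  x <- st$xl[k, ]
  fa <- x[["fil_a"]]; fb <- x[["fil_b"]]
  ia <- x[["sub_i"]]; jb <- x[["sub_j"]]
  pos <- function(fil, i)
    st$C[fil, ] + (i - (st$n_mon[fil] + 1) / 2) * p$delta * st$N[fil, ]
  ori <- function(fil, i) {
    phi <- (i - 1) * 14 * pi / 13
    Nv <- st$N[fil, ]; Mv <- st$M[fil, ]
    NM <- c(Nv[2] * Mv[3] - Nv[3] * Mv[2],
            Nv[3] * Mv[1] - Nv[1] * Mv[3],
            Nv[1] * Mv[2] - Nv[2] * Mv[1])
    cos(phi) * Mv + sin(phi) * NM
  }
  d <- pos(fb, jb) - pos(fa, ia)
  lc <- sqrt(sum(d^2))
  u <- d / lc
  thi <- acos(max(-1, min(1, sum(ori(fa, ia) * u))))
  thj <- acos(max(-1, min(1, -sum(ori(fb, jb) * u))))
  0.5 * p$kappa_ext * (lc - p$l0)^2 + 0.5 * p$kappa_tor * (thi^2 + thj^2)
}

# central finite differences of the oracle energy under displacement /
# rotation of one filament
oracle_xl_force_torque <- function(st, k, side = "a", h = 1e-6) {
  fil <- st$xl[k, if (side == "a") "fil_a" else "fil_b"]
  Fv <- Tv <- numeric(3)
  for (ax in 1:3) {
    e <- numeric(3); e[ax] <- 1
    sp <- sm <- st
    sp$C[fil, ] <- sp$C[fil, ] + h * e
    sm$C[fil, ] <- sm$C[fil, ] - h * e
    Fv[ax] <- -(oracle_xl_energy(sp, k) - oracle_xl_energy(sm, k)) / (2 * h)
    Rp <- oracle_rotmat(h * e); Rm <- oracle_rotmat(-h * e)
    sp <- sm <- st
    sp$N[fil, ] <- drop(Rp %*% st$N[fil, ])
    sp$M[fil, ] <- drop(Rp %*% st$M[fil, ])
    sm$N[fil, ] <- drop(Rm %*% st$N[fil, ])
    sm$M[fil, ] <- drop(Rm %*% st$M[fil, ])
    Tv[ax] <- -(oracle_xl_energy(sp, k) - oracle_xl_energy(sm, k)) / (2 * h)
  }
  list(F = Fv, T = Tv)
}

# --- segment-segment minimum distance: coarse grid + box-constrained
#     refinement ---
oracle_seg_dist <- function(C1, N1, l1, C2, N2, l2, n_grid = 201) {
  d2 <- function(par) {
    sum((C1 + par[1] * N1 - C2 - par[2] * N2)^2)
  }
  s <- seq(-l1 / 2, l1 / 2, length.out = n_grid)
  t <- seq(-l2 / 2, l2 / 2, length.out = n_grid)
  d2grid <- 0
  for (cc in 1:3) {
    d2grid <- d2grid + outer(C1[cc] + s * N1[cc], C2[cc] + t * N2[cc], "-")^2
  }
  hit <- which(d2grid == min(d2grid), arr.ind = TRUE)[1, ]
  starts <- rbind(c(s[hit[1]], t[hit[2]]),
                  c(0, 0), c(-l1 / 2, -l2 / 2), c(l1 / 2, l2 / 2),
                  c(-l1 / 2, l2 / 2), c(l1 / 2, -l2 / 2))
  best <- Inf
  for (r in seq_len(nrow(starts))) {
    o <- optim(starts[r, ], d2, method = "L-BFGS-B",
               lower = c(-l1 / 2, -l2 / 2), upper = c(l1 / 2, l2 / 2),
               control = list(factr = 10))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# --- union-find component sizes for the cluster-count oracle ---
oracle_component_sizes <- function(n, edges) {
  parent <- seq_len(n)
  root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (NROW(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- root(edges[r, 1]); b <- root(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  tabulate(vapply(seq_len(n), root, integer(1)), nbins = n)
}

# --- Gillespie simulation of the crosslinker-number birth-death chain ---
oracle_gillespie_occupancy <- function(kf, kb0, Ec, Gamma, E, t_end) {
  n_max <- length(Gamma) - 1L
  up <- function(n) if (n >= n_max) 0 else
    kf * (n + 1) * Gamma[n + 2] / Gamma[n + 1]
  down <- function(n) if (n == 0) 0 else n * kb0 * exp(E[n] / Ec)
  t <- 0; n <- 0L
  occ_time <- numeric(n_max + 1L)
  while (t < t_end) {
    r_up <- up(n); r_down <- down(n)
    rate <- r_up + r_down
    dt <- if (rate > 0) rexp(1, rate) else (t_end - t)
    stay <- min(dt, t_end - t)
    occ_time[n + 1L] <- occ_time[n + 1L] + stay
    t <- t + dt
    if (t >= t_end) break
    n <- if (runif(1) < r_up / rate) n + 1L else n - 1L
  }
  occ_time / sum(occ_time)
}

# --- brute-force torque-balance re-solve for the detachment ratchet ---
# after removing the first i crosslinkers the filament sits at the rotation
# phi_i that re-balances the remaining torsional springs:
# sum_{j>i} (theta_j + phi_i) = 0  =>  phi_i = -mean(theta_{i+1..n})
oracle_ratchet_dphi <- function(theta) {
  n <- length(theta)
  phi <- vapply(seq_len(n - 1L),
                function(i) -mean(theta[(i + 1L):n]), numeric(1))
  diff(c(0, phi))
}

# --- random valid states for property tests ---
rand_frame <- function() {
  N <- rnorm(3); N <- N / sqrt(sum(N^2))
  M <- rnorm(3); M <- M - sum(M * N) * N; M <- M / sqrt(sum(M^2))
  list(N = N, M = M)
}

rand_state <- function(nf = 3, n_xl = 4, params = cn_params(),
                       spread = 40) {
  ctr <- params$box_size / 2
  C <- matrix(ctr + runif(3 * nf, -spread, spread), nf, 3)
  N <- matrix(0, nf, 3); M <- matrix(0, nf, 3)
  for (k in seq_len(nf)) {
    fr <- rand_frame()
    N[k, ] <- fr$N; M[k, ] <- fr$M
  }
  xl <- NULL
  if (n_xl > 0) {
    used <- character(0)
    rows <- list()
    guard <- 0
    while (length(rows) < n_xl && guard < 1000) {
      guard <- guard + 1
      ab <- sort(sample.int(nf, 2))
      i <- sample.int(params$N_mon, 1)
      j <- sample.int(params$N_mon, 1)
      keys <- c(paste(ab[1], i), paste(ab[2], j))
      if (any(keys %in% used)) next
      used <- c(used, keys)
      rows[[length(rows) + 1L]] <- c(ab[1], i, ab[2], j)
    }
    xl <- do.call(rbind, rows)
    colnames(xl) <- c("fil_a", "sub_i", "fil_b", "sub_j")
  }
  cn_state(params, C, N, M, crosslinkers = xl)
}

# frozen bank of independent filament pairs, each joined by one relaxed
# crosslinker (E = 0): the survival-statistics workbench
rest_pair_bank <- function(n_pairs, params) {
  nf <- 2L * n_pairs
  C <- matrix(0, nf, 3)
  N <- matrix(rep(c(1, 0, 0), each = nf), nf, 3)
  M <- matrix(0, nf, 3)
  xl <- matrix(0L, n_pairs, 4,
               dimnames = list(NULL, c("fil_a", "sub_i", "fil_b", "sub_j")))
  for (k in seq_len(n_pairs)) {
    a <- 2L * k - 1L; b <- 2L * k
    C[a, ] <- c(50 * k, 0, 0)
    C[b, ] <- C[a, ] + c(0, params$l0, 0)
    M[a, ] <- c(0, 1, 0)
    M[b, ] <- c(0, -1, 0)
    xl[k, ] <- c(a, 1L, b, 1L)
  }
  cn_state(params, C, N, M, crosslinkers = xl)
}
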