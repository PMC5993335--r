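# Deterministic fixture states and snapshot serialization.

#' Named deterministic fixture states
#'
#' Constructors for small reference configurations used in examples and
#' tests:
#' \describe{
#'   \item{`"two-parallel"`}{two parallel filaments 10 nm apart (the
#'     crosslinker rest length) with crosslinkers on every other subunit,
#'     binding surfaces facing each other at the first subunit — the
#'     geometry of the detachment-ratchet model.}
#'   \item{`"crossed-pair"`}{two perpendicular filaments offset by 10 nm,
#'     joined by one crosslinker between their middle subunits.}
#'   \item{`"bundle-12"`}{12 aligned filaments on a 3 x 4 grid with 10 nm
#'     spacing, each crosslinked to its grid neighbors (a small bundle with
#'     `S_local = 1`).}
#'   \item{`"random-box"`}{the random uncrosslinked initial condition of
#'     [cn_init()].}
#' }
#'
#' @param name fixture name.
#' @param params a [cn_params()] object.
#' @param seed RNG seed (only `"random-box"` consumes randomness).
#' @return a [cn_state()] object.
#' @export
cn_fixture <- function(name = c("two-parallel", "crossed-pair", "bundle-12",
                                "random-box"),
                       params = cn_params(), seed = params$seed) {
  name <- match.arg(name)
  ctr <- rep(params$box_size / 2, 3)
  nm <- params$N_mon
  switch(name,
    "two-parallel" = {
      C <- rbind(ctr + c(0, -5, 0), ctr + c(0, 5, 0))
      N <- rbind(c(1, 0, 0), c(1, 0, 0))
      M <- rbind(c(0, 1, 0), c(0, -1, 0))
      subs <- seq(1L, nm, by = 2L)
      cap <- floor(params$g_max * nm + 1e-9)
      if (length(subs) > cap) subs <- subs[seq_len(cap)]
      xl <- cbind(fil_a = 1L, sub_i = subs, fil_b = 2L, sub_j = subs)
      cn_state(params, C, N, M, crosslinkers = xl)
    },
    "crossed-pair" = {
      C <- rbind(ctr, ctr + c(0, 0, 10))
      N <- rbind(c(1, 0, 0), c(0, 1, 0))
      M <- rbind(c(0, 0, 1), c(0, 0, -1))
      mid <- as.integer(round((nm + 1) / 2))
      xl <- cbind(fil_a = 1L, sub_i = mid, fil_b = 2L, sub_j = mid)
      cn_state(params, C, N, M, crosslinkers = xl)
    },
    "bundle-12" = {
      grid <- expand.grid(y = 0:2, z = 0:3)
      C <- cbind(ctr[1], ctr[2] + 10 * (grid$y - 1), ctr[3] + 10 * (grid$z - 1.5))
      N <- matrix(rep(c(1, 0, 0), each = 12), 12, 3)
      M <- matrix(rep(c(0, 1, 0), each = 12), 12, 3)
      edges <- list()
      idx <- function(y, z) which(grid$y == y & grid$z == z)
      for (y in 0:2) for (z in 0:3) {
        if (y < 2) edges[[length(edges) + 1L]] <- c(idx(y, z), idx(y + 1, z))
        if (z < 3) edges[[length(edges) + 1L]] <- c(idx(y, z), idx(y, z + 1))
      }
      xl <- do.call(rbind, lapply(seq_along(edges), function(e)
        c(edges[[e]][1], e, edges[[e]][2], e)))
      colnames(xl) <- c("fil_a", "sub_i", "fil_b", "sub_j")
      if (max(xl[, c("sub_i", "sub_j")]) > nm)
        stop("bundle-12 needs filaments with at least ", length(edges),
             " subunits")
      cn_state(params, C, N, M, crosslinkers = xl)
    },
    "random-box" = cn_init(params, seed)
  )
}

SNAPSHOT_VERSION <- "1"

#' Write or read a simulation snapshot
#'
#' Snapshots are versioned JSON files carrying the full state: parameters
#' (external units), filament frames, crosslinkers, elapsed time and the
#' engine RNG state, at full floating-point precision. A run resumed from a
#' snapshot continues bit-for-bit like the uninterrupted run.
#'
#' @param state a [cn_state()] object.
#' @param path file path.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns the reconstructed [cn_state()].
#' @export
write_snapshot <- function(state, path) {
  stopifnot(inherits(state, "cn_state"))
  p <- state$params
  obj <- list(
    version = SNAPSHOT_VERSION,
    params = list(L = p$L, b = p$b, delta = p$delta,
                  kappa_ext = p$kappa_ext, kappa_tor = p$kappa_tor,
                  l0 = p$l0, kf = p$kf, kb0 = p$kb0, Ec = p$Ec, rc = p$rc,
                  fst = p$fst, kBT = p$kBT, N_actin = p$N_actin,
                  eta = p$eta_Pas, dt = p$dt, box_size = p$box_size,
                  g_max = p$g_max, seed = p$seed),
    t = state$t,
    n_mon = as.integer(state$n_mon),
    C = unname(split(state$C, row(state$C))),
    N = unname(split(state$N, row(state$N))),
    M = unname(split(state$M, row(state$M))),
    crosslinkers = unname(apply(state$xl, 1, as.integer, simplify = FALSE)),
    rng_state = if (is.null(state$rng_state)) NULL else state$rng_state)
  # digits = I(17): significant (not decimal) digits, enough for an exact
  # IEEE double round-trip, which the resume-equivalence contract needs
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("corrupted or truncated snapshot: ",
                         conditionMessage(e)))
  if (is.null(obj$version) || !identical(as.character(obj$version),
                                         SNAPSHOT_VERSION))
    stop("snapshot version mismatch (expected ", SNAPSHOT_VERSION, ")")
  params <- do.call(cn_params, c(obj$params, list(check_dt = FALSE)))
  as_mat <- function(rows) do.call(rbind, lapply(rows, unlist))
  xl <- if (length(obj$crosslinkers))
    as_mat(obj$crosslinkers) else NULL
  if (!is.null(xl)) colnames(xl) <- c("fil_a", "sub_i", "fil_b", "sub_j")
  cn_state(params, as_mat(obj$C), as_mat(obj$N), as_mat(obj$M),
           n_mon = unlist(obj$n_mon), crosslinkers = xl, t = obj$t,
           rng_state = obj$rng_state)
}
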