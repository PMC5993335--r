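# Time integration. cn_run() drives the compiled engine (fast path, own
# serialized RNG); cn_step() is a pure-R single step over the exported
# mechanics/kinetics functions, kept as a readable reference that is
# cross-checked against the compiled trajectory in the tests.

#' Random initial state
#'
#' Places `floor(N_actin / N_mon)` uncrosslinked filaments (a partial
#' filament is discarded) uniformly in the box with a margin of `L/2` from
#' the walls, orientations uniform on the sphere and rotational reference
#' vectors uniform on the perpendicular circle. Uses R's RNG via
#' `set.seed(seed)`.
#'
#' @param params a [cn_params()] object; requires `box_size > L`.
#' @param seed integer seed (default `params$seed`).
#' @return a [cn_state()] with no crosslinkers at `t = 0`.
#' @export
cn_init <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "cn_params"))
  if (params$box_size <= params$L)
    stop("box_size must exceed the filament length")
  set.seed(seed)
  nf <- as.integer(params$N_actin %/% params$N_mon)
  if (nf < 1L) stop("N_actin is smaller than one filament")
  margin <- params$L / 2
  C <- matrix(runif(3 * nf, margin, params$box_size - margin), nf, 3)
  N <- matrix(rnorm(3 * nf), nf, 3)
  N <- N / sqrt(rowSums(N^2))
  M <- t(vapply(seq_len(nf), function(k) {
    bas <- perp_basis(N[k, ])
    phi <- runif(1, 0, 2 * pi)
    cos(phi) * bas$e1 + sin(phi) * bas$e2
  }, numeric(3)))
  cn_state(params, C, N, M)
}

#' Reflect filament centers into the box
#'
#' Center-of-mass coordinates outside `[0, box]` are mirrored back
#' (`x -> -x` or `x -> 2 box - x`); orientations are unchanged. Coordinates
#' further than one box length outside indicate a runaway trajectory and
#' abort.
#'
#' @param state a [cn_state()] object.
#' @return the reflected state.
#' @export
apply_boundary <- function(state) {
  box <- state$params$box_size
  C <- state$C
  if (any(!is.finite(C)) || any(C < -box) || any(C > 2 * box))
    stop("runaway filament: center of mass beyond one box length outside")
  C[C < 0] <- -C[C < 0]
  C[C > box] <- 2 * box - C[C > box]
  state$C <- C
  state
}

#' Advance the state by one time step (reference implementation)
#'
#' Pure-R version of the engine step: crosslinker and steric forces/torques,
#' optional thermal kicks (R RNG), component-wise mobility solve in the
#' filament frame, Rodrigues update with re-orthonormalization, reflecting
#' walls, then attachment and detachment sweeps. Suitable for small systems
#' and for validating the compiled engine; [cn_run()] is the fast path.
#'
#' @param state a [cn_state()] object.
#' @param dt time step (s; default `params$dt`).
#' @param kinetics run the attachment/detachment sweeps.
#' @param thermal include stochastic forces and torques.
#' @param steric_torque apply the torque induced by steric contact forces.
#' @param mobile logical vector marking filaments free to move (default all).
#' @return the advanced state.
#' @export
cn_step <- function(state, dt = NULL, kinetics = TRUE, thermal = TRUE,
                    steric_torque = TRUE, mobile = NULL) {
  p <- state$params
  if (is.null(dt)) dt <- p$dt
  nf <- nrow(state$C)
  if (is.null(mobile)) mobile <- rep(TRUE, nf)
  Fe <- Te <- matrix(0, nf, 3)
  for (k in seq_len(nrow(state$xl))) {
    ft <- crosslinker_force_torque(state, k)
    a <- state$xl[k, "fil_a"]; b <- state$xl[k, "fil_b"]
    Fe[a, ] <- Fe[a, ] + ft$F_a; Te[a, ] <- Te[a, ] + ft$T_a
    Fe[b, ] <- Fe[b, ] + ft$F_b; Te[b, ] <- Te[b, ] + ft$T_b
  }
  if (nf >= 2L) {
    for (a in seq_len(nf - 1L)) {
      for (b in seq.int(a + 1L, nf)) {
        st <- steric_force(state, a, b, torque = steric_torque)
        Fe[a, ] <- Fe[a, ] + st$F_a; Te[a, ] <- Te[a, ] + st$T_a
        Fe[b, ] <- Fe[b, ] + st$F_b; Te[b, ] <- Te[b, ] + st$T_b
      }
    }
  }
  for (k in seq_len(nf)) {
    if (!mobile[k]) next
    fr <- friction_set(state$n_mon[k] * p$delta, p$b, p$eta, state$N[k, ])
    Fk <- Fe[k, ]; Tk <- Te[k, ]
    if (thermal && p$kBT > 0) {
      s <- stochastic_force_torque(fr, p$kBT, dt)
      Fk <- Fk + s$F; Tk <- Tk + s$T
    }
    Nk <- state$N[k, ]
    Fpar <- sum(Fk * Nk); Tpar <- sum(Tk * Nk)
    V <- Fpar / fr$xi_par_t * Nk + (Fk - Fpar * Nk) / fr$xi_perp_t
    Om <- Tpar / fr$xi_par_r * Nk + (Tk - Tpar * Nk) / fr$xi_perp_r
    state$C[k, ] <- state$C[k, ] + V * dt
    fr2 <- rotate_frame(Nk, state$M[k, ], Om * dt)
    state$N[k, ] <- fr2$N; state$M[k, ] <- fr2$M
  }
  state <- apply_boundary(state)
  if (kinetics) {
    n_old <- nrow(state$xl)
    state <- attempt_attachments(state, dt)$state
    if (n_old > 0L) {
      # only bonds that existed at the start of the step may detach
      tab <- crosslinker_table(state)[seq_len(n_old), , drop = FALSE]
      kb <- breakage_rate(tab$E, p)
      gone <- runif(n_old) < 1 - exp(-kb * dt)
      keep <- c(!gone, rep(TRUE, nrow(state$xl) - n_old))
      state$xl <- state$xl[keep, , drop = FALSE]
    }
  }
  state$t <- state$t + dt
  if (any(!is.finite(state$C))) stop("non-finite filament positions")
  state
}

#' Run a simulation
#'
#' Advances a state (or a fresh random state built from a parameter set) for
#' `duration` seconds using the compiled Brownian-dynamics engine, recording
#' snapshots at a fixed cadence. The engine RNG is seeded from `seed` on a
#' fresh start and restored from `state$rng_state` when resuming, so a run
#' split across snapshots is bit-for-bit identical to an uninterrupted one.
#'
#' @param x a [cn_params()] object (a random initial state is created with
#'   [cn_init()]) or a [cn_state()] to continue from.
#' @param duration simulated time (s).
#' @param seed integer engine seed; default `params$seed`. Ignored when `x`
#'   carries an RNG state to resume from (pass a seed explicitly to restart
#'   the stream).
#' @param observe_every snapshot cadence in simulated seconds (default
#'   0.01 s, the order of the spring relaxation time); `NULL` disables
#'   recording.
#' @param kinetics,thermal,steric_torque engine switches as in [cn_step()].
#' @param mobile logical vector marking filaments free to move.
#' @param enforce_dt refuse to run when `dt > tau/100`
#'   (see [stability_timestep()]); set `FALSE` to override deliberately.
#' @param engine `"cpp"` (default) or `"r"` (loops [cn_step()]; R RNG,
#'   intended for small validation runs).
#' @return `list(state = final cn_state, records = list of snapshots)`; each
#'   snapshot is `list(t, C, N, M, xl)`.
#' @examples
#' p <- cn_params(N_actin = 200, box_size = 400)
#' run <- cn_run(p, duration = 0.02, seed = 7)
#' cn_observables(run$records, p)
#' @export
cn_run <- function(x, duration, seed = NULL, observe_every = 0.01,
                   kinetics = TRUE, thermal = TRUE, steric_torque = TRUE,
                   mobile = NULL, enforce_dt = TRUE,
                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(x, "cn_params")) {
    state <- cn_init(x, seed = if (is.null(seed)) x$seed else seed)
  } else if (inherits(x, "cn_state")) {
    state <- x
  } else {
    stop("x must be a cn_params or cn_state object")
  }
  p <- state$params
  if (duration < 0) stop("duration must be non-negative")
  if (enforce_dt && p$kappa_ext > 0 && p$kappa_tor > 0) {
    tau <- stability_timestep(p)
    if (p$dt > tau / 100)
      stop(sprintf(paste0("dt = %g s exceeds tau/100 = %g s; reduce dt or ",
                          "pass enforce_dt = FALSE"), p$dt, tau / 100))
  }
  n_steps <- as.integer(round(duration / p$dt))
  nf <- nrow(state$C)
  if (is.null(mobile)) mobile <- rep(TRUE, nf)
  record_every <- if (is.null(observe_every)) 0L else
    max(1L, as.integer(round(observe_every / p$dt)))
  if (n_steps == 0L)
    return(list(state = state, records = list()))
  if (engine == "r") {
    records <- list()
    for (s in seq_len(n_steps)) {
      state <- cn_step(state, dt = p$dt, kinetics = kinetics,
                       thermal = thermal, steric_torque = steric_torque,
                       mobile = mobile)
      if (record_every > 0L && s %% record_every == 0L) {
        records[[length(records) + 1L]] <-
          list(t = state$t, C = state$C, N = state$N, M = state$M,
               xl = state$xl)
      }
    }
    return(list(state = state, records = records))
  }
  par_list <- list(delta = p$delta, b = p$b, l0 = p$l0,
                   kappa_ext = p$kappa_ext, kappa_tor = p$kappa_tor,
                   kf = p$kf, kb0 = p$kb0, Ec_abs = p$Ec_abs, rc = p$rc,
                   fst = p$fst, kBT = p$kBT, eta = p$eta,
                   box_size = p$box_size, g_max = p$g_max)
  rng_state <- if (!is.null(state$rng_state) && is.null(seed))
    state$rng_state else ""
  if (is.null(seed)) seed <- p$seed
  t0 <- state$t
  out <- .bd_run_cpp(state$C, state$N, state$M, as.integer(state$n_mon),
                     state$xl, as.integer(mobile), par_list, p$dt, n_steps,
                     record_every, kinetics, thermal, steric_torque,
                     rng_state, as.integer(seed))
  final <- cn_state(p, out$C, out$N, out$M, n_mon = state$n_mon,
                    crosslinkers = out$xl, t = t0 + n_steps * p$dt,
                    rng_state = out$rng_state)
  records <- lapply(out$records, function(r)
    list(t = t0 + r$step * p$dt, C = r$C, N = r$N, M = r$M, xl = r$xl))
  list(state = final, records = records)
}
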