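# Stochastic crosslinker turnover: Poisson attachment trials per filament
# pair and energy-dependent slip-bond detachment. These R implementations use
# R's RNG; the compiled engine used by cn_run() implements the identical
# schedule with its own serialized generator.

#' Slip-bond breakage rate
#'
#' `k_b = kb0 * exp(E / Ec)`: the detachment rate grows exponentially with
#' the elastic energy stored in the crosslinker.
#'
#' @param E elastic energy (pN nm; vectorized).
#' @param params a [cn_params()] object (`Ec_abs` is the critical energy in
#'   pN nm).
#' @return breakage rate(s) in 1/s.
#' @export
breakage_rate <- function(E, params) {
  if (any(E < -1e-12)) stop("elastic energy must be non-negative")
  if (params$Ec_abs == 0) {
    # zero-temperature limit: any strain breaks the bond immediately
    return(ifelse(E > 0, Inf, params$kb0))
  }
  params$kb0 * exp(E / params$Ec_abs)
}

occupancy_slots <- function(state) {
  xl <- state$xl
  list(occ = tabulate(c(xl[, "fil_a"], xl[, "fil_b"]),
                      nbins = nrow(state$C)),
       keys = c(paste(xl[, "fil_a"], xl[, "sub_i"]),
                paste(xl[, "fil_b"], xl[, "sub_j"])))
}

#' Attempt crosslinker attachments for one time step
#'
#' For each unordered filament pair the number of attachment trials is drawn
#' from `Pois(N_mon_a * N_mon_b * kf * dt)`; each trial picks a uniformly
#' random subunit pair, which is crosslinked iff both subunits are
#' unoccupied, their centers are closer than the reaction distance `rc`, and
#' neither filament would exceed its `g_max` occupancy cap. Pairs are
#' processed in fixed index order for reproducibility.
#'
#' @param state a [cn_state()] object.
#' @param dt time step (s).
#' @return `list(state = updated state, events = data.frame)` where `events`
#'   has columns `kind`, `t`, `fil_a`, `sub_i`, `fil_b`, `sub_j`.
#' @export
attempt_attachments <- function(state, dt) {
  p <- state$params
  nf <- nrow(state$C)
  occ <- occupancy_slots(state)
  cap <- floor(p$g_max * state$n_mon + 1e-9)
  new <- list()
  if (nf >= 2L && p$kf > 0) {
    for (a in seq_len(nf - 1L)) {
      for (b in seq.int(a + 1L, nf)) {
        lambda <- state$n_mon[a] * state$n_mon[b] * p$kf * dt
        n_try <- rpois(1L, lambda)
        if (n_try == 0L) next
        for (trial in seq_len(n_try)) {
          i <- sample.int(state$n_mon[a], 1L)
          j <- sample.int(state$n_mon[b], 1L)
          key_i <- paste(a, i); key_j <- paste(b, j)
          if (key_i %in% occ$keys || key_j %in% occ$keys) next
          if (occ$occ[a] + 1L > cap[a] || occ$occ[b] + 1L > cap[b]) next
          d <- subunit_position(state, a, i) - subunit_position(state, b, j)
          if (sqrt(sum(d^2)) >= p$rc) next
          new[[length(new) + 1L]] <- c(a, i, b, j)
          occ$keys <- c(occ$keys, key_i, key_j)
          occ$occ[a] <- occ$occ[a] + 1L
          occ$occ[b] <- occ$occ[b] + 1L
        }
      }
    }
  }
  events <- attach_events(new, state$t)
  if (length(new)) {
    add <- do.call(rbind, new)
    colnames(add) <- c("fil_a", "sub_i", "fil_b", "sub_j")
    storage.mode(add) <- "integer"
    state$xl <- rbind(state$xl, add)
  }
  list(state = state, events = events)
}

attach_events <- function(new, t) {
  if (!length(new)) {
    return(data.frame(kind = character(0), t = numeric(0),
                      fil_a = integer(0), sub_i = integer(0),
                      fil_b = integer(0), sub_j = integer(0)))
  }
  m <- do.call(rbind, new)
  data.frame(kind = "attach", t = t, fil_a = m[, 1], sub_i = m[, 2],
             fil_b = m[, 3], sub_j = m[, 4])
}

#' Attempt crosslinker detachments for one time step
#'
#' Each existing crosslinker's elastic energy is recomputed from the current
#' geometry, its slip-bond rate evaluated via [breakage_rate()], and the bond
#' broken iff a uniform draw satisfies `u < 1 - exp(-k_b * dt)`. All draws
#' are made before any detachment is applied.
#'
#' @inheritParams attempt_attachments
#' @return `list(state = , events = )` as in [attempt_attachments()]; events
#'   additionally carry `E_at_event`.
#' @export
attempt_detachments <- function(state, dt) {
  n_xl <- nrow(state$xl)
  if (n_xl == 0L || state$params$kb0 == 0) {
    return(list(state = state,
                events = data.frame(kind = character(0), t = numeric(0),
                                    fil_a = integer(0), sub_i = integer(0),
                                    fil_b = integer(0), sub_j = integer(0),
                                    E_at_event = numeric(0))))
  }
  tab <- crosslinker_table(state)
  kb <- breakage_rate(tab$E, state$params)
  u <- runif(n_xl)
  gone <- u < 1 - exp(-kb * dt)
  events <- data.frame(kind = rep("detach", sum(gone)), t = state$t,
                       fil_a = tab$fil_a[gone], sub_i = tab$sub_i[gone],
                       fil_b = tab$fil_b[gone], sub_j = tab$sub_j[gone],
                       E_at_event = tab$E[gone])
  state$xl <- state$xl[!gone, , drop = FALSE]
  list(state = state, events = events)
}
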