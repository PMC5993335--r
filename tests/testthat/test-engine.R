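# Time integration: fixed points, gradient descent, R/compiled agreement,
# boundaries, determinism, diffusion and equipartition checks.

test_that("a force-free athermal state is a fixed point", {
  p <- cn_params(kBT = 0, kf = 0)
  ctr <- rep(250, 3)
  st <- cn_state(p, rbind(ctr, ctr + c(0, 50, 0)),
                 rbind(c(1, 0, 0), c(1, 0, 0)),
                 rbind(c(0, 1, 0), c(0, -1, 0)))
  run <- cn_run(st, duration = 100 * p$dt, seed = 1, observe_every = NULL)
  expect_equal(run$state$C, st$C, tolerance = 1e-12)
  expect_equal(run$state$N, st$N, tolerance = 1e-12)
  expect_equal(run$state$M, st$M, tolerance = 1e-12)
})

test_that("athermal relaxation is a monotone gradient flow", {
  # one stretched crosslinker, kinetics frozen: length decays toward rest,
  # energy never increases
  p <- cn_params(kBT = 0, kappa_tor = 0, kappa_ext = 1)
  ctr <- rep(250, 3)
  st <- cn_state(p, rbind(ctr, ctr + c(0, 25, 0)),
                 rbind(c(1, 0, 0), c(1, 0, 0)),
                 rbind(c(0, 1, 0), c(0, -1, 0)),
                 crosslinkers = cbind(fil_a = 1L, sub_i = 25L,
                                      fil_b = 2L, sub_j = 25L))
  run <- cn_run(st, duration = 0.02, seed = 1, observe_every = 5 * p$dt,
                kinetics = FALSE)
  lc <- vapply(run$records, function(r) {
    st_r <- cn_state(p, r$C, r$N, r$M, crosslinkers = r$xl)
    crosslinker_table(st_r)$l_c
  }, numeric(1))
  expect_true(all(diff(lc) < 1e-12))
  expect_lt(abs(lc[length(lc)] - p$l0), 0.5)
})

test_that("the R reference step reproduces the compiled trajectory", {
  p <- cn_params(g_max = 0.5, kBT = 0)
  st <- cn_fixture("two-parallel", p)
  set.seed(51)
  st$C[2, ] <- st$C[2, ] + c(1.5, 4, 2)
  fr <- rotate_frame(st$N[2, ], st$M[2, ], c(0.1, 0.2, -0.15))
  st$N[2, ] <- fr$N; st$M[2, ] <- fr$M
  str <- st
  for (s in 1:40) str <- cn_step(str, kinetics = FALSE, thermal = FALSE)
  run <- cn_run(st, duration = 40 * p$dt, seed = 1, observe_every = NULL,
                kinetics = FALSE, thermal = FALSE)
  expect_equal(run$state$C, str$C, tolerance = 1e-10)
  expect_equal(run$state$N, str$N, tolerance = 1e-10)
  expect_equal(run$state$M, str$M, tolerance = 1e-10)
  # the r engine of cn_run wraps the same step
  run_r <- cn_run(st, duration = 40 * p$dt, observe_every = NULL,
                  kinetics = FALSE, thermal = FALSE, engine = "r")
  expect_equal(run_r$state$C, str$C)
})

test_that("reflecting boundaries mirror and contain", {
  p <- cn_params()
  ctr <- rep(250, 3)
  st <- cn_state(p, rbind(ctr, ctr + c(0, 50, 0)),
                 rbind(c(1, 0, 0), c(1, 0, 0)),
                 rbind(c(0, 1, 0), c(0, -1, 0)))
  expect_equal(apply_boundary(st)$C, st$C)
  st$C[1, 1] <- p$box_size + 3
  expect_equal(apply_boundary(st)$C[1, 1], p$box_size - 3)
  st$C[1, 1] <- -4
  expect_equal(apply_boundary(st)$C[1, 1], 4)
  st$C[1, 1] <- 3 * p$box_size
  expect_error(apply_boundary(st), "runaway")
  # long free thermal run: every recorded center stays inside the box
  p2 <- cn_params(N_actin = 600, box_size = 300, kf = 0, dt = 1e-4,
                  check_dt = FALSE)
  run <- cn_run(p2, duration = 2, seed = 52, observe_every = 0.02,
                enforce_dt = FALSE)
  for (r in run$records) {
    expect_true(all(r$C >= 0 & r$C <= p2$box_size))
  }
})

test_that("runs are reproducible and resumable from the seed", {
  p <- cn_params(N_actin = 500, box_size = 400)
  r1 <- cn_run(p, 0.02, seed = 53)
  r2 <- cn_run(p, 0.02, seed = 53)
  expect_identical(r1$state$C, r2$state$C)
  expect_identical(r1$state$xl, r2$state$xl)
  expect_identical(r1$records, r2$records)
  # zero duration returns the initial state untouched
  r0 <- cn_run(p, 0, seed = 53)
  expect_identical(r0$state$C, cn_init(p, 53)$C)
  expect_length(r0$records, 0)
  # a run continued from its final state matches the uninterrupted run
  full <- cn_run(p, 0.04, seed = 53, observe_every = NULL)
  cont <- cn_run(r1$state, 0.02, observe_every = NULL)
  expect_identical(cont$state$C, full$state$C)
  expect_identical(cont$state$xl, full$state$xl)
})

test_that("run refuses an unstable time step unless overridden", {
  p <- cn_params(dt = 1e-3, check_dt = FALSE, N_actin = 100)
  expect_error(cn_run(p, 0.01, seed = 1), "tau")
  expect_no_error(cn_run(p, 0.01, seed = 1, enforce_dt = FALSE,
                         observe_every = NULL))
})

test_that("a free filament diffuses with the anisotropic coefficients", {
  # many far-apart filaments in a huge box; no crosslinkers
  p <- cn_params(N_actin = 100 * 50, box_size = 5000, kf = 0, dt = 1e-4,
                 check_dt = FALSE)
  st0 <- cn_init(p, seed = 54)
  run <- cn_run(st0, duration = 0.2, seed = 54, observe_every = NULL,
                enforce_dt = FALSE)
  fr <- friction_coefficients(p$L, p$b, p$eta)
  # translational MSD: 2 kBT t (1/xi_par + 2/xi_perp)
  msd <- mean(rowSums((run$state$C - st0$C)^2))
  want_msd <- 2 * p$kBT * 0.2 * (1 / fr$xi_par_t + 2 / fr$xi_perp_t)
  expect_lt(abs(msd - want_msd) / want_msd, 0.25)
  # orientation decorrelation: <N(0).N(t)> = exp(-2 D_r t), D_r = kBT/xi_perp_r
  ct <- mean(rowSums(run$state$N * st0$N))
  want_ct <- exp(-2 * p$kBT / fr$xi_perp_r * 0.2)
  expect_lt(abs(ct - want_ct), 0.05)
})

test_that("a tethered filament equilibrates to the Boltzmann distribution", {
  # mobile filament held by one relaxed crosslinker to a frozen filament:
  # extension samples have variance kBT / kappa_ext and the extensional
  # energy obeys equipartition. Stiff springs keep fluctuations inside the
  # quadratic regime; steric force off so only the spring acts.
  p <- cn_params(kappa_ext = 10, kappa_tor = 1000, kf = 0, kb0 = 0,
                 fst = 0, dt = 1e-6)
  ctr <- rep(250, 3)
  st <- cn_state(p, rbind(ctr, ctr + c(0, 10, 0)),
                 rbind(c(1, 0, 0), c(1, 0, 0)),
                 rbind(c(0, 1, 0), c(0, -1, 0)),
                 crosslinkers = cbind(fil_a = 1L, sub_i = 1L,
                                      fil_b = 2L, sub_j = 1L))
  run <- cn_run(st, duration = 2, seed = 55, observe_every = 1e-3,
                mobile = c(TRUE, FALSE))
  lc <- vapply(run$records, function(r) {
    st_r <- cn_state(p, r$C, r$N, r$M, crosslinkers = r$xl)
    crosslinker_table(st_r)$l_c
  }, numeric(1))
  lc <- lc[-(1:100)]  # discard the equilibration transient
  expect_lt(abs(var(lc) - p$kBT / p$kappa_ext) / (p$kBT / p$kappa_ext),
            0.15)
  mean_E_ext <- mean(0.5 * p$kappa_ext * (lc - p$l0)^2)
  expect_lt(abs(mean_E_ext - 0.5 * p$kBT) / (0.5 * p$kBT), 0.15)
})

test_that("attached crosslinker count plateaus in a scaled-down run", {
  p <- cn_params(N_actin = 1000, box_size = 300, dt = 1e-4,
                 check_dt = FALSE)
  run <- cn_run(p, duration = 3, seed = 56, observe_every = 0.05,
                enforce_dt = FALSE)
  na <- vapply(run$records, function(r) nrow(r$xl), numeric(1))
  late <- na[seq(ceiling(0.75 * length(na)), length(na))]
  expect_gt(mean(late), 0.6 * max(na))
  # late-time drift is small compared with the plateau level
  half1 <- mean(late[seq_len(floor(length(late) / 2))])
  half2 <- mean(late[-seq_len(floor(length(late) / 2))])
  expect_lt(abs(half2 - half1), 0.25 * mean(late))
})
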