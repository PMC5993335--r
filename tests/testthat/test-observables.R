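# Contact graph, clusters, nematic order, strain statistics, phase
# classification.

test_that("the contact graph aggregates crosslinkers into weighted edges", {
  set.seed(61)
  st0 <- rand_state(nf = 5, n_xl = 0)
  g0 <- build_graph(st0)
  expect_equal(igraph::gorder(g0), 5)
  expect_equal(igraph::gsize(g0), 0)
  # three crosslinkers between one pair collapse to a single weight-3 edge
  p <- cn_params()
  ctr <- rep(250, 3)
  st <- cn_state(p, rbind(ctr, ctr + c(0, 10, 0)),
                 rbind(c(1, 0, 0), c(1, 0, 0)),
                 rbind(c(0, 1, 0), c(0, -1, 0)),
                 crosslinkers = cbind(fil_a = 1L, sub_i = c(1L, 5L, 9L),
                                      fil_b = 2L, sub_j = c(1L, 5L, 9L)))
  g <- build_graph(st)
  expect_equal(igraph::gsize(g), 1)
  expect_equal(igraph::E(g)$weight, 3)
  # edge-weight sum always equals the crosslinker count
  for (rep in 1:5) {
    str <- rand_state(nf = 6, n_xl = 8)
    expect_equal(sum(igraph::E(build_graph(str))$weight), nrow(str$xl))
  }
})

test_that("clusters are components with more than 10 filaments", {
  chain_graph <- function(n, extra = 0) {
    st <- rand_state(nf = n + extra, n_xl = 0)
    if (n >= 2) {
      xl <- cbind(fil_a = 1:(n - 1), sub_i = 1L, fil_b = 2:n, sub_j = 2L)
      st$xl <- crossnet:::normalize_xl(xl)
    }
    build_graph(st)
  }
  expect_equal(count_clusters(chain_graph(11)), 1)
  expect_equal(count_clusters(chain_graph(10)), 0)
  expect_equal(count_clusters(build_graph(rand_state(nf = 30, n_xl = 0))), 0)
  # random graphs against a hand-rolled union-find oracle
  set.seed(62)
  for (rep in 1:20) {
    n <- 40
    m <- sample(0:50, 1)
    edges <- cbind(sample.int(n, m, TRUE), sample.int(n, m, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::gorder(g))
    sizes <- oracle_component_sizes(n, edges)
    expect_equal(count_clusters(g), sum(sizes > 10))
  }
})

test_that("nematic order is 1 for aligned sets and ~0 for isotropy", {
  V <- matrix(rep(c(0.6, 0.8, 0), 12), ncol = 3, byrow = TRUE)
  expect_equal(nematic_order(V), 1)
  expect_equal(sum(diag(nematic_tensor(V))), 0, tolerance = 1e-12)
  set.seed(63)
  Viso <- matrix(rnorm(3 * 2e4), ncol = 3)
  Viso <- Viso / sqrt(rowSums(Viso^2))
  expect_lt(nematic_order(Viso), 0.03)
  expect_error(nematic_order(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("nematic order is head-tail and rotation invariant", {
  set.seed(64)
  for (rep in 1:10) {
    V <- matrix(rnorm(15), 5, 3)
    V <- V / sqrt(rowSums(V^2))
    s0 <- nematic_order(V)
    flip <- sample(c(-1, 1), 5, TRUE)
    expect_equal(nematic_order(flip * V), s0, tolerance = 1e-12)
    R <- oracle_rotmat(rnorm(3))
    expect_equal(nematic_order(V %*% t(R)), s0, tolerance = 1e-10)
  }
})

test_that("small random groups have upward-biased order near 0.45", {
  set.seed(65)
  S <- replicate(400, {
    V <- matrix(rnorm(9), 3, 3)
    nematic_order(V / sqrt(rowSums(V^2)))
  })
  h <- hist(S, breaks = seq(-0.025, 1.025, by = 0.05), plot = FALSE)
  expect_lte(abs(h$mids[which.max(h$counts)] - 0.45), 0.0501)
})

test_that("local order averages over filaments with >= 2 neighbors", {
  p <- cn_params()
  st <- cn_fixture("bundle-12", p)
  g <- build_graph(st)
  expect_equal(local_order(st, g), 1)
  expect_equal(global_order(st), 1)
  # a 3-chain: only the middle filament qualifies
  ctr <- rep(250, 3)
  frames <- replicate(3, rand_frame(), simplify = FALSE)
  set.seed(66)
  st3 <- cn_state(p, rbind(ctr, ctr + c(0, 15, 0), ctr + c(0, 30, 0)),
                  t(vapply(frames, `[[`, numeric(3), "N")),
                  t(vapply(frames, `[[`, numeric(3), "M")),
                  crosslinkers = cbind(fil_a = c(1L, 2L),
                                       sub_i = c(1L, 5L),
                                       fil_b = c(2L, 3L),
                                       sub_j = c(2L, 6L)))
  want <- nematic_order(st3$N)   # group of filament 2 = all three
  expect_equal(local_order(st3), want)
  # no qualifying filament: undefined, reported as NA (not zero)
  st2 <- st3
  st2$xl <- st2$xl[1, , drop = FALSE]
  expect_true(is.na(local_order(st2)))
  # two differently oriented bundles: local order exceeds global order
  stA <- cn_fixture("bundle-12", p)
  stB <- cn_fixture("bundle-12", p)
  C2 <- stB$C; C2[, 1] <- C2[, 1] + 150
  N2 <- matrix(rep(c(0, 1, 0), each = 12), 12, 3)
  M2 <- matrix(rep(c(1, 0, 0), each = 12), 12, 3)
  xlB <- stB$xl; xlB[, c(1, 3)] <- xlB[, c(1, 3)] + 12L
  merged <- cn_state(p, rbind(stA$C, C2), rbind(stA$N, N2),
                     rbind(stA$M, M2), crosslinkers = rbind(stA$xl, xlB))
  expect_gt(local_order(merged), global_order(merged))
  expect_equal(local_order(merged), 1)
})

test_that("strain statistics are self-consistent with their definition", {
  p <- cn_params(g_max = 0.5)
  st <- cn_fixture("two-parallel", p)
  ses <- strain_energy_stats(st)
  # rest-length crosslinkers have zero strain on the first rung
  expect_equal(ses$samples$strain[1], 0)
  expect_equal(ses$samples$E_ext[1], 0)
  # definition consistency: mean E_ext = 1/2 kappa_ext l0^2 mean(strain^2)
  set.seed(67)
  str <- rand_state(nf = 4, n_xl = 8)
  s2 <- strain_energy_stats(str)
  expect_equal(s2$mean_E_ext,
               0.5 * str$params$kappa_ext * str$params$l0^2 *
                 mean(s2$samples$strain^2))
})

test_that("Boltzmann reference densities normalize and peak correctly", {
  dens <- boltzmann_strain_density(kappa_ext = 1, l0 = 10, kBT = 4.1)
  expect_equal(integrate(dens, -1, Inf, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
  adens <- boltzmann_angle_density(kappa_tor = 10, kBT = 4.1)
  expect_equal(integrate(adens, 0, pi, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
  # the angle mode solves cot(theta) = kappa_tor * theta / kBT
  mode_opt <- optimize(adens, c(1e-6, pi - 1e-6), maximum = TRUE)$maximum
  mode_root <- uniroot(function(th) cos(th) / sin(th) - 10 * th / 4.1,
                       c(1e-6, pi / 2))$root
  expect_equal(mode_opt, mode_root, tolerance = 1e-4)
})

test_that("phases classify by order and attachment thresholds", {
  expect_equal(classify_phase(0.95, 800), "bundle")
  expect_equal(classify_phase(0.5, 600), "meshwork")
  expect_equal(classify_phase(0.9, 100), "uncrosslinked")
  expect_equal(classify_phase(c(0.95, 0.5, 0.9), c(800, 600, 100)),
               c("bundle", "meshwork", "uncrosslinked"))
  # border cases: S_local must exceed 0.75, N_attach = 300 counts as linked
  expect_equal(classify_phase(0.75, 500), "meshwork")
  expect_equal(classify_phase(0.8, 300), "bundle")
  # threshold rescaling for smaller actin budgets
  expect_equal(scaled_attach_threshold(cn_params(N_actin = 1400)), 60)
})

test_that("observable series line up with the recorded states", {
  p <- cn_params(N_actin = 400, box_size = 300)
  run <- cn_run(p, 0.05, seed = 68, observe_every = 0.01)
  obs <- cn_observables(run$records, p)
  expect_equal(nrow(obs), length(run$records))
  expect_equal(obs$N_attach,
               vapply(run$records, function(r) nrow(r$xl), numeric(1)))
  expect_true(all(is.na(obs$S_local) |
                    (obs$S_local >= 0 & obs$S_local <= 1 + 1e-9)))
  last <- run$records[[length(run$records)]]
  st_last <- cn_state(p, last$C, last$N, last$M, crosslinkers = last$xl)
  expect_equal(obs$S_global[nrow(obs)], global_order(st_last))
})
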