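# Structural metrics: crosslink graph, clusters, Q-tensor nematic order,
# strain/energy statistics with Boltzmann references, phase classification.

#' Crosslink contact graph
#'
#' Undirected graph with one node per filament and an edge between every
#' crosslinked pair, weighted by the number of crosslinkers joining it.
#'
#' @param state a [cn_state()] object.
#' @return an [igraph][igraph::graph_from_data_frame] graph whose vertex
#'   names are the filament indices; edge attribute `weight` counts
#'   crosslinkers.
#' @export
build_graph <- function(state) {
  nf <- nrow(state$C)
  xl <- state$xl
  if (nrow(xl) == 0L) {
    return(igraph::make_empty_graph(n = nf, directed = FALSE))
  }
  lo <- pmin(xl[, "fil_a"], xl[, "fil_b"])
  hi <- pmax(xl[, "fil_a"], xl[, "fil_b"])
  agg <- table(paste(lo, hi))
  parts <- do.call(rbind, strsplit(names(agg), " "))
  edges <- data.frame(from = as.integer(parts[, 1]),
                      to = as.integer(parts[, 2]),
                      weight = as.integer(agg))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = seq_len(nf)))
}

#' Count clusters in the contact graph
#'
#' A connected component is a cluster when it contains strictly more than
#' `min_size` filaments (default 10).
#'
#' @param g a graph from [build_graph()].
#' @param min_size strict lower bound on cluster membership.
#' @return integer number of clusters.
#' @export
count_clusters <- function(g, min_size = 10) {
  comp <- igraph::components(g)
  sum(comp$csize > min_size)
}

#' Q-tensor of a set of orientation vectors
#'
#' `Q = (1/G) sum_a (N_a (x) N_a - I/3)`; symmetric and traceless, invariant
#' under flipping any vector (head-tail symmetry).
#'
#' @param V numeric G x 3 matrix of unit vectors (a single vector is
#'   accepted as length-3).
#' @return a 3 x 3 matrix.
#' @export
nematic_tensor <- function(V) {
  if (is.null(dim(V))) V <- matrix(V, 1, 3)
  if (nrow(V) < 1L) stop("need at least one orientation vector")
  crossprod(V) / nrow(V) - diag(3) / 3
}

#' Nematic order parameter
#'
#' `S = (3/2) * lambda_max(Q)`: 1 for perfectly aligned vectors, ~0 for a
#' large isotropic set. For very small groups the isotropic baseline is
#' biased upward: for 3 random vectors the distribution of S peaks near
#' 0.45.
#'
#' The largest eigenvalue of the Q-tensor itself reaches 2/3 at perfect
#' alignment; the 3/2 factor rescales it to the conventional [0, 1] range.
#'
#' @param V numeric G x 3 matrix of unit orientation vectors.
#' @return S in `[0, 1]` (up to numerical noise).
#' @export
nematic_order <- function(V) {
  Q <- nematic_tensor(V)
  1.5 * max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
}

#' Global nematic order of a state
#' @param state a [cn_state()] object.
#' @return `S_global` over all filament orientations.
#' @export
global_order <- function(state) nematic_order(state$N)

#' Local nematic order of a state
#'
#' For every filament with at least 2 distinct neighbors in the contact
#' graph, the nematic order of the group {filament, its neighbors} is
#' computed; `S_local` is the mean over all qualifying filaments, or `NA` if
#' none qualify.
#'
#' @param state a [cn_state()] object.
#' @param g optional precomputed [build_graph()] result.
#' @return `S_local`, or `NA_real_` when undefined.
#' @export
local_order <- function(state, g = build_graph(state)) {
  nf <- nrow(state$C)
  adj <- igraph::as_adj_list(g, mode = "all")
  vals <- numeric(0)
  for (k in seq_len(nf)) {
    nb <- unique(as.integer(names(adj[[k]])))
    nb <- setdiff(nb, k)
    if (length(nb) < 2L) next
    vals <- c(vals, nematic_order(state$N[c(k, nb), , drop = FALSE]))
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

#' All structural metrics of one state
#'
#' @param state a [cn_state()] object.
#' @return `list(S_global, S_local, N_attach, n_clusters, Q)`.
#' @export
order_result <- function(state) {
  g <- build_graph(state)
  list(S_global = global_order(state),
       S_local = local_order(state, g),
       N_attach = nrow(state$xl),
       n_clusters = count_clusters(g),
       Q = nematic_tensor(state$N))
}

#' Observable time series from run records
#'
#' @param records the `records` element returned by [cn_run()].
#' @param params the [cn_params()] of the run.
#' @return a data frame with columns `t`, `S_local`, `S_global`, `N_attach`,
#'   `n_clusters`, `mean_E_ext`, `mean_E_tor` (energies in pN nm per
#'   crosslinker; `NA` with no crosslinkers).
#' @export
cn_observables <- function(records, params) {
  rows <- lapply(records, function(r) {
    st <- cn_state(params, r$C, r$N, r$M,
                   n_mon = rep(nrow_mon(r, params), nrow(r$C)),
                   crosslinkers = r$xl, t = r$t)
    met <- order_result(st)
    tab <- crosslinker_table(st)
    data.frame(t = r$t, S_local = met$S_local, S_global = met$S_global,
               N_attach = met$N_attach, n_clusters = met$n_clusters,
               mean_E_ext = if (nrow(tab)) mean(tab$E_ext) else NA_real_,
               mean_E_tor = if (nrow(tab)) mean(tab$E_tor) else NA_real_)
  })
  do.call(rbind, rows)
}

nrow_mon <- function(r, params) params$N_mon

#' Crosslinker strain and energy statistics
#'
#' Per-crosslinker extensional strains `(l_c - l0)/l0`, binding angles and
#' elastic energies, their means, and the closed-form Boltzmann reference
#' densities of a free spring for overlay:
#' `P(eps) ~ exp(-kappa_ext l0^2 eps^2 / 2 kBT)` on `(-1, Inf)` and
#' `P(theta) ~ sin(theta) exp(-kappa_tor theta^2 / 2 kBT)` on `(0, pi)`.
#'
#' @param state a [cn_state()] object.
#' @return a list: `samples` (the [crosslinker_table()]), `mean_abs_strain`,
#'   `mean_theta`, `mean_E_ext`, `mean_E_tor` (pN nm), and normalized
#'   density functions `strain_density`, `angle_density`.
#' @export
strain_energy_stats <- function(state) {
  tab <- crosslinker_table(state)
  p <- state$params
  list(samples = tab,
       mean_abs_strain = if (nrow(tab)) mean(abs(tab$strain)) else NA_real_,
       mean_theta = if (nrow(tab))
         mean(c(tab$theta_i, tab$theta_j)) else NA_real_,
       mean_E_ext = if (nrow(tab)) mean(tab$E_ext) else NA_real_,
       mean_E_tor = if (nrow(tab)) mean(tab$E_tor) else NA_real_,
       strain_density = boltzmann_strain_density(p$kappa_ext, p$l0, p$kBT),
       angle_density = boltzmann_angle_density(p$kappa_tor, p$kBT))
}

#' Boltzmann reference density of the extensional strain
#'
#' Free-spring density `C1 exp(-kappa_ext l0^2 eps^2 / (2 kBT))` normalized
#' over `eps` in `(-1, Inf)`.
#'
#' @param kappa_ext extensional stiffness (pN/nm).
#' @param l0 rest length (nm).
#' @param kBT thermal energy (pN nm).
#' @return a vectorized density function of the strain.
#' @export
boltzmann_strain_density <- function(kappa_ext, l0, kBT) {
  stopifnot(kappa_ext > 0, l0 > 0, kBT > 0)
  kern <- function(eps) exp(-kappa_ext * l0^2 * eps^2 / (2 * kBT))
  Z <- integrate(kern, -1, Inf, rel.tol = 1e-10)$value
  function(eps) ifelse(eps > -1, kern(eps) / Z, 0)
}

#' Boltzmann reference density of the binding angle
#'
#' Free torsional spring on the sphere:
#' `C2 sin(theta) exp(-kappa_tor theta^2 / (2 kBT))` normalized over
#' `(0, pi)`.
#'
#' @param kappa_tor torsional stiffness (pN nm / rad).
#' @param kBT thermal energy (pN nm).
#' @return a vectorized density function of the angle (rad).
#' @export
boltzmann_angle_density <- function(kappa_tor, kBT) {
  stopifnot(kappa_tor > 0, kBT > 0)
  kern <- function(th) sin(th) * exp(-kappa_tor * th^2 / (2 * kBT))
  Z <- integrate(kern, 0, pi, rel.tol = 1e-10)$value
  function(th) ifelse(th > 0 & th < pi, kern(th) / Z, 0)
}

#' Classify the network phase
#'
#' Bundle when `S_local > s_threshold` with enough attached crosslinkers;
#' meshwork when crosslinked but locally disordered; uncrosslinked when
#' `N_attach` falls below `n_threshold`. Defaults are the published borders
#' `S_local = 0.75` and `N_attach = 300` (the latter referring to the
#' 7000-subunit budget; see [scaled_attach_threshold()] for smaller
#' systems).
#'
#' @param S_local local nematic order (vectorized).
#' @param N_attach attached crosslinker count (vectorized).
#' @param s_threshold bundle/meshwork border on `S_local`.
#' @param n_threshold crosslinked/uncrosslinked border on `N_attach`.
#' @return character vector: `"bundle"`, `"meshwork"` or `"uncrosslinked"`.
#' @export
classify_phase <- function(S_local, N_attach, s_threshold = 0.75,
                           n_threshold = 300) {
  stopifnot(all(is.finite(N_attach)))
  out <- ifelse(N_attach < n_threshold, "uncrosslinked",
                ifelse(S_local > s_threshold, "bundle", "meshwork"))
  as.character(out)
}

#' Attachment threshold scaled to the actin budget
#'
#' Rescales the published `N_attach = 300` border (defined at a 7000-subunit
#' budget) proportionally to the budget of a smaller system.
#'
#' @param params a [cn_params()] object.
#' @param reference border at the reference budget.
#' @param reference_budget the budget at which `reference` is defined.
#' @return the scaled threshold.
#' @export
scaled_attach_threshold <- function(params, reference = 300,
                                    reference_budget = 7000) {
  reference * params$N_actin / reference_budget
}
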