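---
title: "Brownian dynamics of crosslinked rigid actin filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian dynamics of crosslinked rigid actin filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnet)
```

## The model

`crossnet` simulates the self-organization of short actin filaments
(81–216 nm, as found in endocytic actin patches) bridged by elastic
crosslinking proteins such as fimbrin. At these lengths a filament is about
two orders of magnitude shorter than its ~10 µm persistence length, so it is
treated as a **rigid rod**: its configuration is a center of mass `C`, a unit
axis `N` (pointed → barbed end) and a rotational reference vector `M`
perpendicular to `N`. Subunit centers sit on the axis, spaced by the
δ = 2.7 nm axial rise and symmetric about `C`. Each subunit `i` carries a
binding-surface normal `O_i`, obtained by rotating `M` about `N` by
`(i − 1)·14π/13` — the actin helical pitch. Consecutive subunits (opposite
strands) therefore face nearly opposite directions, while same-strand
neighbors (`i`, `i+2`) differ by `2π/13 ≈ 28°`. The rigidity assumption is
checked a posteriori by `rigidity_angles()`: thermal fluctuations, a 10 pN
midpoint force and a 100 pN·nm torque each bend or twist a 200 nm filament by
only ~0.15–0.38° per subunit.

A **crosslinker** connects one subunit on each of two different filaments and
stores elastic energy in three springs,

$$E \;=\; \tfrac12\,\kappa_\mathrm{ext}\,(l_c - l_0)^2
      \;+\; \tfrac12\,\kappa_\mathrm{tor}\,(\theta_i^2 + \theta_j^2),$$

where `l_c` is the distance between the two bound subunit centers and
`θ_i`, `θ_j` the angles between each binding-surface normal and the
crosslinker axis. There is deliberately no stiffness for rotation *around*
the crosslinker axis: that would impose a preferred relative filament
orientation and pre-decide the bundle/meshwork competition.

Filament motion is overdamped anisotropic Brownian dynamics. Per filament,

$$\Xi^t V_c = F^e + F^s, \qquad \Xi^r \Omega = T^e + T^s,$$

with slender-body friction matrices
`Ξ = ξ_par N⊗N + ξ_perp (I − N⊗N)` built from

$$\xi_\parallel^t = \frac{2\pi\eta L}{\ln(L/b) - 0.2},\quad
  \xi_\perp^t = \frac{4\pi\eta L}{\ln(L/b) + 0.84},\quad
  \xi_\parallel^r = \pi\eta b^2 L,\quad
  \xi_\perp^r = \frac{\pi\eta L^3}{3(\ln(L/b) - 0.66)}.$$

Deterministic forces and torques come from the crosslinker energy gradient
plus a constant steric repulsion `f_st` applied along the line of closest
approach whenever two filament axes come closer than the diameter `b`.
Stochastic kicks obey the fluctuation–dissipation relation; in the
Euler–Maruyama discretization each step draws Gaussian forces with per-step
covariance `2 k_BT Ξ/Δt` (one variance along the axis, another in the
perpendicular plane, for both the translational and rotational channels).

**Crosslinker turnover** is stochastic. Per filament pair and step, the
number of attachment trials is Poisson with mean
`N_mon^α N_mon^β k_f Δt`; each trial picks a uniformly random subunit pair
and succeeds iff both subunits are free, closer than the reaction distance
`r_c`, and neither filament is at its occupancy cap. Detachment is a **slip
bond**: each existing crosslinker breaks with probability
`1 − exp(−k_b Δt)` where `k_b = k_b0 · exp(E/E_c)` uses the elastic energy
recomputed from the current geometry — strained crosslinkers die faster.
This coupling of mechanics into kinetics is what lets the network remodel
toward bundles, and what converts chemical binding energy into stored
elastic energy: crosslinkers bound to a common rigid filament pair are
geometrically frustrated by the helical pitch and fluctuate around strained
configurations, as the 1D `coupled_spring_density()` toy model illustrates.

## One simulation step

`cn_run()` (compiled core) and `cn_step()` (pure-R reference, cross-checked
against the compiled trajectory in the tests) advance the state as:

1. assemble crosslinker and steric forces/torques, draw stochastic kicks,
   solve the mobility relations component-wise in the filament frame (the
   friction matrices invert in closed form), advance `C`, rotate `(N, M)` by
   the exact Rodrigues rotation `Rot(ΩΔt)` followed by Gram–Schmidt
   re-orthonormalization, and reflect centers at the box walls;
2. attachment sweep (filament pairs in fixed index order);
3. detachment sweep over the bonds that existed at the start of the step
   (a bond formed in step 2 cannot die in the same step — it did not exist
   when the sweep's energies are defined).

The step size must satisfy `Δt ≤ τ/100`, where
`τ = min(ξ^t/κ_ext, ξ^r/κ_tor)` over both friction components is the fastest
spring relaxation time (`stability_timestep()`; ~0.015 s for the reference
parameters, so the reference `Δt = 1e−5 s` is comfortably stable).
`cn_run()` refuses a larger step unless `enforce_dt = FALSE` is passed
deliberately.

## Parameters

`cn_params()` carries the full set; defaults are the reference conditions of
the study the package implements:

| symbol | meaning | default | unit |
|---|---|---|---|
| `L` | filament length | 135 (81–216) | nm |
| `b` | filament diameter | 6 | nm |
| `delta` | subunit rise | 2.7 | nm |
| `kappa_ext` | extensional stiffness | 0.1 | pN/nm |
| `kappa_tor` | torsional stiffness | 10 | pN·nm/rad |
| `l0` | crosslinker rest length | 10 | nm |
| `kf` | formation rate per subunit pair | 1 | 1/s |
| `kb0` | strain-free breakage rate | 10 | 1/s |
| `Ec` | slip-bond critical energy | 10 | kBT |
| `rc` | reaction distance | 20 | nm |
| `fst` | steric force | 100 | pN |
| `kBT` | thermal energy | 4.1 | pN·nm |
| `N_actin` | subunit budget | 7000 | — |
| `eta` | viscosity | 10 | Pa·s |
| `dt` | time step | 1e−5 | s |
| `box_size` | box edge | 500 | nm |
| `g_max` | occupancy cap fraction | 0.25 | — |

Internally everything is pN/nm/s; `eta` is converted on input
(1 Pa·s = 1e−6 pN·s/nm²) and `Ec` is given in kBT (`Ec_abs` in pN·nm). The
high reference viscosity is a deliberate computational choice inherited from
the modeled system: it slows diffusion without changing the local metrics,
keeping the relaxation time near 0.01 s.

## Observables

Crosslinked filaments form an undirected **contact graph** (nodes =
filaments, edge weights = crosslinker counts; `build_graph()`). Connected
components with more than 10 filaments count as clusters
(`count_clusters()`). Alignment is measured by the Q-tensor

$$Q = \frac1G \sum_\alpha \left(N^\alpha \otimes N^\alpha - \tfrac13 I\right),$$

whose largest eigenvalue reaches 2/3 at perfect alignment; `nematic_order()`
reports `S = (3/2)·λ_max(Q)` so that S spans [0, 1] — this rescaling is the
only reading under which all the stated properties of S hold at once
(aligned → 1, isotropic → 0, 3-vector peak near 0.45) and it is flagged here
because the unscaled eigenvalue is also in circulation. `S_global` uses all
filaments; `S_local` averages the group {filament + graph neighbors} over
filaments with at least two neighbors and is undefined (`NA`, never 0) when
no filament qualifies. Because local groups are small (~3), the isotropic
baseline of `S_local` is biased up to ~0.4–0.5; a sparsely crosslinked
random network therefore needs the attachment count, not just `S_local`, to
be distinguished from a dense meshwork. `classify_phase()` implements the
published borders: bundle above `S_local = 0.75`, uncrosslinked below
`N_attach = 300` (defined at the 7000-subunit budget;
`scaled_attach_threshold()` rescales it proportionally for smaller boxes),
meshwork between. `strain_energy_stats()` returns per-crosslinker strains,
angles and energies together with the free-spring Boltzmann references
`P(ε) ∝ exp(−κ_ext l_0² ε²/2k_BT)` on (−1, ∞) and
`P(θ) ∝ sin θ · exp(−κ_tor θ²/2k_BT)` on (0, π), against which the
simulated distributions show the stretch-shifted peaks characteristic of
frustration.

## Reduced models

* `detachment_rotation_sequence()`: two parallel filaments crosslinked on
  every other subunit hold angles `θ_i = θ_1 + (i−1)·2π/13`; torque balance
  gives `θ_1 = −(n−1)π/13` and detaching crosslinkers pointed → barbed
  rotates the filament by exactly `−π/13` per detachment
  (`Δφ^{(i)} = (θ_i + Σ_{j<i}Δφ^{(j)})/(n−i)`). Directional rotation for
  arbitrary ladders needs same-sign consecutive angle steps summing below
  2π. `ratchet_fluctuation_check()` gives the stored-energy-to-kBT ratio
  that must exceed 1 (κ_tor ≳ 2 pN·nm/rad at n = 10) for the ratchet to
  beat thermal noise, and `ordered_detachment_information()` the
  `ln n!` information cost of ordering the sequence (~15 kBT for n = 10,
  small against the ~1250 kBT treadmilling budget of a 50-subunit pair).
* `occupancy_distribution()` / `effective_binding_energy()`: the
  crosslinker-number birth–death chain has steady state
  `P(n) ∝ (k_f/k_b0)^n Γ(n) exp(−Σᵢ Eᵢ/E_c)`; the drive for the (n+1)-th
  bond is `μ_eff(n) = E_c[ln(k_f/k_b0) + ln(Γ(n+1)/Γ(n))]` — about 16 kBT
  for the first crosslink at the reference rates with Γ(1) = N = 50, which
  is why ~10 kBT of stored elastic energy per crosslinker is chemically
  affordable.
* `membrane_work()`: deforming the plasma membrane into a 25 nm × 140 nm
  invagination against 0.8 MPa turgor costs ~5.4×10⁴ kBT, the scale against
  which stored crosslinker energy (~10⁴ kBT for ~900 crosslinkers) is
  meaningful.

## Numerical choices

* **Subunit placement**: centers evenly spaced by δ, symmetric about `C`
  (so `C` is their mean and torque bookkeeping about `C` is natural);
  index 1 at the pointed end. Crosslinkers anchor at subunit centers on the
  axis; a radial offset of b/2 would change `l_c` by O(b) but no anchoring
  convention beyond the center is defined by the geometry used here.
* **Rotation sign**: "counter-clockwise" is taken right-handed about `N`;
  only relative angles enter energies.
* **Torques**: defined through virtual infinitesimal rotations;
  `crosslinker_force_torque(method = "fd")` implements that construction
  literally (central differences, h = 1e−6 rad/nm) and the closed-form
  gradient the engine uses (`method = "analytic"`) is validated against it
  and against an independently coded oracle to 1e−5 relative.
* **Steric torque**: the contact force acts at the closest-approach point of
  a rigid body, so the induced torque is applied too (switchable,
  `steric_torque`); with exactly intersecting axes the direction falls back
  to `N_a × N_b`, then to a lab axis orthogonalized against `N_a`.
* **Occupancy cap**: attachment is refused when it would push a filament's
  occupied-subunit count above `floor(g_max · N_mon)` (12 of 50 at the
  reference 25%), which also bounds the global count by
  `floor(N_actin g_max/2)` = 875.
* **Re-orthonormalization** after every rotation prevents frame drift: the
  tests hold `|N| = |M| = 1`, `N·M = 0` to 1e−9 over 1e5 random rotations.
* **RNG**: the compiled engine owns a mt19937_64 stream whose full state
  serializes into snapshots, with cache-free Box–Muller normals and Knuth
  Poisson draws so that no generator-external state exists; a resumed run
  is bit-for-bit identical to an uninterrupted one. R-level helpers
  (`cn_init()`, `attempt_attachments()`, …) use R's RNG under `set.seed()`.
* **Zero temperature** (`kBT = 0`) is supported for gradient-flow checks;
  the slip-bond exponent then degenerates to "any strain breaks the bond".

## What the tests do and do not show

The test suite builds all inputs synthetically: deterministic fixtures
(parallel pairs, a 12-filament bundle, banks of relaxed crosslinkers) and
random boxes from `cn_init()`. Statistical checks run at reduced scale —
chosen for desk-scale reproducibility, stated here as the package's own
problem sizes: fluctuation–dissipation on 1e5 draws, gradient flow over 1e4
athermal steps, survival statistics on 5×10³ crosslinkers, master-equation
versus Gillespie on 6-state chains, and the structural contrast on 20
filaments in a 300 nm box for 5 s (189 nm / κ_ext = 1 bundles with
time-averaged `S_local > 0.75`; 81 nm / κ_ext = 0.1 stays below, each in
≥ 7/10 seeded replicates). These runs reproduce the direction and
thresholds of the published phase behavior at reduced scale; they are not
the full 7000-subunit, 50 s, 10-replicate phase diagrams, and passing them
does not by itself certify quantitative phase boundaries at production
scale. Real endocytic actin additionally involves polymerization,
Arp2/3-mediated branching, capping and membrane coupling, all outside this
model's scope; filament flexibility is neglected by design and justified
only for lengths well under the persistence length.

## Known limitations

* The structural runs at spec conditions use `Δt = 1e−4 s` with
  `enforce_dt = FALSE`; for the stiff long-filament condition this is ~3×
  above the τ/100 rule, acceptable for the qualitative contrast but not for
  production-grade energy statistics.
* `S_global` converges slowly (cluster reorientation is diffusive);
  conclusions should rest on `S_local`, as the observables vignette section
  notes and the published analysis does.
* Catch-bond kinetics, crosslinker diffusion in solution, and finite
  crosslinker pools beyond the occupancy cap are not modeled.
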