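---
title: "Multicanonical dynamic-docking analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicanonical dynamic-docking analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mcdock)
```

# What the package computes

`mcdock` implements the analysis half of multicanonical-MD (McMD) dynamic
docking: given an ensemble of receptor–ligand snapshots sampled under an
energy-flattening bias, it recovers canonical (fixed-temperature) ensembles
by reweighting, builds a two-dimensional free-energy landscape over
distance-pair principal components, ranks candidate binding configurations
by cluster free energy (CFE), constructs a binding/unbinding path along an
estimated reaction coordinate, and estimates a standard binding free energy
by umbrella sampling plus WHAM.

Because μs-scale all-atom simulations are out of reach for a test suite,
the package also ships the *generation* side at desk scale: a
coarse-grained cryptic-site binding system with a Langevin integrator, so
that every stage can be exercised end-to-end against exact quadrature
oracles and long-run occupancy references.

# The toy systems

## `doublewell1d`

A single particle in \(U(x) = a (x^2 - b^2)^2 + c x\) (defaults
\(a = 1, b = 1, c = 0\); kcal/mol, Å). Every canonical expectation has a
deterministic quadrature reference (`quadrature_reference()`, relative
tolerance \(10^{-10}\)), which makes this preset the oracle backbone: the
reweighting identity, the flat-histogram iteration, and WHAM are all
validated against it. With \(c = 0.5\) the wells are asymmetric
(population 0.193 in the upper well at 300 K), so reweighting errors are
visible rather than hidden by symmetry.

## `cryptic3d`

A rigid cage of repulsive beads forms a tubular pocket (back wall, two
lining rings, a mouth ring and a collar); a mobile *gate* bead carrying a
double-well potential sits over the mouth: its lower well seals the pocket
sterically, its upper well clears it (open-state population ≈ 36% at
300 K, a population-shift gate; there is no explicit gate–ligand coupling
term, only sterics). A three-bead harmonic-chain ligand binds inside the
pocket through a smooth Gaussian well (depth 2.6 kcal/mol per bead, width
2.5 Å) centred in the cavity.

Two design points deserve emphasis:

* **The cage is purely repulsive.** An earlier design used pairwise
  Lennard-Jones attraction between ligand and cage beads; because the cage
  is one bead thick, its *outside* was then as attractive as its inside
  (exterior grooves at about −3 kcal/mol), producing non-specific surface
  adsorption that competed with the pocket. Putting the attraction in a
  smooth central well makes the exterior exactly neutral, so binding is a
  clean two-state process through the gated mouth — the statistical
  structure the analysis assumes. The pairwise LJ machinery remains in the
  energy model (and is what the generic `ToySystem` interface exposes).

* **The study conditions are chosen for desk-scale convergence.** Bead
  masses are 0.1 units (≈ 42 amu), the timestep is 5 fs, friction 1/ps,
  and the box 34 × 22 × 22 Å (periodic, minimum-image). At
  well depth 2.6 the bound-minus-unbound energy gap is ≈ 5.6 kcal/mol, the
  unbiased 300 K site occupancy is ≈ 0.4–0.5, and a 25-ns trajectory shows
  on the order of a hundred binding/unbinding events — enough for the
  long-run occupancy oracle to converge. Deeper wells make unbiased
  exchange unobservable (binding becomes irreversible on test timescales);
  shallower ones let the diffuse unbound state outrank the bound basin.
  These values were fixed once, from those physical considerations.

All quadratic terms (bonds, restraints, umbrella) use the biased-MD
convention \(E = k\,\Delta^2\) with **no** 1/2 factor.

# The multicanonical machinery

## Bias representation

Dynamics run at \(T_{sim}\) (= \(T_{high}\) = 700 K) on \(E + B(E)\); the
force is \((1 + dB/dE)\,\mathbf{F}\). The canonical weight of snapshot
\(j\) at temperature \(T\) is

\[ w_j \propto \exp\!\left[\frac{E_j + B(E_j)}{R T_{sim}} -
   \frac{E_j}{R T}\right], \]

which is exact for *any* B as long as the integrator applies exactly the
stored B. Three numerical choices follow from that requirement:

* B is stored as a **piecewise-linear grid** over the energy histogram
  bins. A global polynomial (the more common representation for large
  solvated systems) oscillates badly here: the 1D double well has a sharp
  density-of-states step at its barrier, and the 12-degree-of-freedom toy
  system has few smoothing degrees of freedom. A degree-8 polynomial fit
  of \(\ln n(E)\) is retained as a diagnostic (it drives the effective
  temperature map \(T_{mc}(E)\), clamped to the window for reporting).
* The force scale \(|1 + dB/dE|\) is clamped (default 10) **at bias
  construction**, by clamping grid-segment slopes with residual
  carry-over. The integrator applies the same bound, so the sampled
  ensemble and the reweighting formula never disagree.
* Flat-histogram updates ignore bins with fewer than `min_count` (10)
  samples. The logarithm of a 1–2-count bin is noise of several kcal/mol;
  written into the bias it creates spurious deep traps at the low-energy
  end that later runs cannot leave.

## Iteration protocol and flatness

Following the staged protocol, a 700 K randomization run seeds the initial
estimate (\(\ln n(E) = \ln P(E) + E / R T_{high}\)); iterations of
*increasing length* (factor 1.5 per iteration) then apply the standard
correction \(B' = B + R T_{sim} \ln P_{mc}(E)\). The flatness score is the
coefficient of variation of bin counts over the energy range spanned by
the temperature window — estimated as the reweighted mean energies at
\(T_{low}\) and \(T_{high}\) — with convergence threshold 0.2. Scoring
over the full bias range instead is dominated by the integrable
density-of-states singularities at well bottoms and barriers, which no
smooth bias can flatten and which carry no weight in any canonical
ensemble of the window.

Below the sampled range the bias extrapolates with slope
\(T_{sim}/T_{low} - 1\) (canonical behaviour at the cold end of the
window); above it with slope 0 (canonical at \(T_{sim}\)).

## Honest errors

Reweighted averages use per-trajectory spread (parallel trajectories with
different seeds) rather than the Kish effective sample size alone, because
multicanonical weights are strongly serially correlated.

# Landscape, clustering, ranking

Distance-pair features (all receptor-site × ligand-site distances plus
intra-ligand pairs, minimum image) feed a weighted PCA; by default the
canonical 300 K weights enter the covariance, so the components describe
the canonical ensemble (a flag restores unweighted PCA — the choice only
matters when the raw and reweighted ensembles differ strongly). Retained
components are the smallest leading set over 90% cumulative variance.

The landscape is \(P_i = \sum_{j \in i} w_j\), \(PMF_i = -RT \ln P_i\),
min-normalized, on a 100 × 100 grid with 2% margin; unvisited bins are
reported as missing, never as zero or infinite.

K-means (k′ = min(1000, n/20) at toy scale, fixed seed, Lloyd iterations)
partitions the retained PC space; cluster probabilities are summed
canonical weights and CFE = −RT ln P ranked ascending. Representatives are
the members nearest the weight-weighted cluster centroid (tie: lowest
snapshot id; a max-weight rule is available). Greedy contact grouping
walks the ranking from the most stable cluster, merging clusters whose
representatives share intermolecular contacts (R > 0.7 against the group
seed), then re-ranks by group weight and retains groups within
1.5 kcal/mol.

At bead scale the contact cutoff is 5.5 Å (stored in the system
parameters): lining beads have 2.8 Å radii, so bound-state contacts sit at
3.4–4.4 Å and the atom-scale default of 4.5 Å would leave the native
R-value fluctuating around 0.4 at 300 K (at 5.5 Å: ≈ 0.77 bound vs ≈ 0.01
unbound). Functions keep 4.5 Å as their default for atom-resolution input.

## Refinement

Representatives are refined by ten independent canonical runs at 300 K
(5 ns each at toy scale) and the refined structure \(q\) is the
nearest-to-average snapshot over the final 40% of the pooled replicas;
400 K replicas quantify relative stability (mean ± SD of the R-value to
the reference pose). The refinement stage is load-bearing: raw McMD
representatives at bead scale sit within one contact shell of the pose but
need canonical relaxation to settle into the minimum. At 300 K the bound
basin is thermally wide — ligand-site RMSD to the minimized reference has
median ≈ 2.3 Å and 90th percentile ≈ 3.4 Å, and the palindromic three-bead
ligand binds in two equivalent orientations — so pose-recovery checks use
the basin-derived thresholds RMSD ≤ 3.5 Å and R(native) ≥ 0.5 (unbound
baseline ≈ 0.01).

# Path construction and umbrella sampling

The unbinding direction minimizes integrated steric obstruction over a
1000-point spherical Fibonacci grid (Gaussian overlap kernel, 12 Å sweep);
ties break to the smallest polar angle. λ is the ligand-COM displacement
along that direction from the refined pose.

Windows of 0.5 Å walk outward from the bound window (which carries \(q\)
itself) — both toward the bulk and, optionally, to negative λ deeper in
the pocket, since the thermal basin extends inward of the minimized pose.
Candidates must resemble the previous window's picks: R-value above an
adaptive cutoff (0.7, relaxing by 0.05 to a floor of 0.3 until ≥ 30
candidates), switching to RMSD_L (translation along λ removed; adaptive
cutoff 2 → 8 Å by 0.5) once the mean intermolecular contact count of a
window drops below 3. Per window, K-means (k = 3) in PC space picks the
highest-weight member of each cluster. Window diagnostics (metric, cutoff
used, candidate count, gap flags) are part of the output: windows adjacent
to the gate report fewer candidates or laxer cutoffs — the narrow-pathway
signature of a population-shift gate.

Umbrella sampling re-runs each window under a harmonic umbrella
(\(k_w = RT/w^2\), matching fluctuations to the spacing) and a flat-bottom
cylinder (radius 8 Å, k = 0.1 kcal/mol/Å²) about the axis, with the staged
protocol: restrained equilibration at 400 K, hot US, linear anneal to
300 K, then production (400 ps per window at toy scale, λ recorded every
50 fs). WHAM solves the self-consistent equations to \(10^{-8}\) on
0.05-Å bins; errors are block bootstraps (blocks of 10 integrated
autocorrelation times). ΔG is the mean PMF over the final 50 bins (2.5 Å),
σ its SD, ε the mean bootstrap error there; the production default
discards the first 60% of each window.

## Standard-state correction

The default (`cylinder_pmf`) variant is exact within the cylinder scheme:

\[ \Delta G_b^0 = -RT\,\ln\!\left[\frac{A_u}{V_0}
   \int_{site} e^{-(W(\lambda) - \Delta G)/RT}\, d\lambda\right]
   - \Delta G, \qquad V_0 = 1660\ \text{Å}^3, \]

where \(A_u\) is the effective cylinder cross-section (flat disc plus the
Boltzmann tail of the quadratic wall, computed by quadrature) and the
integral runs over the binding-site range of λ. A `volume_ratio` variant
(\(-\Delta G + RT \ln(V_{eff,u}/V_0) + RT \ln(V_0/V_{eff,b})\), effective
volumes from COM sample covariances) is available for comparison; the
correction is validated against an independent long-run occupancy
reference (`direct_binding_reference()`:
\(-RT \ln[(N_{site}/N_{out}) \cdot V_{out}/V_0]\)), not against any
external number.

# Problem sizes and determinism

The packaged end-to-end run uses: 8 flattening iterations (60k steps
growing ×1.5, 4 trajectories), production 16 × 1.5M steps (7.5 ns each,
saved every 1 ps, first 20% discarded), k′ = 1000 clusters, 10 × 5 ns
refinement replicas, and ~32 umbrella windows of 2.3 ns each (0.2 ns hot,
2 ns production of which the first 60% is discarded). That is roughly
2 × 10⁸ force evaluations, a few minutes of single-core time. The
independent occupancy reference adds 8 × 25 ns unbiased runs with
alternating bound/unbound starts (cancelling first-order relaxation
bias). All randomness flows from explicit integer seeds
(trajectory i uses base + i); the integrator's RNG is a fully specified
mt19937-64 + Box–Muller chain, so identical seeds give bitwise-identical
trajectories.

# What the toy validation does and does not show

Passing the packaged checks demonstrates that the estimators are correct
and internally consistent: reweighting reproduces quadrature, WHAM
reproduces the known PMF, the pipeline recovers the planted bound pose and
its binding free energy within the stated tolerances on a system whose
ground truth is known. It does not demonstrate force-field accuracy,
convergence at all-atom dimensionality, or the million-fold longer
timescales of the real application — the toy system has a 12-dimensional
configuration space and was deliberately tuned so that desk-scale sampling
converges. Known limitations worth keeping in mind on real data:

* Reweighting across a 280–700 K window is exact only if the flattened
  range covers the energies relevant at the target temperature; the
  low-energy frontier converges slowly (it is the rare-event part of the
  walk), and under-converged biases *underweight* deeply bound states.
* The greedy R-value grouping and the representative rule are
  tie-break-sensitive at the margins; grouping granularity should not be
  over-interpreted.
* The naive direction estimate is geometric; for tortuous exit channels a
  straight λ is a poor coordinate, and the cylinder correction assumes the
  site is contained in the cylinder.
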