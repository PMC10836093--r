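---
title: "Methods: ensemble, kinetic and cross-link analysis in tauens"
author: "tauens authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble, kinetic and cross-link analysis in tauens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauens)
```

## Scope and model

`tauens` analyses conformational ensembles of short aggregation-regulating
peptides — the motivating system is the tau inter-repeat fragment spanning a
`PGGG`/`SGGG` turn and the VQIVYK amyloid motif — through three lenses:
static geometry (distances, clusters, hairpin register), kinetics (a Markov
state model with transition path theory), and experimental observables (Hα
shift propensities, NOE effective distances, cross-link statistics). Every
stage can be validated against synthetic inputs with known ground truth,
which this vignette describes alongside the numerical choices that an
analyst would want to audit.

## Ensemble container and geometry

A `ConformerEnsemble` stores frames of one atom table; coordinates are
Angstrom throughout, with nanometre values accepted only at interface
boundaries (`cutoff_unit = "nm"`) and converted immediately. This single
internal unit avoids the silent nm/Å mix-ups that arise when tooling
conventions disagree.

`min_distance_map()` reports, per residue pair, the mean over frames of the
minimum atom–atom distance — the quantity behind the familiar compaction
heatmaps. `group_com_distance()` uses unweighted selection centroids by
default; a mass-weighted option exists because backbone centre-of-mass is
the stricter reading, but for the Cα-only fixtures the two are identical.

RMSD uses Kabsch superposition (SVD of the 3×3 cross-covariance with a
determinant sign correction), fitting and measuring on the same selection —
the behaviour of the standard trajectory tools. The test suite cross-checks
it against two independent routes: a quaternion (Horn) superposition oracle
and `bio3d::rmsd(fit = TRUE)`.

`gromos_cluster()` implements the greedy neighbour-count rule: the frame
with the most neighbours within the RMSD cutoff becomes a centre, its
neighbourhood is removed, and the procedure repeats. Ties in neighbour count
are broken by lowest frame index so output is deterministic; clusters are
reported in decreasing size. Typical cutoffs are 5.4 Å for broad state
discovery and 4 Å for tighter partitions of better-sampled ensembles.

### The turn-register statistic

The register of a β-hairpin is summarized per frame by
ρ = d(Cα₄, Cα₁₂)/d(Cα₇, Cα₁₂) over three role residues (remappable onto any
absolute numbering). Classification uses the fixed thresholds: left-shifted
below 0.75, right-shifted above 1, centered otherwise. ρ is a distance
ratio, hence invariant under rigid motions and uniform scaling — both are
asserted as properties in the tests. We deliberately do not assert ρ ≈ 1 for
a rigid, idealized centered hairpin: that regime reflects floppier sampled
turns, and the idealized geometry only guarantees the ordering of the three
role distances, not the centered value. Frames with a degenerate (zero)
denominator are excluded from summaries and counted.

## Synthetic generators: what they emulate

`make_hairpin_ensemble()` builds two antiparallel straight strands joined by
a symmetric two-residue turn. The cross-strand register follows the pairing
rule *i* ↔ 2·apex + 1 − *i* at distance `strand_sep` (default 4.8 Å, the
canonical cross-strand Cα separation), and every consecutive virtual bond is
exactly `rise` = 3.8 Å. Those two requirements conflict at the turn itself
whenever `strand_sep` ≠ 3.8 Å, so the two turn residues (apex, apex + 1) dip
symmetrically below the strands with all three bridging bonds at 3.8 Å; the
pairing invariant then holds exactly for all strand pairs. A left-registered
hairpin (residue 12 paired toward residue 4) requires a half-integer apex
under the pairing rule; the generator therefore uses apex = 7, the nearest
integer apex on the left-shifted side, which yields ρ ≈ 0.39 — robustly
inside the left classification band.

`make_extended_ensemble()` is a collinear 3.8 Å chain. Isotropic Gaussian
coordinate noise (default 0) stands in for thermal breathing; 0.5–1 Å gives
well-separated yet non-trivial mixtures for clustering tests.

`simulate_markov_trajectory()` draws a state sequence from a known
row-stochastic matrix started at its stationary distribution, then emits
per-state Gaussian features. It emulates a discretized trajectory with
metastable kinetics; it does not emulate intra-state diffusive correlation
(emissions are i.i.d. within a state), so tICA autocorrelations reflect only
the chain's relaxation.

`make_crosslink_tables()` draws cross-linked lysine pairs by contact-order
class (local/intermediate/long, weights configurable; defaults 0.4/0.4/0.2,
a profile typical of a compact disordered monomer), with quality fields from
stated distributions and two bookkeeping columns: the drawn class and a
pass/fail flag evaluated at generation time against the identification
thresholds. The default lysine list follows the tau repeat domain. What
passes the synthetic end-to-end test is the plumbing — filters, consensus,
normalization, classification — not any claim about real spectra: the
generator has no peak shapes, no decoys, and its FDR column is a label, not
an estimate.

All generators seed one global RNG per call from the spec's `seed` field and
record it in the output metadata, so every fixture is a deterministic
function of its spec.

## The Markov-state-model engine

**Featurization.** `featurize_min_distances()` produces one column per
residue pair between two disjoint groups (minimum atom–atom distance per
frame); two 7-residue groups give the 49-dimensional featurization used for
an 18-residue fragment's inter-strand contacts.

**tICA.** Instantaneous and time-lagged covariances are estimated on
mean-free data and symmetrized, which enforces a real generalized
eigenproblem; components are eigenvectors of C₀^{-1/2} C_τ C₀^{-1/2},
eigenvalues are lag-autocorrelations. On singularity, ε = 10⁻¹⁰·trace/dim is
added to the diagonal with a warning and numerically null directions are
dropped.

**Discretization.** k-means++ seeding with an explicit seed, then capped
Lloyd iterations through `stats::kmeans`. A pass that hits the iteration cap
is still a valid Voronoi partition of the reduced space, so convergence is
recorded in the result rather than raised.

**Estimation.** Transition counts use sliding-window pairs at lag τ
(maximizing counts; the common default). The active set is the strongly
connected component of the count graph carrying the most counts; the
discarded frame fraction is stored. The reversible estimator symmetrizes
counts, C̄ = (C + Cᵀ)/2, then row-normalizes — a closed form whose detailed
balance (with π ∝ row sums of C̄) is testable to 10⁻⁸, chosen over the
iterative maximum-likelihood reversible estimator for transparency;
the non-reversible row-normalized estimator is available alongside.
Spectra of reversible models are computed through the π-symmetrized similar
matrix, guaranteeing real eigenvalues.

**Validation.** Implied timescales are t_i(τ) = −τ/ln λ_i(τ); non-positive
eigenvalues yield `NA` markers rather than errors. The VAMP-2 score is
Σλ², the reversible reduction of the singular-value form. The
Chapman–Kolmogorov test holds the PCCA+ partition fixed from the base model
(no re-clustering at longer lags) and compares the propagated coarse model
(coarse(T))^f against re-estimation at lag f·τ.

**PCCA+.** Memberships come from the inner-simplex construction: the top
n_macro right eigenvectors (first column set to the constant vector), vertex
rows located by the orthogonalization index search, and the inverse-vertex
linear map; small infeasibilities are clipped and rows renormalized. Crisp
labels are argmax memberships. Non-reversible inputs are refused with an
instruction to re-estimate reversibly, since the construction assumes a real
spectrum.

**TPT.** The forward committor solves its linear system exactly; the
backward committor is 1 − q⁺ for reversible models and is otherwise computed
from the time-reversed chain. Gross flux is F_ij = π_i q⁻_i T_ij q⁺_j, net
flux its positive part, and pathways are extracted by iterative widest-path
(maximum-bottleneck Dijkstra) decomposition, subtracting each bottleneck
until less than 10⁻⁸ of the total flux remains. Committor/flux analysis can
be run on the 200-microstate model or on the PCCA+-coarse-grained model
(`coarse_grained_model()`); both are exposed because practice varies, and
the coarse route inherits detailed balance by construction under
π-weighted lumping.

**MFPT.** m_i = τ + Σ_j T_ij m_j with m = 0 on the target, source values
π-weighted; unreachable targets are detected by graph reachability first.

Physical time enters only at reporting: lags are frames internally, with
`dt` (ns per frame) multiplying outputs. For trajectory trimming,
`subsample_trajectory()` keeps the on-grid frames (first frame always, last
when on the grid), so a 3 μs span at a 100 ps target yields 30001 frames.

## NMR observables

`ncsp()` averages secondary Hα shifts over a symmetric neighbour window
(default half-width 3, truncated at termini — a documented behaviour, not an
error), normalizes by the full-structure reference deviation, and inverts
the sign so positive means helical (full-helix Hα deviations are negative).
Values are clamped to [−1.5, 1.5] with the clamp count recorded. Weighting
within the window is uniform; the original neighbour-correction tool's exact
weighting is not restated in accessible form, so uniform weights are the
package's documented choice and the reference table is exported for
substitution. Only Hα is supported — the motivating analyses use Hα
exclusively — and the bundled random-coil/full-structure constants are
adapted from the published shift statistics underlying propensity
calculators.

`noe_effective_distances()` computes r_eff = ⟨r⁻⁶⟩^(−1/6) per atom pair.
Convexity gives min(r) ≤ r_eff ≤ mean(r), and r_eff scales linearly with the
coordinates — both asserted as properties. The 4 Å observability threshold
applies to proton pairs; when Cα proxies are used (as in the bundled
fixtures) the flag is indicative only.

## Cross-link analysis

Filtering applies the xQuest-style acceptance set — score > 25, FDR < 0.05,
mass error in [−2.2, +3.8] ppm, %TIC > 10, peptide length ≥ 6 aa — with
strict/non-strict boundaries exactly as written (score 25 fails, length 6
passes) and per-criterion rejection counts attached, since for this kind of
analysis the filters are the science and must be auditable. Consensus
retains pairs present in n-of-n replicates by default (the five-of-five
rule). "Normalized frequency" is read as within-replicate proportion of
total spectral counts — the formula is not fully pinned down in common
usage, so a raw-mean mode ships alongside and the choice is recorded here.
Contact order is the absolute residue separation of the linked positions,
binned ≤ 10 / 11–39 / ≥ 40; loop-links and cross-links are treated
identically once positions are resolved. Repeat bins default to the tau
repeat domain (R1 244–274, R2 275–305, R3 306–336, R4 337–368, R′ 369–380)
and are fully configurable. Pattern clustering is average-linkage
agglomerative clustering of link columns under Euclidean distance, cut to
four groups by default; a constant matrix degrades to one group with a
warning. Positional ambiguity is out of scope: records must arrive with
resolved positions.

## Problem sizes and tolerances in the test suite

The suite favours analytic fixtures (exact to 10⁻⁸ or better) wherever a
closed form exists: the 2-state spectrum, geometric waiting times, linear
committors, block PCCA+. Stochastic checks use sizes chosen to keep the
whole suite under a minute of compute while leaving comfortable statistical
margins: 10⁵-step chains for occupancy and tICA tests, 2×10⁵–5×10⁵ steps for
full pipeline parameter recovery (macrostate populations to 0.03, slowest
timescale to 15%), 10⁶ steps for Monte-Carlo reactive-flux comparisons (3%),
and 10⁴ links per replicate for contact-class proportions (4σ binomial
bands). Oracle-equivalence tests (GROMOS vs brute force, SVD vs quaternion
superposition) are exact.

## Known limitations

- Ensembles are Cα-centric in the fixtures; all operations accept arbitrary
  atom selections, but proton-level NOE observability on Cα proxies is
  approximate by construction, and whether Cα-only geometry shifts the
  turn-register classification boundaries relative to full-atom ensembles
  is untested — flagged, not assumed.
- The reversible estimator is the symmetrized closed form, not the
  constrained MLE; for heavily non-equilibrium sampling the two differ.
- Hidden-Markov coarse-graining and Bayesian error bars are out of scope;
  PCCA+ crisp assignment is the supported lumping.
- The comparison metric sometimes quoted as "oversampling of extended
  structure by N%" lacks a published formula and is deliberately not
  implemented.
- No periodic-boundary imaging and no binary trajectory formats: inputs are
  multi-model PDB and CSV, which keeps the package dependency-light and its
  fixtures text-based.
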