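# tauens

Conformational-ensemble, Markov-state-model and cross-link analysis for
aggregation-prone peptides.

## The scientific problem

The microtubule-associated protein tau aggregates in many neurodegenerative
diseases. Its repeat domain (tauRD, residues 243–380 in 2N4R numbering)
contains the amyloid-nucleating hexapeptide <sup>306</sup>VQIVYK<sup>311</sup>,
whose exposure is regulated by a conserved `PGGG` β-turn motif immediately
upstream. Whether a peptide fragment spanning this region folds into a
β-hairpin that sequesters the amyloid motif — and how stably, and in which
cross-strand register — correlates with whether the full protein resists or
undergoes aggregation. `tauens` packages the quantitative machinery needed to
ask those questions of a conformational ensemble:

- **Ensemble geometry** — mean minimum inter-residue distance maps
  (`min_distance_map()`), centre-of-mass group distances
  (`group_com_distance()`), least-squares-fitted RMSD (`rmsd_fit()`,
  `pairwise_rmsd()`), and GROMOS-style greedy neighbour-count clustering
  (`gromos_cluster()`).
- **Turn register** — the hairpin-register statistic
  ρ = d(Cα₄, Cα₁₂) / d(Cα₇, Cα₁₂), classifying each frame as
  left-shifted (ρ < 0.75), centered (ρ ≈ 1) or right-shifted (ρ > 1)
  (`turn_register()`).
- **Kinetics** — a Markov-state-model engine: minimum-distance featurization
  (`featurize_min_distances()`), tICA (`tica_fit()`), seeded k-means++
  discretization (`kmeans_discretize()`), reversible MSM estimation with
  ergodic trimming (`estimate_msm()`), implied timescales
  t₂ = −τ/ln λ₂ (`implied_timescales()`), VAMP-2 scores, the
  Chapman–Kolmogorov test (`ck_test()`), PCCA+ coarse-graining (`pcca()`),
  mean first-passage times (`mfpt()`) and transition path theory — committor
  q⁺, gross flux F_ij = π_i q⁻_i T_ij q⁺_j, net flux, and widest-path
  pathway decomposition (`tpt()`).
- **NMR observables** — neighbour-corrected secondary-structure propensity
  from Hα chemical shifts (`secondary_shifts()`, `ncsp()`; negative =
  β-extended, positive = α-helical) and ensemble NOE effective distances
  ⟨r⁻⁶⟩^(−1/6) with a 4 Å observability threshold
  (`noe_effective_distances()`).
- **Cross-linking mass spectrometry** — post-search filtering on the xQuest
  acceptance thresholds (`filter_ids()`), replicate consensus
  (`consensus()`), frequency normalization (`normalize_frequency()`),
  contact-order classes (local ≤ 10, intermediate 11–39, long ≥ 40 residue
  separation; `classify_contact_order()`), tau repeat binning
  (`bin_by_repeat()`), pattern clustering (`cluster_link_patterns()`) and
  peptide modification fractions (`modification_fractions()`).
- **Synthetic ground truth** — generators for idealized hairpin/extended
  Cα ensembles (`make_hairpin_ensemble()`, `make_extended_ensemble()`),
  Markov trajectories with Gaussian emissions
  (`simulate_markov_trajectory()`) and replicate cross-link tables
  (`make_crosslink_tables()`), each returning the truth needed to validate
  the analysis stack end to end.

## Worked example

Mix 40 noisy left-registered hairpin frames with 20 extended frames, cluster
at the 0.4 nm cutoff, and read off the turn register:

```r
library(tauens)

hp  <- make_hairpin_ensemble(hairpin_spec(n_res = 18, apex = 7,
                                          strand_sep = 4.8, noise_sd = 0.5,
                                          n_frames = 40, seed = 1))
ex  <- make_extended_ensemble(n_res = 18, noise_sd = 0.5,
                              n_frames = 20, seed = 2)
ens <- bind_ensembles(hp, ex)

cl <- gromos_cluster(ens, cutoff = 0.4, cutoff_unit = "nm")
round(cl$populations, 3)
#> [1] 0.667 0.333

rp <- turn_register(ens, role_indices = c(4, 7, 12))
table(rp$classification)
#>  left right
#>    40    20
mean(rp$ratio[cl$assignments == 1])
#> [1] 0.397
```

The top GROMOS cluster recovers the planted 2:1 hairpin fraction exactly;
every hairpin frame classifies as left-registered (ρ < 0.75, here ≈ 0.4) and
every extended frame as right-registered (the collinear chain gives
ρ = 8/5 = 1.6), so the register statistic separates the two conformations
cleanly even under 0.5 Å coordinate noise.

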