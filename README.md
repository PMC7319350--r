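# samconf

Tools for analysing the conformational space of S-adenosylmethionine
(SAM), the methyl-donor cofactor of methyltransferases, and of its
demethylated product S-adenosylhomocysteine (SAH).

SAM is flexible in water but strongly restricted when bound to proteins,
and the restriction differs sharply between protein folds — most
strikingly between trefoil-knotted methyltransferases (which bind a bent
ligand) and unknotted ones (which bind an extended one). `samconf`
implements the quantitative pipeline for studying this:

* **ROESY restraints.** Cross-peak intensities are converted to
  interproton distances with the isolated spin-pair relation
  `r = (I_ref / I)^(1/6) · r_ref`, calibrated on the H1'–H2' reference
  pair (2.90 Å ± 0.2 Å), with first-order error propagation over the
  reference distance and both intensity errors. The package ships the
  39-restraint table of free SAM in water at 25 °C as a plain-text
  fixture (`sam_restraints()`).
* **Conformational descriptors.** Two angles capture SAM's overall
  shape: the glycosidic dihedral χ = O4'-C1'-N9-C8 (syn / anti₁ / anti₂ /
  intermediate classes) and the bend angle θ = SD-O4'-N9
  (bent for θ ∈ [80°, 125°], extended otherwise). SAM bound to knotted
  methyltransferases occupies the 2-D window θ ∈ [80, 125] × χ ∈ [−20, 60].
* **Ensemble clustering.** GROMOS neighbour-count clustering of
  conformer ensembles by least-squares RMSD over SAM's 27 heavy atoms
  (default cutoff 1.25 Å), with medoid representatives and cluster
  populations.
* **Population deconvolution.** Exhaustive grid search over cluster
  subsets (up to 4) and population compositions: per restraint the
  medoid distances are r⁻⁶-averaged,
  `d_cl = (Σ vᵢ xᵢ⁻⁶ / Σ vᵢ)^(−1/6)`, and candidates are scored by the
  error-weighted RMSD `√(Σ wᵢ (d_cl,i − d_NMR,i)² / Σ wᵢ)` with
  `wᵢ = eᵢ⁻²`.
* **Structure survey.** Extraction of SAM/SAH conformers from
  protein–ligand PDB/mmCIF files, binding-site residues within 5 Å with
  moiety resolution (adenine / ribose / methionine) and main-chain
  flags, and per-group descriptor distributions.
* **Synthetic data.** An idealised SAM template (27 heavy atoms plus
  non-exchangeable protons), torsion-sampled mixture ensembles with
  known ground truth, simulated noisy ROESY intensities, and synthetic
  protein–ligand complexes — so the whole pipeline is testable without
  downloading anything.

Everything is tidyverse-native: functions take data frames first and
return tibbles, fitted objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

Simulate the four-state water mixture (50% syn-extended, 20% syn-bent,
10% syn-bent-close, 20% anti₁-extended), generate noisy ROESY peaks,
and recover the populations:

```r
library(samconf)

spec <- synthetic_spec(sam_default_components(chi_sd = 0),
                       n_conformers = 500, seed = 42)
bundle <- sample_ensemble(spec)

cal <- roesy_calibration(i_ref = 1000)
peaks <- simulate_roesy(bundle, cal, noise_sigma = 0.02)
restraints <- intensity_to_distance(peaks, cal)

clusters <- cluster_conformers(pairwise_rmsd(bundle$ensemble), cutoff = 1.25)
tidy(clusters)
#> # A tibble: 4 × 4
#>   cluster medoid_id   size population
#>     <int> <chr>      <int>      <dbl>
#> 1       1 synth00003   265      0.53
#> 2       2 synth00004    91      0.182
#> 3       3 synth00005    87      0.174
#> 4       4 synth00001    57      0.114

fit <- medoid_distances(clusters, bundle$ensemble, restraints) |>
  fit_populations(restraints, max_k = 4, grid_step = 10)
fit
#> Population fit: clusters {1, 2, 3, 4} at 50/20/20/10% -> weighted RMSD 0.0134 A
#> (searched 286 candidates over 4 clusters, max_k = 4, 10% grid)
```

Despite 2% multiplicative intensity noise, the grid search recovers the
generating populations exactly (the sampled cluster sizes, 53/18/17/11%,
are *not* the fitted populations — the fit sees only the restraints) and
the residual weighted RMSD is 0.013 Å. Descriptor profiles summarise the
ensemble per group:

```r
desc <- describe_conformers(bundle$ensemble)
labels <- tibble::tibble(conformer_id = desc$conformer_id, group = "water")
compare_groups(build_group_profile(desc, labels))
#> # A tibble: 1 × 14
#>   group     n   syn anti1 anti2 intermediate other  bent knotted_mt_like ...
#> 1 water   500 0.818 0.182     0            0     0 0.288               0 ...
```

`autoplot(fit)` draws measured-vs-fitted distances with error bars;
`autoplot(profile, "map")` draws the 2-D (θ, χ) occupancy chart.

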