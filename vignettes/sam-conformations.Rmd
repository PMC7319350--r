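---
title: "Methods: SAM conformational analysis with samconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAM conformational analysis with samconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

S-adenosylmethionine (SAM) exchanges between conformational families in
solution — syn and anti orientations of the adenine base about the
glycosidic bond, and extended versus bent arrangements of the
methionine chain relative to the adenosine. A ROESY experiment sees
only population-averaged interproton distances, so characterising the
ensemble means (i) turning cross-peak intensities into distance
restraints with honest uncertainties, (ii) reducing a large conformer
ensemble to a handful of representative states, and (iii) asking which
small mixture of representatives reproduces the averaged distances.
Bound-state conformers extracted from protein–ligand structures are
then compared against this free-form ensemble through two scalar
descriptors. `samconf` implements each stage as a data-frame-first
function so the stages compose with the pipe.

## Distance restraints from ROESY intensities

Under the isolated spin-pair approximation the cross-relaxation rate,
and hence the cross-peak intensity, scales as r⁻⁶. Calibrating against
a pair of known separation gives

    r = (I_ref / I)^(1/6) · r_ref

with the H1'–H2' pair (r_ref = 2.90 Å, Δr_ref = 0.2 Å) as the internal
reference. Intensities carry arbitrary units; only the ratio enters, so
no unit is stored, and when the reference peak is absent from a user's
peak list the reference intensity must be supplied explicitly —
`roesy_calibration()` refuses to guess.

Uncertainties propagate to first order assuming independent errors in
r_ref, I_ref and I; the three partial-derivative terms add in
quadrature. Two limiting behaviours are useful checks: with the
intensity errors zeroed, Δr = (r / r_ref) · Δr_ref exactly, and the
propagated error is monotone in every input error. The test suite
verifies the full expression against central finite differences of the
conversion formula. Distances are kept at full precision internally;
the two-decimal precision of the packaged table is presentation only.

The packaged table (`sam_restraints()`) holds the 39 interproton
distances of free SAM in water at 25 °C with their uncertainties.
Proton labels pass through a canonicalisation map
(`normalize_proton_label()`) because prose labels ("methyl group",
"Hβ"), PDB-style names (H5'', H5'2) and typographic variants (H5")
coexist in the wild. The methyl group is a pseudo-atom: on structures
it is evaluated as the r⁻⁶-effective distance over the three methyl
protons, d_eff = (mean(d_k⁻⁶))^(−1/6), which is what the NOE of a
fast-rotating methyl reports; a geometric-centroid alternative is
available via `method = "centroid"`.

## Descriptors and classification

Two angles describe a SAM conformer:

* χ, the glycosidic dihedral O4'-C1'-N9-C8, signed, right-handed
  (IUPAC) convention, range (−180°, 180°]. Classes: syn for
  χ ∈ [−150, −100], anti₁ for χ ∈ [−30, 30], anti₂ for χ ∈ [50, 100],
  intermediate for χ ∈ (−100, −50), otherwise `other`.
* θ, the planar SD-O4'-N9 angle, range [0°, 180°]. Bent for
  θ ∈ [80, 125], extended otherwise.

Choices worth flagging:

* **Boundary handling.** The class windows are stated as loose
  intervals in the literature ("between", "around"); we close them
  (inclusive at both ends) and leave the intermediate window open so it
  cannot collide with syn at −100°. Values falling in no window are
  `other`, never silently absorbed. All windows are configurable
  through `glyco_rules()`, which rejects overlapping χ windows.
* **The extended window.** No explicit θ window for "extended" exists;
  we treat everything outside the bent window as extended. This is an
  assumption, exposed as the `bent` rule.
* **Syn near +180°.** The syn window is defined only on the negative
  side. Whether near-±180° values should count as syn is genuinely
  open; we classify them `other` by default rather than invent a
  window, and users can widen `syn` in `glyco_rules()` if their
  convention differs.
* **Knotted-MT window.** The 2-D region characteristic of SAM bound to
  knotted methyltransferases, θ ∈ [80, 125] and χ ∈ [−20, 60], is
  exposed as `is_knotted_mt_like()`.
* **Bent subtypes.** The distinction between the bent form whose
  carboxylate faces the ribose hydroxyls and the one bending away has
  no published numeric criterion; it is not hard-coded. The synthetic
  generator realises both as distinct torsion sets, and users can add
  their own descriptor on top of the coordinate tibbles.

The dihedral sign convention was cross-checked against
`bio3d::torsion.xyz` and an independent acos-plus-triple-product
construction; the tests enforce agreement to 1e-9°, plus rigid-motion
invariance, reversal symmetry and mirror antisymmetry.

## Clustering and superposition

Conformers are compared by least-squares RMSD after optimal (Kabsch)
superposition, by default over SAM's complete 27-heavy-atom set
(15 C, 6 N, 5 O, 1 S — shipped as `sam_heavy_atoms`). The all-pairs
RMSD matrix is computed in compiled code (one 3×3 SVD per pair after
precentring); the R-level single-pair path and `bio3d::rmsd(fit=TRUE)`
serve as independent cross-checks in the tests.

Clustering uses the GROMOS neighbour-count scheme: the conformer with
the most neighbours within the cutoff (default 1.25 Å) becomes a
medoid, it and its neighbours are removed, and the process repeats.
Ties in neighbour count break to the lowest ensemble index, which makes
the output deterministic. The medoid is an actual ensemble member, not
an averaged structure. Two consequences tested as invariants: every
member is within the cutoff of its medoid at assignment time, and the
cluster count is non-increasing in the cutoff.

## Population fitting

Given per-cluster medoid distances x_i and candidate populations v_i,
the effective distance per restraint is the population-weighted power
mean of exponent −6:

    d_cl = (Σ v_i · x_i⁻⁶ / Σ v_i)^(−1/6)

This is the quantity a ROESY experiment averages over an exchanging
ensemble. (A literal alternative normalising by Σ v_i⁻⁶ without the
−1/6 root is dimensionally inconsistent — it cannot return a length —
and is retained only behind `r6_average(..., literal = TRUE)` for
inspection; it is never used for fitting.) Candidates are scored by the
error-weighted RMSD with weights e_i⁻² from the restraint
uncertainties, which is why zero restraint errors are rejected rather
than clamped.

The search is exhaustive: all cluster subsets of size 1..K (default
K = 4) crossed with all strictly positive population compositions on a
percentage grid. The grid step is not prescribed anywhere authoritative;
the default is 10% (configurable down to 1%). The candidate count is
Σ_k C(n, k) · C(100/step − 1, k − 1) — about 2.8 million for n = 90
clusters, K = 4, 10% grid, which is minutes of compute; at 1% it is
astronomically larger, so coarse steps are the sensible default.
Compositions assign strictly positive weight to every subset member:
zero-weight members would duplicate smaller subsets and inflate tie
handling. Ties break deterministically to the lexicographically
smallest subset, then composition — exercised in the tests with exact
duplicate medoids. The enumeration count is itself asserted against the
closed form.

## The synthetic generator

The generator stands in for two data sources that cannot be shipped: a
microsecond-scale solvent MD trajectory of free SAM and the PDB's
corpus of bound ligands. It emulates the *structure* of those data — a
mixture over glycosidic states with a flexible methionine chain — not
their physics: there is no force field, no solvent, and no kinetics.

`sam_template()` builds an idealised SAM from internal coordinates:
textbook bond lengths and angles, both rings as planar regular polygons
(ribose side 1.43 Å, purine side 1.39 Å), the base and C5' on the
β face of the sugar as in β-D-ribofuranose, and all non-exchangeable
protons (exchangeable N-H/O-H protons are omitted; they are invisible
in the D₂O ROESY bookkeeping). Six torsions are driven: χ and the five
rotatable bonds of the methionine chain (`met1` = C3'-C4'-C5'-SD
through `met5` = CG-CB-CA-C). Torsion driving rotates everything distal
to the bond, using the template's covalent bond table; a conformer is
rejected and resampled when any non-bonded, non-1-3 pair falls below
0.8× the sum of covalent radii, with a bounded retry budget.

Because the rings are rigid, θ is a function of `met1` alone: it spans
roughly 97–154° over the full rotation, crossing the bent window for
`met1` between about −150° and +35°. The default mixture
(`sam_default_components()`) realises the reference free-SAM picture
with exactly four states — 50% syn-extended, 20% syn-bent-away,
10% syn-bent-close, 20% anti₁-extended, i.e. 80/20 syn/anti₁ and
70/30 extended/bent — with χ means −120° (syn) and 0° (anti₁) and chain
torsion sets chosen once, during template construction, so that the
bent components sit near θ ≈ 97° (inside the window), the extended ones
near 139° (outside), and all four are mutually ≥ 1.5 Å apart in
heavy-atom RMSD so a 1.25 Å clustering separates them. The
within-component spread `chi_sd` (wrapped-normal on χ) defaults to 10°;
setting it to 0 makes components rigid, which is the regime where exact
population recovery is provable and tested.

Simulated ROESY intensities invert the calibration relation at the
ground-truth effective distances — the r⁻⁶ average of per-component
representative distances at the *specified* (not realised) populations,
the representative being the member whose χ lies closest to the
component mean. Noise is multiplicative lognormal
(`I · exp(N(0, σ))`): NOE intensities are positive and their errors
scale with signal, and no authoritative noise model exists for this
setting, so this is a documented stand-in. The reported per-peak
intensity error is the exact lognormal standard deviation
`I·√(exp(σ²) − 1)`, consistent with the noise actually applied.

Synthetic protein–ligand complexes place short glycine backbone strands
around the template: the `compact` style sandwiches the adenine base at
4 Å on both faces (guaranteeing main-chain contacts within 5 Å of
adenine atoms), the `open` style moves the sandwich to 14 Å so the base
is exposed, and both keep a small ribose-side probe. These are
geometric scaffolds for exercising the contact code, not believable
proteins — labelled synthetic throughout.

## The structure survey

`extract_ligands()` pulls every SAM/SAH instance (chain + residue
number, optionally every MODEL) out of PDB or mmCIF files via bio3d,
resolving altlocs to the highest occupancy (ties to altloc A) and
normalising atom names to prime notation. Binding-site contacts list
every protein residue with an atom within the cutoff (default 5 Å) of
any ligand atom, recording the minimum distance, the ligand moiety
achieving it under the shipped three-way partition (adenine = purine
ring + N6; ribose = sugar ring + O2'/O3'/C5'; methionine = SD through
the amino-acid backbone, with linkage atoms assigned to their ring
side), and whether the protein atom is main-chain (N, CA, C, O).
Distances use heavy atoms only by default since crystal structures
usually lack hydrogens; whether the original 5 Å definition included
hydrogens is unknowable from the outside, so the choice is exposed as
`heavy_only`. Residue numbering is taken verbatim from the file.

Group labels (knotted / unknotted / ...) are user-supplied metadata —
knot detection is out of scope — and an example label file for eight
knotted methyltransferase PDB entries ships in `inst/extdata/`.
Profiles bin χ and θ at 10° (configurable), keep empty label groups
visible as zero rows, and `compare_groups()` tabulates class fractions,
medians, IQRs and the knotted-window fraction side by side.

## Problem sizes and determinism

The test suite exercises the full inversion at 2,000 conformers (four
rigid components, zero noise: clustering must find exactly 4 clusters
and the fit must return the generating 50/20/10/20 populations with
weighted RMSD below 1e-6 Å) and the noise response at 200 conformers
with 100 noise seeds per σ ∈ {0, 0.02, 0.05, 0.1}, asserting that the
mean absolute population error is zero at σ = 0 and non-decreasing in
σ. These sizes were chosen as the smallest at which the claims are
sharp: recovery exactness does not improve beyond the point where each
component is populated and separable, and the noise sweep needs seed
averaging, not ensemble size. All generation is seeded and
bit-reproducible given `(spec, seed)`.

## Known limitations

* The template's planar rings ignore sugar pucker, so θ is controlled
  by a single torsion and the template's interproton distances are
  ideal-geometry approximations — good enough for exercising the
  pipeline, not for quantitative comparison with experimental tables.
* Passing the synthetic closure tests shows the machinery inverts its
  own forward model; it does not show that four clusters suffice for
  real MD ensembles, that the 10% grid resolves real populations, or
  that the lognormal noise model matches a spectrometer.
* Epimer chemistry ((+)-SAM vs (−)-SAM), spectral processing and peak
  picking, hydrogen-bond/salt-bridge typing, and knot detection are all
  out of scope by design.
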