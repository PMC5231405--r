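---
title: "Geometry of phosphotransfer reaction centers and the slippery HK:RR interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of phosphotransfer reaction centers and the slippery HK:RR interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcsgeom)
```

## The scientific question

Bacterial two-component systems (TCS) transmit signals by moving a
phosphoryl group from a histidine of a sensor histidine kinase (HK) to an
aspartate of a response regulator (RR). Many such systems are strictly
unidirectional — P~His -> Asp proceeds, the back reaction does not — even
though the P–N and P–O bond energies are nearly equivalent. `tcsgeom`
implements the structural analysis that connects this directionality to
the geometry of the phosphotransfer reaction center and to the mechanical
character of the HK:RR interface, starting from deposited crystal
structures of HK:RR complexes (and from synthetic coordinate sets with
known ground truth).

## The reaction-center model

Phosphotransfer is a nucleophilic substitution at phosphorus. Two
geometric descriptors of the pre-transfer complex discriminate its
mechanistic regime:

* **d(His Nε2 – Asp Oδ1)** — the distance between the donor nitrogen and
  the acceptor carboxylate oxygen. Short distances force the entering and
  leaving groups to remain engaged simultaneously (a *tight*, associative
  substitution); long distances only permit a largely dissociated,
  metaphosphate-like intermediate (a *loose*, dissociative substitution).
* **r = d(Mg²⁺–Asp Oδ1) / d(Mg²⁺–His Nε2)** — the asymmetry of the
  divalent cation with respect to the two reactive side chains. A cation
  parked next to the aspartate (r far below 1) stabilises the migrating
  phosphoryl group on the RR side and disfavours back-transfer.

`classify_mechanism()` combines both: **Group I**
(associative-compatible, the geometry of reversible transfer) requires
d < 6.5 Å *and* r > 0.6; **Group II** (dissociative, unidirectional
His -> Asp) requires d > 6.5 Å *and* r < 0.6; every other combination —
including exact threshold hits — is *ambiguous*. Two auxiliary figures are
reported as context, never as extra thresholds: an N–O separation of
6.6 Å is the van-der-Waals bound at which the intermediate can fully
dissociate, and a reaction-coordinate distance (phosphorus surrogate to
the entering atom) of at least 4.9 Å leaves room for a free metaphosphate;
`classify_mechanism()` attaches a note when the latter condition holds.
Both cutoffs are exposed as parameters (`d_cut`, `r_cut`) because they are
empirical discriminants, not physical constants.

Where a structure lacks a moiety — no phosphoryl group, no cation —
`transplant_moiety()` carries it over from a homologous donor structure
after a least-squares fit of a shared region, preserving the donor's
internal geometry exactly and flagging the grafted atoms with their
provenance. This mirrors the standard modelling moves for such tables:
a BeF₃⁻ mimic or cation placed by receiver-domain superposition, or a
phospho-His imported from the free phosphorylated kinase. Energy
minimisation after transplanting is deliberately **not** performed; the
published comparison of minimised and unminimised models differs by only
0.09 Å, which is why the package's benchmarks use ±0.15 Å (distances) and
±0.05 (ratios) tolerances for transplant-derived values.

The Oδ1/Oδ2 labelling of an aspartate is chemically arbitrary in a crystal
model, so the Oδ policy is explicit: the conventional `OD1` by default
(what published tables quote), or `nearest` (to the His Nε2) on request;
reports state which atom was used.

## The two-regime slippage matrix

Whether the receiver domain *rolls* with the kinase or *slides* along it
is quantified by a pair of superpositions for every pair of refined
complexes (`superposition_matrix()`):

1. **DHp-fit regime** — fit the structurally invariant DHp region of the
   kinase (Cα, residues 190–234 by default), then evaluate the rmsd over
   all receiver Cα atoms (residues 1–129) *without refitting*;
2. **REC-fit regime** — fit the receiver on itself and evaluate the same
   atoms.

The no-refit rule is the entire point: the first regime measures how much
the receiver moves relative to the kinase, the second how much it changes
internally. A large first number over a small second one is the signature
of a "slippery" interface — rigid-body gliding with preserved contacts.
On the published nine-pair benchmark matrix shipped with the package
(`reference_slippage_matrix()`), the receiver slips by up to 2.45 Å while
its internal conformation stays at 0.32 Å on average. The residue range
190–234 follows the matrix legend of the published table; the prose
elsewhere says 190–235, and the range is a parameter of `complex_entry()`
for exactly that reason. Missing receiver residues shrink the evaluated
pair set symmetrically for every cell involving that entry, keeping cells
comparable.

## Interface burial and shape complementarity

`sasa()` implements Shrake–Rupley quadrature: per atom, a fixed
golden-spiral point set (default 960 points) on the probe-expanded sphere
(probe 1.4 Å, a water), with a point counted accessible when no
neighbouring expanded sphere covers it. The golden-spiral set makes
results bit-reproducible for a given `n_points`. Radii come from a single
named Chothia-like element table; hydrogens and waters are excluded by
default (the relevant X-ray structures carry none), and unknown elements
either fall back to 1.8 Å with a warning or error out, as configured.

`buried_surface()` reports BSA = SASA(A) + SASA(B) − SASA(A∪B). The
headline number is the *two-partner sum* (the convention behind the
published ~1400 Å² figure for the phosphatase complex); the halved
"interface area" is also emitted for cross-tool comparison, and the burial
of partner A can be decomposed by domain ranges (DHp vs CA contributions).
Because the result depends on the radii table and quadrature, deposited
benchmark comparisons use a ±15 % tolerance. Hetero ligands (the ATP
analogue, BeF₃⁻, cations) are excluded from interface SASA by the default
selections; the toggle is the selection itself.

`shape_complementarity()` is the Lawrence–Colman statistic: dots on each
partner's van-der-Waals surface (dots inside a same-partner atom removed —
a solvent-excluded-surface approximation), a buried patch defined by
solvent occlusion (gap to the partner surface below one probe diameter), a
peripheral trim band (default 1.5 Å) and, per dot, the score
S = (n̂_a · −n̂_b) · exp(−w·d²) against the nearest opposing buried dot,
with w = 0.5 Å⁻². Sc is the mean of the two per-patch medians: +1 for
perfectly apposed parallel surfaces, ~0.7 for tight protein interfaces,
lower for loose ones.

## What the synthetic generator emulates — and what it does not

The `make_*` fixtures reproduce the *geometry* that each operation
measures, with ground truth known by construction:

* `make_reaction_center()` places Nε2, Oδ1, Mg²⁺ and an in-line
  phosphorus surrogate at exact requested distances (the near-180°
  donor–phosphorus–acceptor arrangement), wrapped in plausible His/Asp
  residues so the full file-I/O and atom-location path is exercised. The
  default loose-center parameters (7.6, 3.0, 6.38 Å) give r = 0.47, the
  dissociative exemplar geometry.
* `make_rigid_pair()` and `make_slippage_series()` impose known rigid
  motions; recovery is exact (≤ 1e−8 Å) because no noise intervenes.
* `make_sphere_system()` has closed-form spherical-cap areas, valid while
  overlaps stay pairwise — the generator's layouts respect that.
* `make_sc_surfaces()` builds two parallel walls from heavily overlapping
  large pseudo-atoms (default radius 15 Å, grid spacing 1 Å), so the
  facing surfaces are flat to ≈0.02 Å — far below dot resolution — and
  exactly complementary across the set gap: the measured Sc must approach
  exp(−w·gap²). Outside the finite wall the faces curve apart, producing
  a divergent rim of width ≈ √(2·probe·r_atom); the fixture therefore
  prescribes a trim band of that width (its `sc_args`), which is the same
  peripheral-trim mechanism the statistic always uses, sized to the
  fixture's geometry.

None of this is physically realistic protein structure: no rotamers, no
sequence, no packing, no noise model beyond optional Gaussian coordinate
jitter. Passing the fixture suite therefore demonstrates that the
*operations* are correct — pairing, fitting, measuring, classifying,
integrating areas — not that any biological conclusion holds for real
coordinates. The deposited-structure benchmarks play that second role,
and they require the coordinate files to be fetched once (see the README);
the package never downloads anything.

## Numerical choices

* **Superposition** is the closed-form SVD solution; the smallest
  singular direction is sign-corrected so a proper rotation
  (det = +1) is always returned, including at the degenerate 180°
  rotation. Collinear fit sets raise an error rather than a silent
  ill-conditioned answer. No outlier trimming is applied anywhere: the
  published rmsd figures read as plain all-pairs fits.
* **Alternate locations** collapse to the highest-occupancy conformer,
  ties broken lexicographically ('A' first) — deterministic and in line
  with common practice. Multi-model files yield model 1 unless asked.
* **Torsions** follow the IUPAC sign convention (trans = 180°), checked
  against both a constructed-geometry oracle and an independent
  implementation.
* **Orthogonalisation** uses the standard PDB frame (a along x, b in the
  xy-plane); symmetry operators are parsed from fractional notation into
  an affine map and applied in fractional space. Distance preservation is
  only guaranteed — and only asserted — for operators compatible with the
  cell's lattice system.
* **Seeds**: every stochastic generator takes an explicit seed (default
  20161212) and restores the caller's RNG state, so identical calls give
  byte-identical files.
* **Problem sizes** in the shipped tests and acceptance script — point
  clouds of 20–120 atoms, 100 superposition seeds, 1920-point SASA
  quadrature, 31 000-dot Sc sampling — were chosen so each check runs in
  seconds while keeping quadrature errors an order of magnitude below the
  asserted tolerances.

## Known limitations

* Transplant models are unminimised; steric strain is reported as clash
  warnings, not resolved.
* The Sc surface is a dot-sampled approximation of the solvent-excluded
  surface; absolute values depend mildly on dot density (the shipped
  parameters keep this within ±0.02 on the analytic fixtures).
* BSA depends on the radii table; cross-tool comparisons should use the
  same table or accept ~15 % spread.
* Label-to-chain correspondences for the deposited benchmark entries are
  not machine-readable from the published material; recomputation from
  coordinates therefore requires an explicit per-entry chain
  configuration, documented in the README, rather than guessed chains.
* Crystallographic data processing, molecular dynamics, coevolutionary
  analysis and energy minimisation are out of scope by design.
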