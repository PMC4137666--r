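---
title: "Methods: coiled-coil stability analysis with coilstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coiled-coil stability analysis with coilstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`coilstab` analyses the thermal stability of parallel trimeric coiled
coils — the fold adopted by bacterial lipoprotein-like "alanine zippers" —
from structure ensembles resolved over a replica temperature ladder. The
package covers the full chain of analysis: sequence diagnostics (heptad
register, lipobox motif, hydropathy, pH-dependent protonation), a geometric
interaction census (hydrogen bonds, salt bridges, intermonomer hydrophobic
contacts, helix content), superposition-based descriptors (RMSD, RMSF,
supercoil radius, neighbor clustering of decoys), melting-temperature
extraction, and 2-D free-energy-surface reconstruction by the weighted
histogram analysis method (WHAM). Because molecular-dynamics trajectories
are bulky and engine-specific, the package ships a synthetic generator that
emulates the relevant phenomenology — an ideal Crick-parameterised trimer
whose residues and chain association melt with logistic temperature
dependences — so every stage is testable end to end.

## Ideal coiled-coil construction

Chains are built in two steps. First a straight ideal alpha-helix is
assembled from fixed peptide internal coordinates (N–CA 1.458 Å, CA–C
1.525 Å, C–N 1.329 Å, omega 180°) with helical dihedrals (phi, psi) =
(−57.8°, −47.0°), using a natural-extension (NeRF) chain builder in C++.
The helix's exact screw symmetry (twist and rise per residue) is extracted
from the rigid transform mapping residues 1..L−1 onto 2..L; the chain is
then corrected per residue to the Crick local frequency `w1 = 720/7 ≈
102.86°`/residue and rise 1.51 Å, and wound onto the supercoil: a point at
transverse offset (x, y) and axial position z in the straight frame is
carried by the rotating radial frame of a supercoil centerline with radius
`R0` (default 6.1 Å) and frequency `w0` (default derived from a 190 Å
pitch, left-handed). Because the radial frame itself rotates with the
supercoil, the straight-helix twist plays the role of the Crick `w1`, and
one heptad closes exactly two local turns — the geometric condition that
keeps a/d positions facing the core along the whole bundle. Chains are
exact copies rotated by 360°/3, so C3 symmetry holds to machine precision.

Side chains are reduced to one pseudo-atom (`SCM`) per residue at a
per-residue calibrated distance from CA along the canonical CB direction,
serving as the side-chain center of mass; charged residues (K, R, H, D, E)
carry a second pseudo-atom (`SCQ`) 2.5 Å further out for salt-bridge
detection. This is sufficient because all contact definitions used here
need only side-chain centers of mass and charged-group termini, not
rotamers. Amide hydrogens are placed 1.00 Å from N in the C(i−1)–N–CA
plane opposite the bisector; chain-initial residues and prolines carry
none.

Verified properties of the construction: the supercoil radius round-trips
through `estimate_supercoil_radius()` to better than 0.1 Å across R0 in
[4, 8] Å; backbone dihedrals land near (−61°, −50°), inside the helical
window; and each chain of length L carries exactly L−4 backbone i→i−4
hydrogen bonds at ~3.1 Å and 12–14° deviation from linearity — comfortably
inside the 3.5 Å / 30° criteria, as in real alpha-helices.

## Interaction census

All cutoffs are inclusive (≤) and live in one configuration object:

* **Hydrogen bonds** — donor–acceptor heavy-atom distance ≤ 3.5 Å and
  deviation of the donor–H–acceptor angle from linearity ≤ 30° (i.e. angle
  at the hydrogen ≥ 150°). The stated 30° criterion is ambiguous between
  the angle at H and its supplement; the deviation convention used by the
  common trajectory-analysis tools was adopted, and both the distance and
  the angle are configurable. One record per (donor-H, acceptor) pair;
  records are classed `mainchain` (both partners backbone atoms of one
  chain), `intermonomer` (chains differ) or `intramonomer`.
* **Salt bridges** — closest charged-atom distance ≤ 4.0 Å between a basic
  group (Lys/Arg, protonated His, protonated N-terminus) and an acidic
  group (unprotonated Asp/Glu or C-terminal carboxylate), with no angular
  test; only intermonomer pairs are recorded, one per residue pair.
* **Hydrophobic contacts** — side-chain centers of mass of two hydrophobic
  residues (default set A, V, L, I, M, F, W) on different chains within
  7.0 Å. Glycine never participates.
* **Helix content** — a residue is helical when its available backbone
  dihedrals fall in phi ∈ [−100°, −30°], psi ∈ [−67°, −7°]. This is a
  deliberate, documented dihedral-window replacement for assignment
  programs that use empirical energy functions; it is exact on the ideal
  builds and on the generator's bookkeeping, which is what the tests pin.

Protonation follows a threshold pKa model: a group is protonated iff
pH < pKa (strict), with defaults Asp 3.65, Glu 4.25, His 6.0, Lys 10.4,
Arg 12.0, C-terminus 3.6, N-terminus 8.0. Protonation is therefore
monotone in pH, acidic conditions neutralise carboxylates (removing salt
bridges and carboxylate H-bond acceptors), and the model reproduces the
standard acidic-pH assignment for a chain with carboxyls at positions
6, 15, 23, 37, 50, 64, 65, 68, 71 plus the C-terminus.

## Synthetic replica ensembles

The melting model is two-state at two levels. At temperature T, each
residue is helical with probability `1/(1+exp((T−tm_helix)/width_helix))`;
the whole trimer is *associated* with probability
`1/(1+exp((T−tm_association)/width_association))`, so the expected radial
chain separation grows with the inverted association order parameter.
A dissociated frame has every chain displaced 15 Å radially outward —
far beyond the 7 Å contact cutoff — which makes the mean contact count an
unbiased logistic with midpoint `tm_association`. A deterministic
temperature-dependent displacement was rejected because it would place the
contact-loss midpoint where the displacement happens to cross the cutoff
rather than at `tm_association`. The model enforces
`tm_association < tm_helix`, encoding the unfolding order in which
intermonomer interactions are lost before secondary structure.

Frames are rebuilt from dihedrals: helical residues take the ideal helical
pair, coil residues draw phi ∈ [−180°, −30°] and psi ∈ [60°, 180°] — a
range disjoint from the helical psi window, so the dihedral criterion
rejects coil residues by construction. The chain-final residue has no psi,
so its coil phi is drawn from [−180°, −101°], outside the helical phi
window, preserving exact agreement between generator flags and geometric
helix assignment. Rebuilt chains are superposed onto the folded reference
by least squares; non-backbone atoms (O, SCM, SCQ) of coil residues get
0.5 Å Gaussian jitter (amide H rides with its nitrogen so donors stay
intact). Frames are i.i.d. within each temperature — the analysis stage
uses only the trailing-window rule, never time correlation. The per-frame
pseudo-energy is
`E = −2 kJ/mol × (#helical residues) − 1 kJ/mol × (#contacts) + N(0, 5 kJ/mol)`;
these scales are artifact choices of plausible per-residue magnitude, not
measured quantities, and `kB = 0.0083144621 kJ/mol/K` everywhere.

Defaults (`tm_association` 450 K, `tm_helix` 550 K, widths 20 K) place
both transitions in the interior of the 303.15–809.57 K ladder, in the
temperature range where the real systems of this fold family unfold in
implicit-solvent replica-exchange studies. Exact Boltzmann toy samplers
(1-D harmonic oscillator; two-level system) provide closed-form oracles
for the reweighting stage.

What the generator does *not* emulate: force-field energetics, solvent,
replica-exchange swap dynamics, autocorrelation, partial (per-interface)
dissociation, and side-chain rotamer excursions. Passing tests therefore
demonstrate the correctness of the analysis operators and the internal
consistency of the pipeline on data with known ground truth — not the
absolute melting temperatures of any real protein.

## Ladder, averaging and melting temperatures

`make_ladder()` builds the constant-ratio (geometric) ladder
`T_i = t_min · r^(i−1)`; with 64 rungs anchored at 303.15 and 809.57 K it
reproduces the published replica ladder for this fold family to within
0.28 K (the published rungs came from an exchange-probability server; the
geometric ladder is its standard analytic approximation). Observables are
averaged over the trailing `window_fraction` (default 0.5, the "last half
of each replica" convention), reporting mean ± SD per rung.

`extract_tm()` differentiates the (width-3 moving-average smoothed) means
by central differences on the non-uniform ladder and reports the rung of
the most negative derivative — Tm stays on-grid, matching the convention
of reading unfolding temperatures off the ladder. A curve is flagged
`non_sigmoidal` when the steepest rung is within 2 rungs of either end or
the total drop is below 4× the median per-rung standard error; the
midpoint fallback `extract_midpoint()` then interpolates the first
crossing of the half-amplitude level and is invariant under affine
rescaling. The smoothing width trades derivative noise against bias and is
configurable; 3 rungs is mild enough not to displace a logistic minimum.

A note on recovery precision: the helix-content curve pools hundreds of
independent residue states per frame, so its Tm lands on the true rung (or
a bracketing neighbour) reliably at 200 frames/rung for widths 5–30 K. The
contact count, by contrast, is an all-or-none trimer-level variable with
binomial noise maximal at the midpoint, so its derivative argmin scatters
by a few rungs; the robust statement for contacts is the unfolding *order*
(contacts always melt below helix content when
`tm_association < tm_helix`), and that is what the tests assert.

## WHAM

`wham_reweight()` implements Ferrenberg–Swendsen multiple-histogram
reweighting with a discretised energy axis (default 200 bins): frames are
histogrammed jointly on (energy bin, coordinate 1, coordinate 2), the
dimensionless replica free energies f_i are iterated to self-consistency
(`max |Δf_i| < 1e−7`, all sums in log space), and the density of states is
projected onto the coordinates at the target temperature. The
representative energy of each bin is the observed mean energy of its
samples, which makes discrete-energy systems (the two-level toy) exact and
reduces discretisation bias generally. Empty bins carry probability 0 and
masked (NA) free energy rather than a sentinel; f_i are reported relative
to f_1 = 0 (they are determined only up to a constant). Non-convergence
warns and flags the report rather than failing.

Validation: with a single replica at its own temperature the surface
equals the empirical histogram to 1e−10; two-level occupancies reweight to
the Boltzmann closed form within 2%; harmonic variances match kB·T0/k
within 5%; and reweighting to a ladder temperature reproduces that
replica's empirical moments within sampling error.

`find_basins()` locates local maxima of the probability surface (3×3
neighbourhood, out-of-grid neighbours ignored), merges peaks closer than
`min_separation` bins, and attaches every occupied bin to a peak by
steepest ascent, ordering basins by attached mass; a flat surface yields
none. On generator data the surface at the lowest ladder temperature is
dominated (mass ≈ 0.9) by a basin near 100% helix / 100% contacts and at
the highest temperature by one near 0/0 — the two-basin, no-intermediate
picture expected for a two-state folder.

## Decoy clustering and descriptors

`cluster_by_neighbors()` reproduces the standard decoy-selection
procedure: take the `top_n = 400` lowest-energy models, and iteratively
promote the model with the most still-unassigned neighbours (superposed CA
RMSD ≤ 3.0 Å, self excluded) to a cluster center, absorbing its
neighbours, until all models are assigned; ties go to the lower energy,
and the final representative is the center of the largest cluster. RMSD
uses proper least-squares (Kabsch) superposition on alpha-carbons; RMSD
series use frame 1 as reference (first value exactly 0); RMSF is taken
about a two-pass iterative mean structure with per-frame superposition of
the whole trimer (whole-trimer versus per-monomer framing is an open
convention; whole-trimer is the default and the choice is configurable by
operating on single-chain ensembles), and equivalent residues of the three
monomers are averaged. `estimate_supercoil_radius()` measures the mean
distance of window-5 CA running centroids (which cancel the helical
excursion to ~0.03 Å) from the principal axis of all CA atoms.

## Numerical and design choices

* Units: Å, K, kJ/mol, degrees; residues numbered 1-based; chains A/B/C.
  A mature-chain numbering offset (full-length minus signal peptide) is a
  presentation concern left to the caller.
* All cutoffs inclusive; boundary behaviour is test-pinned.
* Heptad register: the offset maximising hydrophobic occupancy of a/d;
  ties resolve to the smallest offset (poly-A returns offset 0). The
  hydrophobic set {A,V,L,I,M,F,W} is a single configurable constant —
  conventionally apolar, excluding G, P, Y.
* Kyte–Doolittle is the shipped hydropathy scale; windows are odd and
  truncated at the ends.
* The problem sizes used by the tests and the acceptance script (trimers
  of 14–28 residues, 120–200 frames per rung, 16–64 rungs, 2–3·10^4 toy
  samples) were chosen as the smallest ensembles at which the stochastic
  tolerances above are comfortably resolved.
* Reproducibility: every stochastic stage takes an integer seed and
  restores the caller's RNG state; identical configuration and seed give
  bit-identical series, tables and reports.

## Limitations

The synthetic ensembles are a phenomenological stand-in: absolute Tm
values, interaction counts of real proteins, and solvent- or
force-field-dependent effects are out of reach by design. H-bond detection
on pseudo-atom structures sees only the backbone network (side-chain
donors/acceptors require full-atom input, which the reader supports); the
intermonomer H-bond channel is therefore sparse on generated data. The
dihedral-window helix criterion ignores H-bond registry and will count
isolated helical-dihedral residues that an energy-based assigner might
not.
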