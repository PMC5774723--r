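---
title: "Models and methods behind asitetools"
author: "asitetools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind asitetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design choices made where conventions were genuinely open.

# The system

The package models the bipartite constructs of the 16S rRNA decoding
A-site: a 21-nt strand A spanning E. coli residues 1401–1412 and a 23-nt
strand B spanning 1488–1501, each flanked by four stabilizing terminal G:C
pairs and one dangling 3' nucleotide.  The eukaryotic variant differs by
six substitutions (A1408G, A1410U, C1411A, G1489U, U1490A, G1491A), which
removes the C1409:G1491 pair from the canonical pairing.  Three
2'-O-methylated decamers (1489, 1490, 1491) are fully complementary to the
prokaryotic strand B and carry 3, 2 and 1 mismatches against the eukaryotic
one.

`build_registry()` encodes the sequences, the E. coli numbering and the
reference Watson-Crick pairing.  Two conventions deserve note:

* **Numbering defaults.**  Only part of the numbering map is verifiable
  from in-text pair names (G1401:C1501, the 1407–1412 region, the
  1488–1501 span, and A1493 at strand-B position 10).  The terminal
  extensions are labelled `"ext"` rather than given speculative numbers;
  users can override the numbering through `rna_strand()`.
* **Mismatch definition.**  The antiparallel window scan counts only A:U
  and G:C as matches.  G:U wobbles count as mismatches — the printed
  1489/1490/1491 selectivity pattern (3/2/1 against the eukaryotic strand)
  only reconciles under strict Watson-Crick matching.  Ties between windows
  are broken toward the smallest window start.

# Synthetic trajectories

`generate_duplex_frame()` assembles an idealized duplex from rigid
nucleotide templates (planar idealized bases with polar hydrogens and a
schematic sugar–phosphate backbone) on a helical lattice with A-form-like
rise 2.81 Å and twist 32.7° per step.  The templates live in
`inst/extdata/aform_templates.csv` (rebuilt by `data-raw/make_templates.R`)
and were constructed so that, by construction,

* every canonical pair satisfies the hydrogen-bond criteria with 3 (G:C)
  or 2 (A:U) near-linear bonds and no spurious contacts,
* consecutive intra-strand bases pass the stacking criteria,
* intra-helical bases have flip pseudo-dihedrals within a couple of
  degrees of zero (the phosphate offset in the residue frame was tuned for
  this).

Bulged (unpaired) residues are placed intra-helically at lattice levels
interpolated between their flanking pairs and displaced radially outward by
`bulge_offset` (default 2 Å) so their hydrogen-bonding edges stay out of
register — the ideal fixtures therefore contain exactly the declared pairs,
which is what makes occupancy and counter tests exact.

`generate_flip_trajectory()` rotates a scheduled nucleobase about its local
P→P backbone axis until the flip pseudo-dihedral equals ±`out_angle`
(default 170°, negative for the major groove); because the dihedral
responds linearly and exactly to that rotation, a schedule is recovered
*exactly* by the classifier at zero jitter.  Thermal noise is isotropic
per-atom Gaussian jitter with no covariance structure — the simplest model
that exercises occupancy statistics.  By default a schedule realizes a
single flip event (the residue leaves and stays out), mimicking the
one-way transitions seen in the study trajectories; explicit per-frame
state vectors are accepted.

What the generator does **not** emulate: force-field energetics, solvent
and ions, backbone connectivity across residues (the backbone is schematic,
placed per residue), sequence-dependent helical parameters, correlated
motions, and partial/intermediate flip states.  Passing tests therefore
demonstrate the correctness of the analysis operators, not the realism of
any particular trajectory.

# Hydrogen bonds and base-pair edges

A hydrogen bond requires donor–acceptor distance ≤ 3.5 Å **and**
acceptor–hydrogen–donor angle ≥ 150°.  Donors are the nucleobase
amine/imine nitrogens plus the ribose O2'; acceptors are the base carbonyl
oxygens and ring nitrogens plus, optionally, the backbone oxygens.
Hydrogens missing from the input are reconstructed at idealized positions
(`place_hydrogens()`): amine hydrogens in the base plane at ±60° off the
exocyclic bond extension, imine hydrogens along the outward ring radial.

Pairs are classified by mapping each bond's base atoms to edges via a fixed
per-base table (Watson-Crick, Hoogsteen, sugar; O2' is always sugar).  The
shipped table follows the Leontis–Westhof convention; since the exact
variant used by trajectory-annotation tools is not standardized, the table
is an argument (`edge_table`) and can be overridden.  Atoms listed under
two edges are *corner* atoms (A:N6, G:O6, G:N2, C:N4, C:O2, U:O4, U:O2); a
pair held by a single bond through a corner atom is reported with the
ambiguous `Edge1*Edge2` type.  With several bonds the residue edge is the
unique edge consistent with all bonded atoms; in the (fixture-free) case of
a genuinely bifurcated pair the majority edge wins, with ties resolved
WC > HG > sugar.  A pair is WC-WC iff both residues interact strictly
through their Watson-Crick edges — canonical identity is not required.
Contacts mediated solely by the backbone never form base-pair records.

Occupancy tables report the fraction of frames per (pair, type); entries at
or below the reporting threshold (default 5%) are suppressed from the
report but kept in the raw table.

# Stacking energetics

Stacked pairs are detected geometrically: six-membered-ring centroid
distance ≤ 4.5 Å and interplanar angle ≤ 30°, excluding pairs linked by
base-mediated hydrogen bonds.  These thresholds are configuration defaults,
documented assumptions rather than a reproduction of any specific
annotation tool.  The stacking energy is the sum of the Coulomb term
(k = 332.0636 kcal Å mol⁻¹ e⁻²) and the 12-6 Lennard-Jones term with
Lorentz–Berthelot-style combining (ε_ij = √(ε_i ε_j), Rmin_ij = Rmin_i/2 +
Rmin_j/2) over the *heavy atoms of the two nucleobases only* — no sugar, no
phosphate, no hydrogens, no cutoff, no solvation or screening corrections.
Totals can therefore legitimately be positive when the single-point-charge
electrostatics dominates.  The shipped parameter CSV carries representative
Amber-94-lineage base charges and Lennard-Jones parameters; it is intended
for the synthetic fixtures and is user-overridable
(`load_ff_params(path)`).  Region summaries attribute each pair's energy
50/50 to its partners, so pairs internal to a region count once in full and
boundary pairs count half.

# Base flipping

The flip pseudo-dihedral is the torsion over four centres of mass: (i) the
flipping nucleobase's heavy atoms, (ii) its phosphate group {P, OP1, OP2},
(iii) the 3'-neighbour's phosphate group, and (iv) the base heavy atoms of
the two reference pairs flanking the analysed nucleotide.  Flanking pairs
are taken from the declared reference structure rather than re-detected per
frame, keeping the angle well defined when neighbours transiently unpair.
Point (iv) uses base heavy atoms of both flanking pairs (the leanest choice
consistent with the definition).  States: `in` for |angle| < 50°, `out` for
|angle| ≥ 140°, `intermediate` between; negative angles face the major
groove.  The 140° out-threshold interpolates between the stated "roughly
(−50°, +50°)" intra-helical range and "close to ±180°" extra-helical pole;
both thresholds are arguments.

# Trajectory metrics

RMSD uses Kabsch superposition (SVD with determinant correction),
mass-unweighted, over all heavy atoms by default ("RNA heavy atoms" without
exclusions; terminal extensions are excludable via `select_atoms()` since
the published selection is not stated).  RMSF superposes frames onto the
average structure with a single refinement pass — standard practice, with
differences from full iteration far below fixture tolerances — and averages
squared deviations over each residue's heavy atoms.  gromos clustering
repeatedly extracts the structure with the most neighbours within the RMSD
cutoff (ties toward the lowest frame index).  Block standard error uses
power-of-two block sizes up to N/4, with BSE(1) = sd/√N; an optional
two-exponential autocorrelation model (`fit_bse_two_exp()`) provides the
analytic curve used to judge whether blocks exceed the correlation time.

# Solution thermodynamics

*Melting.*  The generator and fitter share the exact two-state model:
Ka(T) = exp(−ΔH/RT + ΔS/R), with the duplex fraction obtained from the
numerically stable root f = a / (1 + a + √(1 + 2a)), a = Ka·c₀ (the naive
quadratic root cancels catastrophically at small a).  The fit runs
Levenberg–Marquardt over (ΔH, ΔS, four baseline coefficients) from
data-driven starts: baselines from the first/last 15% of points, Tm from
the normalized-signal half-crossing, and a small ΔH multi-start
(−50…−140 kcal/mol).  Degenerate inputs are flagged rather than fitted: a
curve whose fitted fraction never crosses ½ in range, or whose
folded/unfolded branches are separated at Tm by less than 2% of the
absorbance range (a flat or purely linear curve is otherwise fit perfectly
by two coincident baselines), returns `converged = FALSE`.  Reported Tm
solves f = ½ in closed form; ΔG and TΔS are reported at T_ref = 294.15 K
(21 °C) with R = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹.  Van't Hoff regression of a
fitted curve uses only points with f ∈ [0.15, 0.85] by default — the
baseline-dominated tails carry no information about Ka — and the window is
an argument.  A nonlinear variant with nonzero Δcp is deliberately not
implemented.

*ITC.*  The exact 1:1 model tracks a constant-volume perfusion cell: each
injection displaces its own volume of pre-injection solution, the aliquot
mixes in, and the complex concentration is the physical root of the binding
quadratic with site concentration n·[B].  The defaults mirror the
strand-association scheme (twenty 2 µL injections of 100 µM titrant into
10 µM cell solution at 21 °C); the 190 µL cell volume is the nominal volume
of the low-volume calorimeter class used for such titrations, and is an
argument everywhere.  Dilution heat handling is explicit because both
conventions are defensible: `"subtract"` (default) averages the last three
post-saturation injections and subtracts — faithful to routine practice but
slightly biased when the tail still binds; `"fit"` adds Qdil as a fourth
parameter (exact on synthetic data); a numeric value fixes it; `"none"`
sets it to zero.  If subtract mode finds no plateau (tail range above 5% of
the heat range) it falls back to the free parameter with a warning.  Fits
are Levenberg–Marquardt over (ln Ka, ΔH, ln n) with a Ka multi-start over
10⁵–10⁸ M⁻¹; `ΔG = −RT ln Ka` and `TΔS = ΔH − ΔG` hold to machine
precision by construction.

# Problem sizes and limitations

The test fixtures use the full 44-residue constructs (~1100 atoms) with
4–25 frames for structural tests, 4096–16384-point series for the
block-averaging closed forms, and the titration/melting schemes above; the
whole suite runs in about a minute on one CPU.  Known limitations: the
schematic backbone precludes backbone-torsion analyses; base-pair edge
tables are a documented convention, not a reproduction of any specific
annotation tool; stacking detection thresholds are assumptions; the ITC
model assumes a single class of independent sites; and synthetic fixtures
exercise correctness, not conformational realism.
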