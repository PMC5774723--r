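# asitetools

Thermodynamic and structural analysis of bipartite RNA models of the 16S
rRNA decoding A-site (helix 44) and of their complexes with 2'-O-methylated
antisense oligoribonucleotides.

## The scientific problem

The decoding site of the small ribosomal subunit hosts two overlapping
aminoglycoside binding pockets (the paromomycin/kanamycin pocket with the
flexible adenines A1492/A1493, and the neighbouring hygromycin B pocket
around U1498).  Short 2'-O-Me RNA decamers complementary to the prokaryotic
sequence are candidate antimicrobials, provided they discriminate against
the eukaryotic counterpart, from which they differ by one to three
mismatches.  Assessing that selectivity combines two workflows:

* **Solution thermodynamics.**  UV melting curves are fitted to a two-state
  duplex model with sloping baselines.  The duplex fraction *f*(*T*) obeys
  the mass-action law for a non-self-complementary duplex at equal strand
  concentrations *c*₀,

      Ka = 2 f / ((1 - f)^2 c0),

  van't Hoff analysis `ln Ka = -ΔH/R · 1/T + ΔS/R` yields ΔH and ΔS, the
  melting temperature is defined by *f*(*T*ₘ) = ½, and ITC titrations are
  fitted with the exact 1:1 binding isotherm, linked to the melting results
  through `ΔG = -RT ln Ka = ΔH - TΔS` at *T* = 21 °C (294.15 K).

* **Trajectory structure.**  Multi-model PDB trajectories are analysed for
  superposition RMSD and per-residue RMSF, hydrogen bonds (donor–acceptor
  ≤ 3.5 Å, acceptor–H–donor ≥ 150°), base pairs classified by
  hydrogen-bonding edge (Watson-Crick / Hoogsteen / sugar, with the
  corner-atom `Edge1*Edge2` convention for single-bond pairs), nucleobase
  stacking energies (Coulomb + Lennard-Jones over base heavy atoms),
  base-flip pseudo-dihedral angles (flipped-in ≈ 0°, flipped-out ≈ ±180°,
  negative toward the major groove), gromos RMSD clustering and
  block-standard-error convergence curves.

Because microsecond explicit-solvent trajectories and calorimeter output
are not portable test fixtures, the package ships seeded generators that
emulate them: an idealized A-form duplex builder whose reference pairs
satisfy the hydrogen-bond criteria by construction, scheduled base flips
with Gaussian thermal jitter, exact two-state melting curves and exact 1:1
ITC isotherms.  Every analysis stage is validated against these generators
and against independent brute-force oracles.

## Worked example

```r
library(asitetools)

reg <- build_registry()
count_mismatches(reg$oligo_1489, reg$euk_B)
#> <mismatch_report> oligo_1489 vs euk_B: 3 mismatch(es), best window start 6
ecoli_label(reg$prok_B, 10)
#> [1] "A1493"

## melting: generate a noiseless curve at the prokaryotic duplex parameters
## (dH in kcal/mol, TdS at 294.15 K, 2 uM per strand) and refit it
fit <- fit_two_state(generate_melting_curve(
  melt_sim_params(dH = -99.8, TdS = -81.5, c0 = 2e-6)))
fit
#> <melt_fit> dH -99.8  TdS(294.15 K) -81.5  dG -18.3 kcal/mol  Tm 53.1 C

## ITC: the strand-association scheme (20 x 2 uL of 100 uM into 10 uM)
fit_itc(generate_itc_series(itc_sim_params(ka = 1.14e7, dH = -76, n = 0.85)),
        qdil = "none")
#> <itc_fit> Ka 1.14e+07 1/M  dH -76.0  TdS -66.5  dG -9.5 kcal/mol  n 0.85

## trajectory: a uridine that leaves the helix through the major groove in
## 40% of frames is recovered exactly by the flip classifier
tr <- generate_flip_trajectory(reg$prokaryotic,
        list(flip_schedule("U1498", fraction_out = 0.4, groove = "major")),
        jitter_sd = 0, nframes = 10, seed = 1)
attr(classify_flip(pseudo_dihedral(tr, "U1498")), "fractions")
#>   in intermediate          out
#>  0.6          0.0          0.4
```

The interpretation: the fitted ΔG of −18.3 kcal/mol at 21 °C and the
melting temperature of ~53 °C characterize the prokaryotic duplex; the ITC
fit returns the association constant on the 10⁷ M⁻¹ scale and a
stoichiometry near 0.85–0.9, confirming 1:1 duplex formation; the flip
fractions report how often a nucleobase is extra-helical and which groove
it faces.

Full workflows (`run_trajectory_pipeline()`, `run_thermo_pipeline()`)
write CSV/JSON report bundles from a validated `run_config()`.

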