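# ldhtraj

Trajectory analysis for hybrid layered double hydroxides (LDHs) that
intercalate dicarboxylate anions — succinate, L-aspartate, L-glutamate —
with interlayer water, stoichiometry `[Mg4Al2(OH)12]A²⁻ · X H2O`.

These materials respond to hydration by re-organising their galleries:
anions reorient relative to the sheets, explore anti/gauche backbone
conformers, and the carboxylate stretch band changes shape.  The package
implements the full post-processing chain used to follow that response in
molecular-dynamics trajectories, for R users who would otherwise script it
ad hoc:

* **Infrared spectra from dipole dynamics.**  The absorption intensity is
  proportional to the Fourier transform of the dipole time-correlation
  function, `I(ω) ∝ ∫ dt e^{-iωt} ⟨μ(0)·μ(t)⟩`, with
  `μ = Σ qᵢ (rᵢ − r_com)` per anion.  The transform is estimated by the
  maximum entropy method (Burg autoregressive fit), spectra are averaged
  over anions, and the symmetric/antisymmetric carboxylate stretch maxima
  (near 1400 and 1600 cm⁻¹) and their **band gap** `Δν = ν_AS − ν_S` are
  extracted.  A constant `−200 cm⁻¹` shift can be applied for comparison
  with experiment; the gap is invariant under it.
* **Orientational states.**  θ is the angle between the vector joining the
  two carboxylate carbons and the layer normal; an anion is *parallel* when
  θ > 80.0° (strict), intermediate/perpendicular otherwise, and populations
  are reported in percent.
* **Conformers.**  The classifying torsion (C–C–C–C in succinate,
  C–Cα–Cβ–Cγ in the amino acids) is binned into anti (|χ| > 120°) and
  gauche± wells.
* **Spatial structure.**  Number densities along the stacking axis,
  per-interlayer and midplane-referenced, and radial distribution functions
  restricted to ≲ 5 Å (one interlamellar spacing), where spherical
  normalization is still meaningful in a slab.
* **Synthetic trajectories.**  A stoichiometric slab generator with presets
  for the standard hydration states of all three anions produces
  trajectories with prescribed orientation/conformer populations,
  carboxylate stretch modes at prescribed frequencies, and water placed in
  carboxylate hydration shells or at the gallery centre — so every
  estimator is testable against ground truth without an MD engine.

Trajectories are read/written as XYZ (box and time in the comment line),
PDB (CRYST1 + MODEL blocks) and DCD; topologies (elements, charges,
molecule membership, atom roles, per-anion index records) are YAML.

## Worked example

```r
library(ldhtraj)

rc  <- run_config(preset = "ASP_6.5_WAT", n_frames = 4096, seed = 11)
rep <- run_pipeline(rc)
rep
#> <ldh_report> ASP_6.5_WAT
#>   band gap: 200 cm^-1 (nu_S 1196, nu_AS 1396, shift -200)
#>   parallel orientation: 37.54%
#>   conformers: anti 55.91%, g+ 0%, g- 44.09%
```

The report says: for the highest-hydration aspartate system (X = 6.5 waters
per anion, spacing 12.10 Å), the computed S/AS carboxylate band gap is
200 cm⁻¹ (band positions quoted after the −200 cm⁻¹ shift); 38% of
(frame × anion) samples are parallel to the sheets; and the backbone is
56% anti / 44% gauche−, the single gauche well sterically available to
aspartate.  `write_report(rep, "out/")` serialises the tables, the averaged
spectrum, density profiles and RDFs as headed TSV files.

Hydration trends across systems:

```r
tab <- compare_systems(list(
  run_pipeline(run_config(preset = "SUC_0_WAT",   n_frames = 4096, seed = 11)),
  run_pipeline(run_config(preset = "SUC_2_WAT",   n_frames = 4096, seed = 11)),
  run_pipeline(run_config(preset = "SUC_6.5_WAT", n_frames = 4096, seed = 11))))
tab[, c("system", "X", "gap", "gap_non_increasing")]
#>        system   X gap gap_non_increasing
#> 1   SUC_0_WAT 0.0 256               TRUE
#> 2   SUC_2_WAT 2.0 216               TRUE
#> 3 SUC_6.5_WAT 6.5 204               TRUE
```

The succinate band gap narrows as water enters the gallery — the strongest
hydration response of the three anions — and the trend flag confirms it is
monotone.  A thin command-line front end over the same functions ships in
`inst/scripts/ldhtraj-cli.R`.

The methods vignette (`vignettes/ldh-interlayer-analysis.Rmd`) documents the
spectral model, the descriptor conventions, every generator parameter with
units and defaults, and the generator's limitations.

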