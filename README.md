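# memprofiler

Quantitative analyses of how a transmembrane lipid-saturation sensor reads
its bilayer environment. The guiding hypothesis is that such a sensor (the
archetype being the yeast protein Mga2, whose sensory tryptophan sits
roughly 3–10 Å from the bilayer midplane) responds to **local lipid-packing
density** — the number density of lipid atoms in the shell around the
sensory residue — rather than to bulk membrane fluidity.

The package provides:

* **Density maps** — voxelized lipid-atom number density from bilayer
  trajectories, composition difference maps, depth profiles, and the
  3–10 Å sensor-band statistic (`voxel_density`, `difference_map`,
  `band_statistic`).
* **Bilayer descriptors** — area per lipid, thickness, and acyl-chain
  order parameters S = ⟨(3cos²θ − 1)/2⟩ (`area_per_lipid`, `thickness`,
  `order_parameters`).
* **TMH dimer rotamers** — per-frame sensor azimuths, classification into
  facing-facing / mixed / away-away states, and bootstrap population
  estimates (`analyze_dimer`, `state_populations`).
* **Spectroscopy reductions** — C-Laurdan generalized polarization
  GP = (I₄₀₀₋₄₆₀ − I₄₇₀₋₅₃₀)/(I₄₀₀₋₄₆₀ + I₄₇₀₋₅₃₀); ratiometric FRET
  E_rel = I_A/(I_D + I_A); FCS fitting of the 2D-diffusion-with-triplet
  model with D = w²/(4τ_D); and a cwEPR line-height proximity index
  (`gp`, `fret_erel`, `fit_fcs`, `epr_proximity_index`).
* **Liposome chain molarity** — the effective molar concentration of
  unsaturated acyl chains inside a vesicle membrane
  (`unsaturated_chain_molarity`).
* **Seeded synthetic generators** for every input (`generate_bilayer`,
  `generate_dimer`, `generate_emission_spectrum`, `generate_fcs_curve`,
  `generate_epr_spectrum`), so the whole pipeline runs with known ground
  truth and no external data.

## Worked example

Compare the sensor-band packing of a saturated-analog bilayer against a
cis-unsaturated-analog reference, then reduce a two-band emission spectrum
to GP and a liposome composition to its chain molarity:

```r
library(memprofiler)

spec_cis <- bilayer_gen_spec(25, fraction_kinked_chains = 1, seed = 1)
spec_sat <- bilayer_gen_spec(25, fraction_kinked_chains = 0, seed = 2)
m_cis <- voxel_density(center_and_wrap(generate_bilayer(spec_cis, n_frames = 2, label = "cis")))
m_sat <- voxel_density(center_and_wrap(generate_bilayer(spec_sat, n_frames = 2, label = "sat")))
m_sat
#> density_map: 40 x 40 x 58 voxels of 1 A, 2 frame(s), label: sat

d <- difference_map(m_sat, m_cis)
band_statistic(d)$mean          # straight chains pack the band more densely
#> [1] 0.00921875

s <- generate_emission_spectrum(list(c(430, 12, 1), c(500, 14, 0.6)),
                                noise_sd = 0.005, seed = 7)
gp(s)
#> [1] 0.1874837

popc <- data.frame(species = "POPC", mol_fraction = 1, chains = 2,
                   unsat_chains = 1)
unsaturated_chain_molarity(liposome_spec(composition = popc))
#> [1] 1.277692
```

Rotamer-state populations of a synthetic TMH dimer are recovered from the
classified frames:

```r
d2 <- generate_dimer(dimer_gen_spec(c(0.5, 0.3, 0.2), n_frames = 2000, seed = 9))
state_populations(analyze_dimer(d2), n_boot = 200, seed = 1)
#>           state fraction     ci_lo     ci_hi
#> 1 facing-facing    0.498 0.4784875 0.5215125
#> 2         mixed    0.314 0.2934875 0.3325250
#> 3     away-away    0.188 0.1710000 0.2055125
```

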