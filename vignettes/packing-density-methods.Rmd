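---
title: "Methods: profiling local lipid-packing density around a membrane sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling local lipid-packing density around a membrane sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(memprofiler)
```

## The scientific question

Transmembrane sensors of lipid saturation, such as the yeast protein Mga2,
must extract a physical signal from the surrounding bilayer. A long-standing
candidate was bulk membrane fluidity; the alternative this package is built
around is *local lipid-packing density*: the number density of lipid atoms in
the shell of hydrophobic core that surrounds a sensory residue (a tryptophan
roughly 3–10 Å from the bilayer midplane). `memprofiler` provides the
quantitative reductions needed to test that hypothesis end to end:

1. voxelized lipid-atom density maps and composition difference maps from
   bilayer trajectories, with a band statistic over the sensor region;
2. standard bilayer descriptors (area per lipid, thickness, acyl-chain order
   parameters);
3. rotational-state populations of a transmembrane-helix (TMH) dimer whose
   sensory residues can face each other or turn away;
4. spectroscopy reductions — C-Laurdan generalized polarization (GP),
   ratiometric FRET, FCS autocorrelation fitting, and a cwEPR line-height
   proximity index;
5. the effective molarity of unsaturated acyl chains inside a liposome
   membrane.

Every input has a seeded synthetic generator, so the full pipeline is
testable without external trajectories or spectra.

## Density maps and the sensor band

`voxel_density()` bins the atoms of every frame into cubic voxels (default
1 Å edge, half-open intervals, box-anchored grid) and averages counts over
frames, normalized to atoms/Å³. Trajectories are first passed through
`center_and_wrap()`, which defines the midplane as the mean of the two
per-leaflet mean headgroup heights and moves it to $z = 0$, so "distance
from the bilayer center" is well defined.

`difference_map()` subtracts two maps voxel-wise after cropping to the
common grid, and `band_statistic()` averages the (signed) density over all
voxels whose centers satisfy $3 \le |z| \le 10$ Å — the sensor band. The
central claim translated into this machinery: replacing kinked
(cis-unsaturated-analog) chains with straight (saturated-analog) chains
*increases* the band density, while a headgroup change (PC to PE analog)
produces a smaller band difference that is spread across all depths rather
than concentrated in the band.

```{r density}
mk <- function(frac, hg = 8, apl = 64, seed) {
  spec <- bilayer_gen_spec(25, fraction_kinked_chains = frac,
                           headgroup_atom_count = hg,
                           area_per_lipid = apl, seed = seed)
  voxel_density(center_and_wrap(generate_bilayer(spec, n_frames = 2)))
}
m_cis <- mk(1, seed = 1)
m_sat <- mk(0, seed = 2)
band_statistic(difference_map(m_sat, m_cis))$mean   # positive
```

## The synthetic bilayer generator

`generate_bilayer()` builds jointed segment-stick lipids on a square
lattice sized from the requested area per lipid, mirrors the lower leaflet
exactly, and adds per-frame Gaussian thermal noise. The geometry constants
(headgroup at 18.5 Å, glycerol at 17.2 Å, chains starting at 16 Å with a
1.27 Å per-segment rise over 12 segments) place a straight chain's segments
throughout the 3–10 Å band.

The kink deserves a note. Kinked ("cis-analog") chains bend by 70° at
segment 4. With this angle the kinked tail still descends into the band but
deposits fewer segments there, so (a) the straight-vs-kinked band ordering
holds by construction, and (b) the cis-analog band density stays nonzero —
which matters because the PE-analog comparison needs a strictly positive
but *small* band difference against the same reference. These defaults are
the study conditions; they were chosen from the geometry, not fit to any
result.

The generator is a geometric caricature of a bilayer, not a force field:
there are no excluded-volume interactions, no lateral diffusion, and the
two leaflets are mirror images up to noise. It exists to give the analysis
functions inputs with known ground truth.

## Bilayer descriptors

`order_parameters()` computes the segmental order parameter
$S = \langle (3\cos^2\theta - 1)/2 \rangle$ against the bilayer normal,
with either the segment convention (vector from atom $i-1$ to $i+1$) or the
bond convention. Closed forms anchor the tests: chains along the normal
give $S = 1$, chains perpendicular give $S = -1/2$, and isotropic vectors
give $S = 0$.

## TMH dimer rotamers

`analyze_dimer()` fits each helix axis by SVD, computes the signed azimuth
of the sensory residue about its own axis relative to the inter-helix
connector, and classifies each frame: both sensors within 60° of facing is
*facing-facing*, both beyond 120° is *away-away*, anything else *mixed*.
Frames where the two axes cross by more than 45° are flagged rather than
classified. `state_populations()` adds percentile-bootstrap confidence
intervals.

The generator draws one dimer state per frame and places both protomers'
azimuths around that state's center (the second protomer mirrored). This
per-frame-state design is what makes "recover the state weights from the
classified frames" a well-posed exercise; independent per-protomer sampling
would not reproduce the weights as state populations.

## Spectroscopy reductions

* **GP**: $\mathrm{GP} = (I_{400\text{–}460} - I_{470\text{–}530}) /
  (I_{400\text{–}460} + I_{470\text{–}530})$ with trapezoidal band
  integrals; bounded in $[-1, 1]$ and attaining the bounds for spectra
  confined to one channel.
* **FRET**: $E_\mathrm{rel} = I_A / (I_D + I_A)$ read at 525 and 614 nm
  after `acceptor_normalize()` cancels the reconstitution yield.
* **FCS**: the 2D-diffusion-with-triplet model
  $G(\tau) = \left(1 + \frac{T}{1-T} e^{-\tau/\tau_T}\right) \frac{1}{N}
  \left(1 + \tau/\tau_D\right)^{-1}$, with
  $D = w^2 / (4\tau_D)$. Fitting uses `stats::nls` with the bounded `port`
  algorithm: the Gauss–Newton default rejects this model's
  well-conditioned-but-skewed Jacobian on noise-free curves, while `port`
  recovers noise-free parameters exactly and pins $T$ at its zero bound
  when no triplet is present (`t_pinned`). Failures return a flagged
  `fcs_fit` with `converged = FALSE` instead of an error.
* **cwEPR**: the proximity index is the low-field/mid-field line-height
  ratio. The mid-field line is identified as the tallest derivative peak
  and the low-field line as the first peak before it; dipolar broadening in
  the generator widens the outer lines and reduces their amplitude, so the
  index decreases monotonically with broadening.

## Liposome chain molarity

`unsaturated_chain_molarity()` treats the membrane of a vesicle as the
solvent volume for its own acyl chains: lipid count from the two leaflet
areas divided by the area per lipid, membrane volume from the spherical
shell, chains weighted by the composition's unsaturated-chain counts. For a
200 nm liposome (4 nm membrane, 0.65 nm² per lipid) this gives ~370,000
lipids in ~4.8×10⁻¹⁹ L, hence ~1.3 M unsaturated chains for pure POPC and
~1.9 M for 1:1 DOPC:POPC:

```{r liposome}
popc <- data.frame(species = "POPC", mol_fraction = 1, chains = 2,
                   unsat_chains = 1)
unsaturated_chain_molarity(liposome_spec(composition = popc))
```

## Problem sizes and limitations

The shipped analyses use small study sizes: bilayers of 25–49 lipids per
leaflet over 2–4 frames, dimers of 2,000–10,000 frames, 120-point FCS
curves. These are large enough for every statistical claim tested (binomial
standard errors, bootstrap CIs) while keeping the full suite fast.

Limitations to keep in mind when pointing these functions at real data:
the density machinery assumes an orthorhombic box and a planar bilayer
normal to $z$; the rotamer analysis assumes two mostly parallel, mostly
straight helices; the FCS model is single-component 2D diffusion; and the
synthetic generators trade physical realism for analytic ground truth.
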