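---
title: "Simulating fiducial-marker visibility and artifact across radiotherapy imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fiducial-marker visibility and artifact across radiotherapy imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Implanted fiducial markers serve as surrogates for tumour position during
image-guided radiotherapy (IGRT). A useful marker must be conspicuous on the
verification images (planar kV, planar MV, cone-beam CT, helical MV CT) yet
produce little artifact on the planning CT, where streaks can corrupt both
contouring and dose calculation. The three materials in clinical use pull in
opposite directions: gold (Z = 79) is bright everywhere but streaks badly on
kV CT; carbon and radiopacified polymer are nearly artifact-free but fade as
the beam energy climbs into the Compton-dominated megavoltage range.

fidviz simulates a uniform soft-tissue phantom with embedded cylindrical
markers of all three materials under each of these modalities, and scores
every image with two statistics:

* **Contrast-to-noise ratio.** For a square profile around each marker,
  \( \mathrm{CNR} = (S_{\max} - \bar S_{bg}) / \sigma_{bg} \), where
  \(S_{\max}\) is the maximum intensity in the profile (the most visible
  part of the marker) and the background mean and SD are computed over
  profile pixels outside a 7.5 mm exclusion disk. The statistic is invariant
  under affine intensity maps, so HU and raw reconstruction values give the
  same number.
* **Ring artifact profile.** The SD of bilinearly interpolated pixel values
  along 1000 rings of radius 1 to 15 mm around the marker; its mean (the
  *artifact index*) summarises the streak burden.

Because \(S_{\max}\) is a maximum over many pixels, a marker-free profile
already yields a CNR near the expected maximum of the noise field
(about 3-4 for the profile sizes used here). The Rose visibility threshold
of 4 should be read against that floor.

## Physics model

### Attenuation

Each material is described by an effective atomic number \(Z_{\mathrm{eff}}\),
mass density \(\rho\), and electron density
\(n_e = \rho N_A (Z/A)\). The linear attenuation coefficient is the two-term
model

\[ \mu(E) = n_e\,\sigma_{KN}(E) + k_{pe}\, n_e\, Z_{\mathrm{eff}}^3 / E^3 , \]

a Klein-Nishina Compton term proportional to electron density plus a
photoelectric term with the textbook \(Z^3/E^3\) scaling (exponents kept at
exactly 3; the 3.2-3.8 refinements matter for absolute dosimetry, not for
the trend directions this package studies). The scale \(k_{pe}\) is
calibrated once so that soft tissue's photoelectric and Compton terms are
equal at 26 keV, which places the crossover where diagnostic-energy tissue
behaves. This model reproduces the two facts all the observed contrast
trends rest on: gold's photoelectric fraction exceeds tissue's at every
diagnostic energy while decaying as \(E^{-3}\), and the low-Z markers'
contrast over tissue is mostly a density (Compton) effect.

Default material constants (all overridable through `material_table()` or a
YAML config):

| material | \(Z_{\mathrm{eff}}\) | \(\rho\) (g/cm³) | Z/A | note |
|---|---|---|---|---|
| gold | 79 | 19.3 | 0.401 | elemental |
| carbon | 6 | 2.2 | 0.500 | pyrolytic carbon |
| polymer | 8.5 | 1.50 | 0.52 | radiopacified polymer |
| soft_tissue | 7.4 | 1.00 | 0.55 | water-equivalent bolus |
| air | 7.64 | 0.0012 | 0.499 | |

The marker vendors do not publish compositions, so the carbon and polymer
rows encode what the devices physically are rather than their generic
namesakes: clinical carbon fiducials are dense pyrolytic carbon, and a plain
\(\rho \approx 1.2\) polymer would be invisible on a kV radiograph of 15 cm
of tissue — commercial "polymer" markers carry a higher-Z filler, which is
also what gives them (and carbon, whose \(n_e Z^3\) exceeds tissue's at
\(\rho = 2.2\)) the observed gentle *decline* of CT contrast with kVp.

### Spectra and beams

Kilovoltage tubes use a Kramers bremsstrahlung shape, \((\mathrm{kVp} -
E)/E\) per 1 keV bin above a 10 keV cutoff, hardened by 2.5 mm of
aluminum-equivalent filtration and renormalised. Characteristic lines are
omitted: they move effective energies by a keV or two without touching any
trend direction. Megavoltage beams are monoenergetic at a configurable
effective energy (2 MeV planar, 1 MeV helical MV CT) with Compton-only
contrast, which is the textbook account of why only density differences
survive MV imaging.

### Image formation

All 3D modalities use parallel-beam geometry, 360 views over 180 degrees in
the presets, with Beer-Lambert transmission evaluated per spectrum bin and
an energy-integrating detector. The chain keeps exactly the nonlinearities
the study's artifact results hinge on:

* **Beam hardening.** Projections are \(-\ln\) of polychromatic
  transmission. A water-equivalent precorrection (the measured value mapped
  through the background material's transmission curve to its monochromatic
  equivalent at the spectrum's effective energy) makes the uniform phantom
  reconstruct flat, as clinical water corrections do; gold violates the
  water assumption, and the residual inconsistency is what streaks.
* **Photon starvation.** Detected counts are floored at half a photon, so
  rays through gold saturate — the dominant source of kV-CT gold streaks at
  low kVp and the reason the gold signal stops growing with contrast.
* **Partial volume.** Each slice averages detector fluence over sub-slice
  samples (0.1 mm steps, odd count, capped at 51) across the slice
  thickness before the log, so a 3 mm marker dilutes once slices grow past
  its length.
* **Quantum noise.** Poisson counts per detector bin, drawn by inversion of
  a seeded uniform stream.

Reconstruction is filtered back-projection with a band-limited Ram-Lak
kernel assembled in the spatial domain (a pure \(|f|\) frequency ramp loses
the DC term and biases a 30 cm object's interior by several percent),
linear interpolation, and per-marker region-of-interest grids: each marker
is reconstructed on its own 128 x 128 grid of 0.25 mm pixels from the full
sinogram, which is what lets the default suite run on one CPU in minutes.

Planar radiographs project along the phantom's z axis with analytic
line-cylinder path lengths, 3 x 3 sub-pixel sampling, and the same Poisson
model; pixels store \(-\ln\) detected fraction so markers are the bright
feature, matching the inverted display convention under which the maximum-
based CNR makes sense. CBCT is CT with a flat additive scatter fraction
(default 20%) and a lower count budget.

## The synthetic study and its conditions

`default_phantom()` builds the study geometry: a 30 x 31 x 15 cm³
soft-tissue block of 2 cm layers with three markers per material (gold
0.9 x 3 mm, carbon 1 x 3 mm, polymer 1 x 5 mm) on a 3 x 3 grid, 5 cm apart,
in the central plane. Marker axes point along z, the scan axis: implanted
markers lie roughly along the patient axis, and this orientation is also
what produces the observed slice-thickness behaviour — the marker fills
every slice up to its 3 mm length (so thicker slices win through their
lower noise) and dilutes beyond it (so the gold curve turns over at an
interior thickness).

Exposure follows what the clinical devices do rather than a single global
constant:

* Planar kV: incident budget of 6e5 counts/pixel at 200 mAs, linear in mAs.
* Planar MV: 22,000 counts/pixel per MU — calibrated once so that gold
  clears the Rose threshold at 1 and 2 MU (CNR ~ 6-9, bracketing the
  reported portal-image operating point) while carbon and polymer stay
  below it.
* CT/CBCT: an auto-exposure model holds the *detected* budget behind the
  phantom at a reference (800 counts/ray for CT at 2.5 mm; the scanners the
  study protocols come from run noise-targeted auto-mA, and no CT mAs is
  part of the protocol set), scaled with the square root of slice
  thickness — thin-slice protocols boost tube current to partially offset
  fluence loss. Protocols given an explicit mAs instead use 1e5 counts/ray
  at 200 mAs and 2.5 mm, scaled by both.
* MV CT: per-mode detected budgets (fine 660, normal 750 counts/ray)
  calibrated to the reported fine/normal gold CNR operating points of
  roughly 23 and 18; the normal mode's thicker slice loses more gold signal
  to partial volume than its coarser pitch costs in fluence, which is why
  the two effective budgets come out similar.

These budgets are the model's free constants: detector response is not
publishable physics, so they are pinned to reported modality-level
operating points and then frozen. Everything the package is judged on —
the *directions* and *shapes* of the CNR trends with kVp, mAs and slice
thickness, the visibility split between materials, the artifact ordering —
is emergent from the attenuation physics above, not calibrated.

## Sweeps, seeds, and common random numbers

`run_sweep()` simulates a grid of protocol values with `n_realizations`
noise repeats (default 5), locates every marker
(`detect_marker_center()`), and aggregates CNR per material;
`sweep_preset()` bundles the study's parameter grids. Two design choices
matter for interpreting its output:

* **Material isolation.** Each material is simulated in its own copy of the
  phantom. Gold streaks reach several centimetres at low kVp, and with all
  nine markers in one slice they contaminate the carbon and polymer
  background SD with gold's (strongly kVp-dependent) artifact. Isolation
  keeps each material's trend its own; `isolate_materials = FALSE` restores
  the all-in-one acquisition.
* **Common random numbers.** Child seeds depend on the base seed, the
  realization index and the material set — *not* on the grid value — and
  Poisson noise is drawn by inversion of the shared uniform stream. Grid
  cells of one realization therefore share their noise field, and
  estimated slopes difference the quantum noise out instead of being buried
  in it: the small negative kVp slope of carbon CNR, for example, is
  reproduced with the correct sign in every realization rather than in
  ~90% of seeds. CRN sharpens trend estimates without biasing any
  individual cell.

Re-running any sweep with the same base seed reproduces every number
exactly; all seeds are recorded in the sample table and the report
manifest.

## Worked example

```{r example}
library(fidviz)

sw <- sweep_preset("ct-kvp", base_seed = 1, n_realizations = 5)
glance(sw)
trend_summary(sw)
autoplot(sw)

ph <- default_phantom()
pr <- imaging_protocol("ct", kvp = 120, slice_thickness_mm = 1.25,
                       n_views = 360, detector_bin_mm = 0.5, seed = 1)
rings <- marker_artifact_profiles(ph, pr)   # noise-free artifact curves
```

## Numerical choices

* Sample SD (n - 1) everywhere.
* Ring radii include both endpoints: spacing \((r_{\max} - r_{\min}) /
  (n_{\mathrm{rings}} - 1)\); 720 angular samples (0.5 degrees) per ring;
  samples leaving the image raise an error rather than pad.
* The 15 x 15 cm CNR profile is clipped to each marker's sub-image (32 mm
  in the presets); profiles overlapping a neighbouring marker would
  otherwise report that marker's peak as their own.
* Tie-breaks in `trend_summary()` go to the smaller parameter value.
* Detector bins 0.5 mm with 0.25 mm reconstruction pixels in the presets;
  the 0.9 mm gold marker stays resolved while halving projection cost.
* Voxelization labels a voxel by its center; `voxelize()` refuses grids
  coarser than half the smallest marker diameter.
* Starved rays are floored at 0.5 detected counts both with and without
  noise, so noise-free artifact studies see the same saturation geometry.

## What the synthetic data does and does not show

The generator reproduces the mechanisms — photoelectric-vs-Compton energy
dependence, beam hardening against a monochromatic reconstruction
assumption, photon starvation, partial volume, Poisson statistics — on an
idealised platform: parallel beams, no detector lag or glare, no focal-spot
blur, no anatomy, vendor-free exposure models, monoenergetic MV beams. A
passing suite therefore says the package's statistics and trend directions
are faithful to that physics; it does not certify absolute CNR or HU values
for any particular scanner, and the paper-reported absolute numbers on
vendor hardware are expected to differ. Bone- or lung-adjacent markers,
anatomical phantoms, and metal-artifact-reduction reconstructions are out
of scope.
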