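# fidviz

Simulation and image-quality analysis of gold, carbon, and polymer fiducial
markers across the imaging modalities used in image-guided radiotherapy
(IGRT): kV CT, planar kV, kV cone-beam CT, planar MV, and helical MV CT.

Fiducial markers implanted in or near a tumour act as position surrogates
during treatment. Choosing the marker material is a trade-off: high-Z gold
is visible on every modality but streaks badly on the planning CT, while
carbon and polymer markers are artifact-free but can vanish on megavoltage
images. fidviz reproduces this trade-off mechanistically on a synthetic
phantom, so the dependence of marker visibility and artifact on technique
factors (kVp, mAs, slice thickness, modality) can be studied quantitatively
without scanner time. It is aimed at medical-physics researchers and at
clinics that want a desk-scale version of a marker-selection study before
committing to measurements.

## The model in brief

* Linear attenuation: `mu(E) = n_e * sigma_KN(E) + k_pe * n_e * Z_eff^3 / E^3`
  — Klein-Nishina Compton scattering plus a `Z^3/E^3` photoelectric term,
  with `k_pe` calibrated so soft tissue's two terms balance at 26 keV.
* Kilovoltage tube spectra: Kramers bremsstrahlung hardened by
  aluminum-equivalent filtration; megavoltage beams monoenergetic,
  Compton-only.
* Image formation: polychromatic Beer-Lambert forward projection,
  parallel-beam filtered back-projection with a water beam-hardening
  precorrection, sub-slice partial-volume averaging, a photon-starvation
  floor, and seeded Poisson noise. Beam hardening, streaks, and quantum
  mottle emerge from the physics rather than being painted on.
* Metrics: per-marker contrast-to-noise ratio
  `CNR = (S_max - mean(S_bg)) / sd(S_bg)` on a square profile, and the SD of
  pixel values along 1000 rings of radius 1-15 mm around each marker
  (artifact profile).

The methods vignette (`vignettes/fiducial-marker-visibility.Rmd`) documents
every model assumption, parameter, and calibration constant.

## Worked example

```r
library(fidviz)

# CT contrast-to-noise ratio of each marker material vs tube voltage,
# 5 noise realizations per grid point
sw <- sweep_preset("ct-kvp", base_seed = 1, n_realizations = 5)
sw$summary
#> # A tibble: 12 × 5
#>    material value mean_cnr sd_cnr     n
#>    <chr>    <dbl>    <dbl>  <dbl> <int>
#>  1 carbon      80     5.01  0.709    15
#>  2 carbon     100     5.01  0.697    15
#>  3 carbon     120     5.01  0.689    15
#>  4 carbon     140     4.99  0.686    15
#>  5 gold        80   283.    4.22     15
#>  6 gold       100   400.   30.7      15
#>  7 gold       120   417.   17.0      15
#>  8 gold       140   448.   12.0      15
#>  9 polymer     80     4.12  0.452    15
#> 10 polymer    100     4.09  0.421    15
#> 11 polymer    120     4.08  0.414    15
#> 12 polymer    140     4.07  0.403    15

trend_summary(sw)
autoplot(sw)          # trend curves with 1-SD ribbons
```

Gold's CNR rises steeply with kVp (its photoelectric contrast survives
while its streak artifact — which dominates the background SD — fades),
whereas carbon and polymer decline gently: their `n_e * Z^3` photoelectric
surplus over tissue decays as the beam hardens. The same pipeline drives
slice-thickness and mAs sweeps, MV visibility reports
(`visibility_report()`, Rose criterion: only gold passes on planar MV), and
noise-free ring-artifact comparisons (`marker_artifact_profiles()`: gold's
kV-CT artifact index is hundreds of HU against ~1 HU for carbon and
polymer, and collapses by ~98% on MV CT).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/fidviz simulate --modality ct --kvp 120 --slice 1.25 \
    --seed 7 --out slice.nii.gz
Rscript inst/cli/fidviz analyze --image slice.nii.gz --centers centers.csv
Rscript inst/cli/fidviz sweep --preset obi-kvp --seed 1 --out-dir out/
```

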