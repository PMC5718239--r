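Package: fidviz
Title: Visibility and Artifact Analysis of Fiducial Markers Across
    Radiotherapy Imaging Modalities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates kilovoltage and megavoltage imaging (CT, cone-beam CT,
    planar radiographs, megavoltage CT) of gold, carbon, and polymer fiducial
    markers embedded in a uniform soft-tissue phantom, and quantifies marker
    visibility and artifact. The physics core couples a two-term linear
    attenuation model (Klein-Nishina Compton scattering plus a Z^3/E^3
    photoelectric term) with polychromatic bremsstrahlung spectra, Beer-Lambert
    forward projection, and filtered back-projection, so that beam hardening,
    photon starvation, partial volume, and quantum noise emerge mechanistically.
    Image quality is assessed with the contrast-to-noise ratio of each marker
    and with the standard deviation of pixel values along rings of increasing
    radius around it; sweep drivers reproduce the dependence of both statistics
    on kVp, mAs, and slice thickness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
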