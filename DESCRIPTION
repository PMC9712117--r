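Package: varveSST
Title: Annual and Seasonal Sea Surface Temperature Reconstruction from
    Mass Spectrometry Imaging of Varved Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct annually resolved sea surface temperature
    (SST) from laser-spot alkenone intensities obtained by mass spectrometry
    imaging (MSI) of laminated (varved) marine sediments.  Implements the
    U37K' unsaturation index with spot-level quality control and annual
    intensity pooling, gas-chromatography equivalence scaling, a linear
    temperature calibration, greyscale-based deconvolution of upwelling and
    non-upwelling seasons with elemental (Ca, Fe, Ti, Si) constraints,
    ramp (change-point) regression of seasonality series, red-noise
    spectral analysis, Morlet wavelet transforms, band-pass filtering with
    windowed variability and analytical-noise correction, and an optimal
    two-group split of modern monthly SST climatologies.  A forward
    simulator of varved-sediment MSI spot tables with known ground truth
    supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
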