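# varveSST

Annual and seasonal sea surface temperature (SST) reconstruction from mass
spectrometry imaging (MSI) of varved marine sediments.

## The problem

Annually laminated (varved) sediments, such as those of the anoxic Cariaco
Basin off Venezuela, archive climate at seasonal resolution, but classical
alkenone palaeothermometry homogenises centimetres of sediment — decades to
centuries — into a single value. Laser-based MSI instead measures the di-
and tri-unsaturated C37 alkenones in ~100-µm laser spots, about 20,000 of
them per 5-cm thin section, so that single varves (≈0.5–1.4 mm) are covered
by tens to hundreds of individual proxy measurements. `varveSST` provides
the full data-processing chain from such spot tables to:

- **an annually resolved SST record** — spot quality control, tilt
  correction of laminae, age-model application, pooling of intensities into
  1-year horizons, the U37K' index, gas-chromatography (GC) equivalence
  scaling and a linear calibration to °C;
- **an SST seasonality record** — deconvolution of each spot into the
  upwelling (light, Si-rich laminae) or non-upwelling (dark, Fe/Ti/Ca-rich
  laminae) depositional season via a greyscale threshold anchored by
  elemental constraints, 5-yr seasonal SST records, and ramp (change-point)
  regression of their difference;
- **interannual variability analysis** — gap interpolation, detrending,
  red-noise (AR(1)) spectra, Morlet wavelets, 2–8-yr band-pass filtering,
  25-yr windowed standard deviations, and correction for the analytical
  noise of pooled MSI values;
- **a modern benchmark** — the optimal two-group split of monthly SST
  climatologies into contiguous warm/cold seasons;
- **a forward simulator** of varved-sediment MSI datasets with known truth,
  so every stage can be validated by parameter recovery.

## The statistics at the core

For each 1-yr (or 5-yr × season) horizon, intensities of spots passing
quality control (S/N ≥ 3 for both compounds, both detected, ≥ 10 spots) are
summed and converted:

    U37K' = C37:2 / (C37:2 + C37:3)
    U37K'(GC) = 1.194 × U37K'(MSI)
    SST = (U37K'(GC) − 0.044) / 0.033

The analytical precision of a value pooled over *n* spots follows the
fitted power law

    SD_analytical = 0.0741 × n^(−0.558)     (MSI proxy scale)

which the variability module subtracts from observed 25-yr windowed
variability before converting to °C. Seasonality is the difference between
non-upwelling and upwelling 5-yr SST; a season-mean difference *d* of a
sinusoidal annual cycle corresponds to a peak-to-peak annual amplitude of
(π/2)·*d*.

## Worked example

Simulate the default scenario — a 700-yr record (11.9–11.2 kyr b2k) whose
true seasonality steps from 0.8 to 1.8 °C at 11.64 kyr b2k, with the
sedimentation rate dropping from 1.4 to 0.5 mm/yr at 11.673 — and run the
whole chain:

```r
library(varveSST)
res <- run_full_pipeline(pipeline_config(seed = 1L))
res$ramp_unconstrained
#> ramp fit: 11.658 -> 11.628 kyr b2k (midpoint 11.643), levels 0.802 -> 1.781, rms 0.210 (n = 140)
res$window_means
#>   age_lo age_hi     mean        sd   n
#> 1 11.673 11.873 23.86793 0.3555453 200
#> 2 11.473 11.673 23.86643 0.5304661 200
amplitude_from_seasonality(res$ramp_unconstrained$level_after -
                           res$ramp_unconstrained$level_before)
#> [1] 1.537708
```

The ramp fit recovers the true step (0.8 → 1.8 °C at 11.64 kyr b2k) to
within ~0.02 °C in the levels and ~3 yr in timing; the 200-yr window means
on both sides of the transition midpoint sit at the true annual mean of
23.8 °C (the ≈ +0.07 °C offset reflects the higher alkenone flux of the
warm season weighting annual pools slightly warm); and the implied
peak-to-peak amplitude increase is 1.54 °C. The corrected 2–8-yr
variability averages 0.138 °C in the simulated Younger Dryas section versus
0.240 °C in the Holocene section (Welch t-test p = 1.2e-4), recovering the
configured era contrast.

A thin command-line front end (`inst/cli/varvesst`) exposes `simulate`,
`reconstruct`, `seasonality`, `variability`, `climatology` and
`full-pipeline` subcommands over the same functions, driven by a YAML run
configuration (`read_run_config()`).

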