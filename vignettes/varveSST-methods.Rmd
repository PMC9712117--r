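---
title: "Methods: annual and seasonal SST reconstruction from MSI of varved sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annual and seasonal SST reconstruction from MSI of varved sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varveSST)
```

# The measurement model

A mass-spectrometry-imaging (MSI) dataset is a raster of laser spots at a
100-µm pitch over a sediment thin section. Each spot carries the
intensities of the di- and tri-unsaturated C37 alkenones (`i372`, `i373`),
their signal-to-noise ratios, a greyscale value (`gs`, 0 = black), and
micro-XRF elemental intensities (Ca, Fe, Ti, Si). In varved sediments of
the Cariaco type, one year deposits a couplet: a dark lamina (rainy,
non-upwelling season; terrigenous Fe/Ti plus biogenic CaCO~3~) and a light
lamina (upwelling season; diatom opal, high Si). SST information enters
through the alkenone unsaturation index

$$\mathrm{U^{K'}_{37}} = \frac{C_{37:2}}{C_{37:2}+C_{37:3}},$$

computed on *summed* intensities of all quality-controlled spots of a
horizon — pooling is always done on intensities, never by averaging
per-spot ratios, so each spot contributes in proportion to its signal.

Quality control retains spots with S/N ≥ 3 for both compounds and both
intensities strictly positive; a horizon needs at least 10 such spots
(`sn_min = 3`, `min_spots = 10`; both configurable). MSI-scale values are
multiplied by the measured GC-equivalence factor 1.194 (SD 0.021) and
converted to °C by the linear core-top calibration
$\mathrm{U^{K'}_{37}} = 0.033\,T + 0.044$.

**Calibration choice.** Published applications of this workflow convert
GC-equivalent values with a Bayesian spline calibration whose uncertainty
grows at warm temperatures (95% CI of several °C above ~24 °C).
`varveSST` deliberately uses the linear calibration throughout: it is the
same equation those applications use for converting *variability* (SD) from
proxy to temperature units, it is exactly invertible (which the simulator
and recovery tests require), and it keeps the package free of an external
posterior look-up. Absolute reconstructed SSTs therefore can differ from
spline-calibrated values by a systematic offset; differences and ratios of
SSTs — seasonality, variability, window contrasts — are insensitive to
this choice at the slope's scale.

## Depth, age and binning conventions

- Composite depth = slice offset (cm below seafloor) + within-slice,
  tilt-corrected depth, measured at spot centres, 0 at the slice top.
- Tilt correction interpolates tie-point depths linearly across the
  lateral coordinate per lamina (≥ 4 tie points each) and shifts each spot
  by the offset of the nearest lamina surface above it. The registration
  of MSI to radiographs ("teaching points") is instrument-side and outside
  the package; only the tie-point mechanism is modelled, and the exact
  2-D transform used upstream (rigid vs affine) is acknowledged as a gap.
- Age from depth is piecewise-linear through the age-model control points;
  queries outside the control range fail loudly rather than extrapolate.
- Year bins are half-open on the age axis with a spot exactly on a
  boundary assigned to the *younger* year; 5-yr seasonal bins follow the
  same rule.
- Greyscale normalisation: spots with `gs` ≤ 30 (configurable; the raw
  data show sediment-free areas as essentially black) are flagged
  background and excluded everywhere; `delta_gs` is the difference from
  the median `gs` of the non-background spots of the same slice, so its
  per-slice median is 0 by construction.
- GC-equivalent values > 1 are flagged but retained: clamping would bias
  every pooled statistic computed from them.

# Season deconvolution

Alkenone-bearing spots are binned by `delta_gs` at 1-unit resolution and
split at the integer threshold that maximises pooled
SST(darker side) − SST(lighter side), subject to three constraints:

1. the threshold is lighter than the `delta_gs` bins (bin size 5) where
   Ca, Ti and Fe peak,
2. darker than the bin where Si peaks,
3. both sides keep ≥ 25% of the spots; if (1)–(2) make that impossible
   the limit relaxes to 15% and the result is flagged.

Interpretation choices made here: "average SST above/below the cut" is
computed as *pooled-intensity* U37K' per side, consistent with every other
pooling step in the package, not as a mean of per-bin SSTs; the elemental
peak of each element is the single argmax bin, restricted to bins holding
at least 25 spots so that sparsely populated extreme-greyscale bins cannot
capture the argmax by sampling noise. Thresholds are estimated per 5-cm
slice by default, because greyscale scale and lamina contrast drift
between thin sections; ties in the SST difference break toward the
smallest absolute threshold, making the search deterministic. A
brute-force enumeration of every integer cut serves as the test oracle for
this search.

Seasonal records are built exactly like the annual record but per season
at 5-yr resolution; seasonality is non-upwelling minus upwelling SST where
both seasons satisfy the spot minimum.

## Ramp regression

The seasonality series is fitted with a constant–linear–constant "ramp":
level_before for ages at or older than `t_start`, level_after at or
younger than `t_end`. Breakpoint pairs are searched exhaustively on the
observed bin midpoints with the two levels solved by least squares per
pair — the global optimum on that grid, no iterative optimiser involved.
Ties in residual sum of squares break toward the shortest ramp. Negative
seasonality values are excluded from fitting (they are unphysical
season-label noise) but retained in the series. The constrained variant
restricts both breakpoints to configurable age intervals (defaults
11.725–11.8 and 11.6–11.675 kyr b2k). A season-mean difference *d* maps to
a sinusoidal peak-to-peak annual amplitude of $(\pi/2)\,d$: a sine of
half-amplitude $a$ has half-cycle means $\pm 2a/\pi$, so $d = 4a/\pi$ and
the peak-to-peak amplitude is $2a = (\pi/2) d$.

# Interannual variability

The GC-scale annual proxy series is prepared by linear interpolation of
interior missing years (leading/trailing gaps are an error; more than 20%
missing aborts) and removal of a linear trend. Filtering and windowing are
done on the proxy scale, with SDs converted to °C by dividing by the
calibration slope at the end — matching the convention of converting
variability through the linear equation; a flag allows the alternative
°C-first ordering, which differs only by the constant slope factor.

**Band-pass.** The 2–8-yr band of an annually binned record has its short
edge exactly at the Nyquist period, so a band-pass with an upper corner at
Nyquist is not realisable; the filter is a zero-phase (forward–backward)
4th-order Butterworth high-pass whose corner is placed at 0.64× the
1/8 yr⁻¹ band edge, giving a two-pass gain ≥ 0.97 across 2–8 yr and
≤ 0.03 below 20 yr. The normative property is this gain contract, not any
particular filter realisation; tests measure the response with sine
probes.

**Windowed variability and noise correction.** The SD of the filtered
signal is taken over non-overlapping 25-yr blocks (trailing partial block
dropped). The analytical component is predicted per year by the fitted
power law $0.0741\, n^{-0.558}$ (MSI scale, R² = 0.838 in the underlying
replicate experiment), averaged over the block's years, and — because the
filtered series is on the GC-equivalent scale — multiplied by the
GC-equivalence factor 1.194 before subtraction; the law itself was fitted
on the MSI scale and would otherwise under-correct by ~19%. Subtraction is
done on SDs by default, matching the stated convention of the method, and
floored at zero. Because $\sqrt{s^2+n^2}-n < s$, SD-domain subtraction is
conservative (biased low) whenever noise is comparable to signal; a
variance-domain option (`domain = "variance"`,
$\sqrt{\max(\mathrm{obs}^2-\mathrm{noise}^2,0)}$) is provided and is the
one under which the simulator's era-dependent band SDs are recovered
within 20% in the test suite. Era contrasts are tested with a two-sided
Welch t-test; seasonality group contrasts with a Mann–Whitney rank test.

**Spectrum.** The red-noise spectrum is a Welch estimate: 2 segments with
50% overlap, Hanning taper, frequency oversampling 2 by zero padding,
evaluated to the Nyquist frequency (period 2 yr). The null continuum is
the theoretical AR(1) spectrum with the lag-1 coefficient estimated from
the series, scaled to the estimate's mean power, and the 95% false-alarm
level is the χ² quantile at 2 × segments degrees of freedom. This
deliberately simplifies the full Monte-Carlo bias machinery of dedicated
red-noise spectral tools: the contract tested is *false-alarm
calibration* — white noise exceeds the 95% level in ≈ 5% of bins — and
known-line recovery to within one frequency bin, not bit-level agreement
with any particular program.

**Wavelet.** The continuous Morlet transform (ω₀ = 6) follows the
standard FFT formulation with dyadic scales at 1/4-octave resolution,
cone of influence at the e-folding time $\sqrt{2}s$ expressed as a period,
and pointwise significance against the same AR(1) continuum with χ²₂. It
is implemented in-package in ~40 lines; tests check zero-input nullity,
burst localisation and the closed-form cone.

# The forward simulator

`simulate_truth()` builds the per-year truth: annual mean =
`mean_sst` + sinusoids at `cycle_periods` + an AR(1) anomaly rescaled per
era so its 2–8-yr band SD equals `interannual_sd` + white noise; seasonal
truths sit at ± half the seasonality function around the annual mean, so
the configured seasonal difference is exact by construction. Varves stack
with thickness equal to the era's sedimentation rate. `simulate_dataset()`
rasters slices at the configured pitch (50 mm × 4 mm at 100 µm =
20,000 spots per slice), assigns spots to varves and laminae, and draws:

- greyscale: Gaussian per lamina type (dark 130, light 170, SD 5 —
  unstated in the source material; chosen to give clean but overlapping
  modes around a mid-grey median);
- elements: lognormal, with Fe/Ti/Ca twofold enriched in dark and Si in
  light laminae;
- alkenones: each spot is detected with probability 0.7; detected spots
  draw a lognormal total intensity, 1.5× larger in the non-upwelling
  season (the direction is documented in the source material, the factor
  is not; 1.5 is a deliberate, fixed choice), and split it by the noisy
  ratio $r = \mathrm{clamp}(u + N(0, 0.0741), 0, 1)$ with
  $u = (0.033\,T_{season} + 0.044)/1.194$.

Per-spot noise is additive Gaussian with the power law's $n{=}1$
coefficient; pooling $n$ equal spots then scales as $n^{-1/2}$, while the
correction module honours the empirically fitted exponent −0.558. The
mismatch is intentional — the generator encodes the physical $\sqrt{n}$
mechanism, the correction encodes the measured law — and the pooled
precision of the generator stays within a factor 1.5 of the law for
$n \in \{5, \dots, 50\}$, which the test suite verifies.

Defaults encode the study conditions: ages 11.9 → 11.2 kyr b2k,
sedimentation rate 1.4 → 0.5 mm/yr at 11.673, true annual mean 23.8 °C on
both sides, seasonality stepping 0.8 → 1.8 °C at 11.64, cycles at 120 and
42 yr. Where no value is documented, one realistic value was fixed once:
cycle amplitudes 0.3/0.2 °C (visible but not dominant against interannual
noise), interannual band SD 0.15 °C (old era) / 0.35 °C (young era, split
at 11.66) expressing the qualitative weak-to-prominent strengthening,
AR(1) φ = 0.5, white noise 0.1 °C, 50:50 dark:light lamina split, mean
detected-spot intensity lognormal(log 100, 0.3) with S/N equal to
intensity.

**What the simulator does not emulate** — and hence what passing recovery
tests do and do not show: no calibration-model error (simulator and
reconstruction share the linear calibration, so recovery cannot detect
calibration bias); no bioturbation, varve-thickness variability within an
era, or the divergent deeper-YD lamination regime; no within-varve phasing
of alkenone deposition relative to the greyscale extremes (proxy season is
tied strictly to lamina type); no matrix effects, mass-spectral
interferences or spatial intensity drift. Recovery results demonstrate
that the *processing chain* is unbiased and correctly propagates the noise
law under these idealised conditions, not that real-sediment systematics
are absent.

# Modern monthly climatology

`monthly_seasonality()` splits the 12 months of a year into two
complementary blocks of consecutive calendar months, each 3–9 months long,
and maximises the absolute difference of the block means. Blocks are
*circular* (a warm season may wrap December → January): the defining
description says only "consecutive months", and at a tropical station the
warm season can straddle the year boundary, so the circular reading is the
physically sensible one. The two blocks partition the year — months are
never left unassigned — which matches the reading of "dividing monthly
data into two groups". The implementation is itself an exhaustive
enumeration; an independently written enumeration in the tests guards the
block/complement bookkeeping. Applying the split to a gridded product's
Cariaco cell for 1980–2020 requires that external download and is outside
the offline test scope; the algorithm is exercised on synthetic monthly
climatologies with known splits instead.

# Problem sizes and runtime choices

The test suite and the acceptance script run the full default scenario
(700 simulated years, ~240,000 spots) for end-to-end recovery; the
across-seed ramp-recovery property uses 20 seeds of that scenario;
spectral false-alarm calibration uses 120 white-noise series of length
256; precision-law checks use 1,500 replicates per spot count. These sizes
were chosen so each property is measured with comfortable statistical
margin while the whole suite completes in about a minute.

# Known limitations

- Absolute SSTs inherit the linear calibration's behaviour at warm values;
  only a configurable slope/intercept is provided, not a spline posterior.
- The season threshold is a single cut per slice (or per record); mixed or
  transitional laminae are assigned wholly to one season.
- The SD-domain noise correction is conservative by construction; use the
  variance-domain flag when an unbiased magnitude matters and the noise
  model is trusted.
- The simplified AR(1) false-alarm level omits the Monte-Carlo bias
  correction of dedicated spectral packages; significance near the Nyquist
  and fundamental frequencies is approximate.
- `fit_ramp()` searches breakpoints on the observation grid only;
  sub-grid change-point timing is not interpolated.
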