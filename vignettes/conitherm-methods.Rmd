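---
title: "Methods: thermography-based drought-stress inference for conifer seedlings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermography-based drought-stress inference for conifer seedlings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

A seedling is imaged from above while mounted between black heated plates
held near 40 °C; a wet reference (water-soaked fabric over floating
styrofoam) and a dry reference (laminated board) sit in the same frame.
The plates guarantee that every background pixel is hotter than any
transpiring canopy — the contrast on which segmentation rests — and the
references bracket the physiological temperature range: a canopy at the
wet reference behaves like a fully transpiring leaf, at the dry reference
like a closed one. The two indices,

$$CWSI = \frac{T_{canopy}-T_{wet}}{T_{dry}-T_{wet}}, \qquad
  I_g = \frac{T_{dry}-T_{canopy}}{T_{canopy}-T_{wet}} = \frac{1-CWSI}{CWSI},$$

are dimensionless and invariant to a common temperature offset, which is
what makes them comparable across measuring days with different weather.
Out-of-range CWSI values (canopy beyond a reference) are retained with a
warning rather than clipped: clipping would truncate the response
distribution and bias the mixed models downstream.

### Emissivity

Cameras are operated with the emission coefficient set to 1 and corrected
afterwards. The apparent emission coefficient of each surface is the
quotient of its contact temperature over its image temperature, taken in
kelvin — the only scale on which a temperature ratio is physically
meaningful. Correction is the inverse map, multiplication of the apparent
kelvin temperature by the coefficient, so that correcting an image
temperature with its estimated coefficient returns the contact
temperature exactly (the package asserts this round trip to $10^{-9}$ °C).
No reflected-background compensation is attempted; under constant shading
the coefficients are *apparent* emissivities and are documented as such.
The defaults (canopy 0.90, wet 0.95, dry 0.93) are the calibrated values
for Scots-pine needles and the reference materials.

## The image-processing chain

`segment_scene()` runs, in order:

1. **Unsharp masking**, $S = (I - w\,G_\sigma(I))/(1-w)$ with
   $\sigma =$ 2 px and $w = 0.9$ — the standard definition of the
   "Unsharp Mask" command, written out so the implementation is
   independent of any particular tool. All convolutions use reflective
   padding; a constant raster is an exact fixed point.
2. **Intermodes thresholding** of the sharpened values in the canopy
   search region (the frame minus the reference rectangles). The 256-bin
   equal-width histogram is smoothed with the kernel (1, 2, 1)/4 until
   exactly two local maxima remain; the threshold is the midpoint of the
   two mode centers. Because the smoothing uses only additions and
   divisions by four, which are exact in binary floating point, the
   result is bit-reproducible and the test suite checks it against an
   independently written brute-force oracle for exact equality.
   One numerical choice matters here: at $w = 0.9$ the unsharp mask
   amplifies values near crisp boundaries roughly tenfold, and on an
   unbounded floating-point raster that over/undershoot stretches the
   histogram range until the tissue and plate modes merge into a single
   bin cluster. The histogram is therefore built from sharpened values
   *saturated at the original raster's value range* — exactly what
   happens implicitly when the command is applied to an integer image.
   Without this the threshold lands in the ringing tail (15 °C or 55 °C
   instead of ≈34 °C on default scenes).
3. **Keep the cool class.** Plant pixels are those *below* the threshold;
   this direction is forced by the 40 °C plates being hotter than any
   transpiring canopy in the observed air-temperature range.
4. **Edge removal.** Pixels whose Sobel gradient magnitude (computed on
   the sharpened raster, where masks are built) exceeds an Otsu split
   within the candidate set are removed after dilation by 1 px. Mixed
   plant/background pixels live on region boundaries and carry high
   gradients; a data-driven split adapts across noise levels where a
   fixed cut would not.
5. **Medians from the original raster.** Sharpening distorts radiometry,
   so masks come from the sharpened image but temperatures are always
   read from the unsharpened one (a test makes the sharpening extreme
   and checks the medians do not move). Reference medians discard the
   hottest decile of their rectangle first — rims and plate bleed-over
   sit in that tail. Medians from fewer than 25 pixels are flagged.
6. **Daily aggregation** averages the 1–3 replicate medians per tree and
   day, skipping failed replicates.

## The synthetic scene generator

`generate_thermal_scene()` emulates the imaging setup, not its physics:
crisp regions at stated temperatures, plus two corruption processes, plus
i.i.d. Gaussian sensor noise. The crown is a stem axis with dense
elliptical needle whorls and thin (1–3 px) radiating needle segments.
The whorls matter: a crown of only 2-px needles has no interior on the
sharpened raster (every pixel is boundary at $\sigma = 2$), the tissue
mode vanishes from the histogram and thresholding degenerates — whereas
the real images resolve needles over many pixels. Mixed pixels are drawn
on the one-pixel canopy boundary: each boundary pixel becomes, with
probability `edge_mix_fraction` (default 0.3), a mixture
$\alpha T_{canopy} + (1-\alpha) T_{plate}$ with
$\alpha \sim U(0.2, 0.8)$ — the simplest stand-in for partial-volume
mixing. Default sensor noise is 0.2 °C, a little above the 0.08 K
thermal resolution of research-grade cameras to allow for within-canopy
temperature texture.

The generator returns ground-truth masks (which partition the frame
exactly) and true temperatures, so segmentation accuracy is measured
against truth, on the apparent-temperature scale, with emissivities set
to 1. What passing these tests does *not* show: robustness to
radiometric calibration error, reflected radiation, optics blur, or
canopy temperature gradients — none of which the generator simulates.

Scenes are written as 32-bit single-band TIFF. TIFF samples live on
[0, 1], so temperatures are stored as $(T + 20)/100$ with the affine map
recorded in the sidecar JSON and inverted on read.

## The synthetic experiment generator

`generate_experiment()` produces tree × measuring-day tables with the
structure the two model families assume.

- **Design**: 48 trees, six provenances (F3, PL9, ES1, D8, BG10, I4),
  27 control / 21 drought, unbalanced across provenances exactly as in
  the greenhouse trial; 17 measuring days spread over a 61-day summer
  study window.
- **Soil water deficit** (PSWD) is stored as a deficit-positive
  *fraction*: 0 at field capacity, 1 when the plant-available water at
  field capacity (40% of pot weight at 10 kPa) is depleted, negative
  when over-saturated. The magnitudes of the default model coefficients
  (−2.49, 1.61) are only consistent with a 0–1 predictor scale. The
  default schedule has both treatments identical until measuring day 4,
  a drought plateau near 0.88 (around the permanent wilting point)
  against a control plateau near 0.30, and partial re-saturation from
  day 14 (0.45 vs. 0.15); each tree adds a N(0, 0.03) offset. A rank
  test between treatments is non-significant before the divergence day
  and strongly significant after it, which is what defines the stress
  window (days 4–13) and recovery window (days 14–17).
- **Meteorology** is sampled uniformly within the measuring-day envelope
  (air temperature 20.4–37.1 °C, relative humidity 29–66%, radiation
  24–234 W/m²): a uniform daily mean plus a ±5%-of-range within-day
  deviation, since the 48 trees are measured sequentially; the
  measurement order is randomised per day and recorded. VPD follows the
  FAO-56 form $e_s = 0.6108\,e^{17.27T/(T+237.3)}$, $e_a = RH\,e_s/100$.
  No weather model beyond the envelope is attempted.
- **Response**: fixed linear predictor + per-tree random intercept
  N(0, $\sigma_0^2$) + residual N(0, $\sigma_\epsilon^2$), built from a
  named coefficient list covering every term of the chosen model family;
  unnamed terms are zero and unknown names are rejected with the valid
  list. For Ig the linear predictor lives on the square-root scale (the
  fitting scale) and the table stores its square. Covariates enter
  *uncentered* — centering belongs to the modelling stage, which records
  the means it used. Reference and canopy temperatures consistent with
  each index value are back-computed so the index algebra holds row by
  row.
- **Default coefficients** use the characteristic magnitudes for these
  indices under greenhouse drought (CWSI: deficit −2.49, deficit² 1.61,
  VPD 0.044, radiation 0.00032; treatment model: −0.23 during stress),
  with modest provenance offsets and interactions. Note a quirk these
  magnitudes inherit: on the deficit-positive fraction scale the CWSI
  quadratic has its minimum at 0.77, so simulated CWSI *falls* over most
  of the deficit range — the sign conventions around this quantity are
  genuinely tangled in the source material (a deficit-positive textual
  definition against an over-saturation-positive figure convention), and
  the package documents its own convention rather than asserts the
  original intent. Parameter-recovery results are unaffected by the
  direction quirk. Default variance components $\sigma_0 = 0.10$,
  $\sigma_\epsilon = 0.15$ were chosen once to put the marginal R² of
  the fitted deficit model near 0.65, the regime reported for this kind
  of data; they are not tuned per test.

## The two model families

Both are Gaussian random-intercept models fitted by `nlme::lme` (ML for
AIC comparisons and term deletion, REML for reported fits), with
optional `varIdent` (per-treatment residual variances) or `varPower`
variance functions — the two standard remedies for the heteroscedasticity
such index data show.

**Deficit model** (whole study period): index ~ provenance + PSWD +
PSWD² + height + diameter + meteorology + radiation +
provenance×(PSWD, PSWD²) + meteorology×PSWD, random intercept per tree.
PSWD stays uncentered so that re-centering it at a scenario value turns
the provenance dummies into provenance differences *at that deficit*;
all other covariates are mean-centered and the centers stored for exact
refits (re-centering changes the log-likelihood by < 10⁻⁶, which is
tested). No time variable enters: time and deficit are collinear by
design of the experiment. The meteorology set is either VPD or air
temperature + relative humidity — strongly correlated alternatives —
selected by ML-AIC with ties going to VPD (fewer parameters).

**Treatment model** (stress or recovery window): index ~ provenance +
treatment + t + t² + height + diameter + T + RH + radiation +
treatment×(provenance, t, t², height, diameter, T, RH). The treatment
dummy is 0 for drought, 1 for control; a test flips the labels and
checks the coefficient flips sign with |z| unchanged. Time is days since
the study start scaled by 42 (the treatment-window length), which puts
the time coefficients on the order the field reports; the scaling is
recorded in output metadata.

**Simplification** is single-term backward deletion under ML-AIC with a
marginality map (an interaction protects its main effects; the quadratic
protects the linear; the provenance×PSWD² interaction additionally
protects provenance×PSWD). Deletion stops when no removal lowers the
AIC, and the deletion log is returned. A useful calibration fact: for a
truly inert term the single-step AIC rule removes it with probability
P(χ²₁ < 2) ≈ 0.84, not 1 — the tests assert majorities accordingly.

**R²** follows the Nakagawa–Schielzeth decomposition for Gaussian
identity-link mixed models: marginal = var(fixed predictor)/total,
conditional adds the random-intercept variance to the numerator. Under a
variance function the residual variance is averaged over observations.

**Contrasts.** All pairwise families use one coherent procedure: z
statistics from the fitted fixed-effect covariance,
Benjamini–Hochberg-adjusted within each family (the adjusted p-values
are checked against a directly coded step-up oracle). Families are kept
per table — provenance pairs at each deficit scenario (0, 0.5, 1);
control-vs-drought within each provenance; provenance pairs within each
treatment — a conservative, reproducible choice where a single global
family would be ambiguous. Curvature differences between provenances are
tested jointly on the (linear, quadratic) interaction-coefficient
differences with a 2-df Wald χ². Under a global provenance null both
procedures hold their type-I error below 5% over 500 simulated studies
(part of the acceptance suite).

**Response magnitude.** Per-tree index means over the stress window,
then every drought individual paired with every control individual
*within the same provenance* — the only pairing under which the
provenance groups of deltas remain comparable — followed by
Kruskal–Wallis (whose null distribution is checked against χ²ₖ₋₁ by
simulation) and Dunn's pairwise z tests with tie correction and BH
adjustment.

## Numerical choices and degenerate inputs

- Mixed-model optimisation tries `nlminb` first (it resolves
  zero-variance boundaries sharply, which the OLS-collapse tests rely
  on) and falls back to `optim`.
- Histograms: intermodes caps smoothing at 10,000 iterations and raises
  "not bimodal" for monotone or constant input (constant = relative
  range below 10⁻⁸); a noisy unimodal sample can legitimately pass
  through a two-mode state and yield a threshold — the cap is a
  guarantee of termination, not a unimodality test.
- Reference level for provenance dummies is alphabetical (BG10); all
  contrast machinery is invariant to the choice.
- Degenerate geometry (overlapping or non-fitting reference rectangles,
  images under 32 px, canopy at plate temperature) is rejected with
  descriptive errors rather than silently mis-segmented.

## Problem sizes

The test and acceptance suites run at the scale of the original study
where the claim concerns that scale: 48 trees × 17 days for parameter
recovery (200 replicates for coverage, 500 for test calibration), 100
synthetic scenes for segmentation accuracy plus 50 paired seeds for the
edge-removal comparison, 2,000 simulations for the rank-test null, and
10,000 random triples for the index algebra. Smaller designs (12–24
trees) are used where only code paths, not operating characteristics,
are under test.

## Known limitations

- The scene generator has no energy balance, optics model or radiometric
  calibration error; segmentation results transfer to real images only
  to the extent that tissue/background contrast and mixed-pixel
  structure do.
- The experiment generator draws meteorology independently across days
  (no autocorrelation) and gives all provenances the same dimension
  distribution.
- Random slopes and temporal autocorrelation are out of scope: the
  models use tree-level random intercepts only, as the analysis they
  implement did.
- The response-magnitude pairing and the FDR family boundaries are
  documented design choices where the original description is ambiguous;
  alternative readings would change the multiplicity accounting.
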