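---
title: "Methods: micro-hyperspectral calibration models for anthocyanin content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro-hyperspectral calibration models for anthocyanin content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthospec)
```

## The problem

Anthocyanin content in pigmented plant tissue (the motivating system is
potato outer and inner skin) is conventionally measured by HPLC, which is
slow and destructive. Transmittance micro-hyperspectral imaging offers a
fast alternative: a cube of raw digital numbers (lines x pixels x 616
spectral bands over 365--1025 nm) is calibrated against dark and white
reference frames, a region of interest is averaged into one spectrum per
sample, and a regression model maps spectra to content. `anthospec`
implements that pipeline end to end: cube calibration and ROI extraction,
spectral preprocessing, wavelength selection (CARS and SPA), two
regression families (PLS and a 1-D CNN), and the standard evaluation
metrics, plus a synthetic-data generator so every stage is testable
without instrument data.

## Cube calibration and extraction

Raw counts are converted to percent transmittance per pixel and band:

$$C = \frac{R - B}{W - B} \times 100\%$$

with $R$ the raw cube, $B$ the dark frame (lens capped) and $W$ the white
reference. The identity is affine-gauge invariant: re-scaling all three
frames by the same positive affine map leaves $C$ unchanged, which is the
property the tests assert. Positions where $W \le B$ (dead or saturated
pixels) are set to `NA` and excluded from ROI means; a band aborts only
when more than 1% of its ROI pixels are invalid, so isolated dead pixels
do not kill a run. The ROI is a 0-based, half-open window, by default
100 x 100 pixels, and its per-band arithmetic mean is the sample's
spectrum; averaging $10^4$ pixels shrinks i.i.d. pixel noise by a factor
of 100. Band labels are integer-rounded nanometres and may repeat
(616 bands over 660 nm is ~1.07 nm spacing); all internal indexing is
positional and labels are display-only.

## Preprocessing

Three row-wise operators and their ordered pairs give the seven standard
treatments (Raw, SG, SNV, DET, SG+SNV, SG+DET, SNV+DET):

* **SG** — Savitzky–Golay smoothing, the local least-squares polynomial
  filter. Window and degree are unspecified in the source protocol and are
  configuration here, defaulting to window 11 / degree 2, a mild filter
  that smooths without visibly distorting band shapes. Edges are handled
  by evaluating the local polynomial at the edge positions, keeping full
  length with no padding artifacts. The implementation delegates to
  `signal::sgolayfilt`; its interior weights are verified against the
  closed-form least-squares solution (window 5 / degree 2 gives the
  classic (-3, 12, 17, 12, -3)/35).
* **SNV** — per-spectrum centering and scaling to unit sample SD
  (denominator $n-1$), removing additive offset and multiplicative
  scatter. Undefined for a constant spectrum; that is a hard error.
* **DET** — subtraction of the least-squares polynomial baseline, default
  order 2 (offset, slope, curvature). The wavelength axis is rescaled to
  $[-1, 1]$ before fitting for conditioning; the residual is orthogonal to
  the fitted polynomial space, so detrending is idempotent.

Order matters (`SG` then `SNV` differs from `SNV` then `SG`), so a
treatment is an ordered list.

## Wavelength selection

**CARS** (competitive adaptive reweighted sampling) runs 50 Monte Carlo
iterations. Each iteration records the 10-fold RMSECV of a PLS model on
the retained bands — the fold assignment is drawn once per call, so every
subset is scored on identical folds — then fits PLS on a random 80% sample
subset, converts absolute regression coefficients to weights, applies the
exponentially decreasing function (retention ratio decaying from 1 to
$2/p$), and applies adaptive reweighted sampling (weighted draws with
replacement; bands drawn at least once survive). The subset with minimal
RMSECV wins. Because the first recorded subset is the full spectrum, the
winner can never lose to the full spectrum on those folds, and retained
sets are nested across iterations. If concentrated weights collapse the
retained set below 2 bands before the schedule ends, the schedule is
truncated with a warning — on smooth, highly informative spectra this is
expected behaviour, not a failure. The number of latent variables feeding
the weights is chosen by the same cross-validation, capped at 15.

**SPA** (successive projections algorithm) grows a chain from each
candidate starting band on the centered calibration block: each step picks
the band whose column has maximal norm after projection orthogonal to the
span of the chosen columns, so chains are nested in $k$. Every prefix with
1 to 30 bands is scored by ordinary multiple-regression RMSE on a held-out
third of the samples (one unpivoted QR per chain serves all nested
prefixes); the prefix with minimal validation RMSE wins. Ties everywhere
resolve to the lowest band index / earliest start / smallest subset, so a
fixed seed reproduces selections exactly.

Selection runs on the calibration partition only by default, so no test
information leaks into the band choice; a `selection_on = "full"` flag
reproduces whole-set selection where that is wanted for comparison.

## Regression

**PLS** is univariate NIPALS on mean-centered data. One decomposition
yields the cumulative coefficient path for every latent-variable count, so
10-fold cross-validation over up to 15 LVs costs one fit per fold. The LV
count minimizing RMSECV is chosen, ties toward fewer LVs. At full rank PLS
equals ordinary least squares and its first weight vector is proportional
to $X^\top y$ — both are test oracles, alongside agreement with an
independent reference implementation (`mixOmics`). The 2:1
calibration/prediction split (384/192 of 576) is the PLS convention here.

**CNN** is a compact 1-D convolutional network: three blocks of
(convolution with 16 kernels of width 5, stride 1, same padding; batch
normalization; ReLU; max-pool of 2), a flatten, a 64-unit ReLU layer and a
scalar linear output, trained with Adam at learning rate 0.001 for 100
epochs, batch size 32, mean-squared-error loss, on an 4:1 split (460/116).
The block count, kernel count, activation, normalization, learning rate
and epochs follow the published architecture; kernel width, pooling, the
hidden width, the optimizer variant and the batch size are the smallest
conventional completion of that description. Inputs are standardized per
band and the target is standardized, with training-set statistics only
(stored in the model, inverted at prediction); this is required for stable
training at the stated learning rate and is disclosed configuration.
Pooling degrades to the identity once the signal length reaches 1, so the
same architecture accepts short selected-band inputs. The
forward/backward passes are written against im2col convolutions with the
elementwise kernels in C++; gradients are verified against finite
differences to 1e-5, and fits are exactly reproducible by seed. Batch
normalization keeps running statistics, so inference is deterministic.
There is no early stopping and no weight decay.

## Evaluation

For a calibration (training) and prediction (test) set the five numbers
are Rc and RMSEC (Pearson correlation and root-mean-square error on the
calibration set), Rp and RMSEP (the same on the prediction set), and the
residual prediction deviation
$\mathrm{RPD} = \mathrm{SD}(y_{\text{test}})/\mathrm{RMSEP}$ (sample SD,
$n-1$). The conventional reading is RPD > 2 usable, > 2.5 robust. The
identity $\mathrm{RPD} \times \mathrm{RMSEP} = \mathrm{SD}(y_{\text{test}})$
is asserted to 1e-9 for every emitted report. `run_grid()` evaluates the
treatment x selector x model design, records per-cell failures without
stopping, and `rank_reports()` orders by RPD (descending), RMSEP breaking
ties.

## The synthetic generator

No instrument data accompany the motivating study, so the generator is a
first-class module. A spectrum is

$$T(\lambda) = 100\,B(\lambda)\,(1 + d(\lambda))\, s\,
  \exp\{-f(c_{\mathrm{eff}}) \textstyle\sum_k g_k G(\lambda; \mu_k, \sigma_k)\}
  + \epsilon(\lambda)$$

with a fixed quadratic transmittance baseline $B \in [0.65, 0.875]$,
per-spectrum polynomial drift $d$ (coefficient SD 0.005), a log-normal
scatter factor $s$ (log-SD 0.02), Gaussian absorbance bands at 530, 700
and 850 nm (SDs 15/25/20 nm — the visible pigment dips plus the third C-H
overtone region; gains 0.15/0.10/0.08 per unit %, giving a ~30-point
transmittance dynamic range at the main dip), i.i.d. band noise (SD 0.3
points), and an effective concentration
$c_{\mathrm{eff}} = \max(0, c + \mathcal{N}(0, 0.35))$.

Two of these defaults deserve comment:

* **Concentration scale.** The content unit is % with targets uniform on
  [0.6, 4.0], so the target SD is $3.4/\sqrt{12} \approx 0.98$ — the
  spread implied by published full-spectrum potato-skin results, where
  RPD x RMSEP is consistently ~0.97–0.98. Keeping this spread keeps
  synthetic RPD magnitudes comparable with that effect-size regime.
* **Concentration noise.** The 0.35% effective-concentration noise
  represents biological variability and reference-method error that
  decouple the optical signal from the HPLC value. It sets the
  irreducible prediction floor: without it, 616 clean bands predict the
  target to RMSEP ~0.03 and every model looks perfect, which matches no
  real tissue-calibration study. With it, full-spectrum PLS lands at
  RMSEP ~0.33 and RPD ~2.5–3.0, the regime real studies report.

Cubes are generated to satisfy
`raw = black + (white - black) * T / 100` per pixel and band, with the
black frame strictly below the white frame, optional fixed-pattern
texture and a smooth lamp profile, so black/white calibration plus ROI
averaging recovers the generating spectrum (exactly at zero pixel noise
— a round-trip test).

### The nonlinear study

`nonlinear_study_config()` is a second, named condition set used to
compare the CNN against PLS: a saturating quadratic link
$f(c) = c + 0.25 c^2$, strong multiplicative scatter (log-SD 0.15) and
baseline drift (SD 0.03), low concentration noise (0.05), n = 300. The
design finding behind it: with clean spectra, the multi-band exponential
attenuation family is rich enough for a *linear* model to invert even a
strongly curved link essentially perfectly (PLS reaches r = 0.9997 on
noiseless quadratic-link data), so curvature alone cannot demonstrate a
nonlinear model's advantage. The advantage appears when raw spectra carry
realistic multiplicative interference — exactly what the preprocessing
operators exist to remove, and the regime in which published CNN-on-raw
results beat PLS. Under these conditions the CNN's prediction-set r
exceeds PLS's in the majority of seeds.

### What passing synthetic tests does and does not show

The generator produces smooth, low-rank spectra with known truth; it does
not model cell morphology, variety differences, detector nonlinearity,
wavelength miscalibration, or spatially structured noise. Tests passing
here demonstrate that the algorithms are implemented correctly and behave
sensibly in the intended effect-size regime — not that any particular
accuracy will be achieved on real tissue.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite: the full 576 x 616 study is exercised
  once per regressor; selector recovery studies use n = 200, p = 100
  (CARS) and p <= 6 (SPA oracle comparisons); grid determinism uses
  n = 80, p = 64 with a 4-epoch CNN. These sizes make the properties
  identifiable while keeping the suite quick.
* Ties: lowest band index wins in selectors; fewer LVs win in PLS CV.
* Degenerate calibration pixels become `NA` (policy above); constant
  spectra are SNV errors; constant targets are model errors; zero RMSEP
  reports RPD as infinite with a warning rather than failing.
* The CARS schedule truncates with a warning if the retained set collapses
  below 2 bands.
* Detrend and SPA use QR; SPA declares a prefix rank-deficient when the
  corresponding diagonal of R falls below 1e-10 relative.

## Known limitations

* PLS is univariate (one target at a time), which is all this pipeline
  needs.
* The CNN trains on CPU in seconds-to-minutes at study scale; it is not a
  general deep-learning engine and deliberately has no early stopping,
  scheduling or regularization beyond what the architecture states.
* ENVI I/O covers the common cases used here: BSQ/BIL interleave,
  little-endian, data types 4, 5 and 12.
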