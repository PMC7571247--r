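---
title: "Response mapping for wavelet denoising: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response mapping for wavelet denoising: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wavelet shrinkage is a workhorse for denoising biomedical signals (EMG,
ECG) and images (CT, MR), but its performance depends strongly on three
coupled choices: the mother-wavelet family, the filter order within the
family, and the decomposition depth. There is no universal best setting —
the optimum shifts with image content and, critically, with the amount and
kind of noise. `wavemap` turns this selection problem into a measurement
problem: it sweeps the full setting grid against a controlled, escalating
noise schedule and maps the resulting quality scores so the best settings
can simply be read off.

## The procedure

For a gold-standard record $X$ (a clean signal or image), a noise intensity
$\eta$ from a schedule, and a wavelet setting $(f, n, k)$ — family, order
$n \in 1..5$, level $k \in 1..5$:

1. **Degrade.** A composite noise model produces $X_\eta$. For signals this
   is additive white Gaussian noise at SNR $\eta$ dB (relative to the
   measured signal power) plus sparse symmetric impulses with variance
   $1/\eta$. For images it is Gaussian noise whose *mean* is $\eta$
   (variance fixed at 0.01), multiplicative speckle $J = I + nI$ with a
   uniform zero-mean multiplier of variance 0.05 held constant across the
   schedule, and salt-and-pepper noise with density $\eta$, applied in that
   order so the impulse extremes reach the denoiser intact.
2. **Denoise.** Discrete wavelet decomposition to level $k$ with the
   order-$n$ filters of family $f$; noise scale estimated as
   $\hat\sigma = \mathrm{median}(|d_1|)/0.6745$ from the finest detail
   band ($d_1$ = diagonal band for images); global universal threshold
   $T = \hat\sigma\sqrt{2\ln N}$ with $N$ the element count; soft
   thresholding of every detail band; reconstruction.
3. **Score.** The denoised output is compared with $X$ by MSE, Pearson
   correlation over all elements, Euclidean distance, and PSNR.

The scores populate a $5\times 5$ **spatial response map** per
$(\eta, \text{item})$ and stack into a 4D **volumetric response** with axes
(level, order, noise index, item). From the tensor the package extracts
per-$\eta$ optimal settings, maximum-achievable-quality curves (best cell
per item, then the mean over items), and per-family summaries.

## Noise-model details and their free constants

* **AWGN (1D)** uses *measured* signal power, so the realised noise power is
  $\overline{x^2}\,/\,10^{\eta/10}$ regardless of signal scaling.
* **Impulse (1D)**: only the variance contract is fixed by the protocol
  (variance $=1/\eta$). We use a Bernoulli($p$) occurrence with symmetric
  amplitudes $\pm\sqrt{v/p}$ and default $p = 0.05$; $p$ is exposed in the
  configuration since the split between rate and amplitude is otherwise
  unidentified.
* **Gaussian (2D)**: the swept parameter is the noise *mean* with variance
  0.01. Because a constant mean shift plus clipping is an unusual noise
  model, the alternative reading (swept parameter = variance of zero-mean
  noise) is available via `gaussian_interpret = "variance"`.
* **Speckle (2D)**: uniform multiplier on $[-\sqrt{3v}, \sqrt{3v}]$, which
  is the unique zero-mean uniform law with variance $v$ (default 0.05).
* All 2D outputs are clipped to $[0,1]$ after every noise stage.
* Default schedules: $\eta = 0.05, 0.10, \dots, 10$ (200 levels, 1D);
  $\eta = 0, 0.1, \dots, 1$ (11 levels, 2D).

## Wavelet engine

The three families (Daubechies, Symlet, Coiflet; Symlet order 1 coincides
with Haar) are orthogonal filter banks; lowpass coefficients ship as a
plain-text table and the highpass/synthesis filters follow from the
quadrature-mirror relations. Orders are capped at 5 for every family so the
sweep grid stays square — 5 is the highest order at which all three
families exist.

At load the table entries are projected (minimal-norm correction) onto the
constraints $\sum h = \sqrt2$ and $H(\pi) = 0$; published tables satisfy
these only to about $10^{-12}$, which would otherwise leave visible residue
in the detail bands of smooth inputs.

Boundary handling is half-sample symmetric extension by default: band
lengths are $\lfloor (n + F - 1)/2 \rfloor$, and the mild redundancy makes
the decimated transform perfectly invertible (round-trip error
$< 10^{-10}$ in the test suite). A periodized mode is also provided; its
analysis operator is exactly orthogonal, which the energy-conservation
tests exploit. A setting is *feasible* when every stage keeps the
approximation band at least as long as the filter; infeasible settings
raise a typed condition that sweep drivers record as missing cells, so
deep levels on small records never masquerade as poor performance.

Soft thresholding is the default rule — the universal threshold is
classically paired with soft shrinkage — with hard thresholding available.
One global threshold, computed from the whole record's element count, is
applied to all detail levels.

## Intensity adjustment

The classical post-denoise image-adjust step (mapping $[l, 1]$ linearly
onto $[0,1]$) is implemented as `adjust_intensity()`, with field-typical
defaults exposed by `recommended_low_in()`: 0.45 for high-contrast
piecewise (CT-like) content, 0.40 for smooth textured (MR-like) content,
0.50 otherwise. The *sweep default is the identity window*: those low-in
values are tuned for real clinical images, and a non-identity stretch
applied to the denoised image alone breaks the zero-noise limit (a clean
record should score perfectly against itself). Enable it per run with
`run_config(adjust = TRUE)`.

## Synthetic gold standards

The generators emulate the structural character, not the physics, of three
input classes:

* `piecewise` phantoms: 3–8 constant-intensity ellipses over a 0.1
  background with intensity gaps $\ge 0.2$ — the high-contrast,
  edge-dominated regime of CT content.
* `smooth_textured` phantoms: a low-frequency oriented ramp plus a bulge
  and band-limited sinusoidal texture of amplitude $\le 0.15$ — the smooth
  shaded regime of MR soft tissue.
* EMG-like signals: a white Gaussian carrier under a raised-cosine burst
  envelope (quiet baseline 0.05, bursts of half the segment width), the
  intermittent-activation pattern of surface EMG.

They are deterministic given a seed; banks derive child seeds from a master
seed. What passing tests on these phantoms do *not* show: behaviour under
Rician MR noise, partial-volume effects, anatomical texture spectra, or
electrode artefacts — the generators make the pipeline testable, not
clinically validated.

## Numerical and statistical choices

* Degenerate correlations (constant arrays) propagate as missing values,
  never as silent zeros, and are excluded from means and extrema.
* Ties in best-setting extraction resolve to the lowest level, then lowest
  order, then family enumeration order (Daubechies, Symlet, Coiflet) —
  preferring the cheaper setting at equal quality.
* The Chi-squared normality screen uses equal-probability bins under the
  fitted normal, $k = \lceil 1 + 3.322\log_{10} n\rceil$ bins and
  $k - 3$ degrees of freedom; simulation in the test suite confirms type-I
  calibration at $n = 10^4$.
* The Mann–Whitney comparison uses the exact U distribution for tie-free
  samples up to $n = 8$ per group and a tie- and continuity-corrected
  normal approximation otherwise; the two branches agree to
  $|\Delta p| < 0.02$ at the crossover.
* The populations compared across datasets are the per-noise-level,
  per-item best values per family — the quantity the response mapping is
  designed to deliver; pooling all cells instead is possible by operating
  on the tensors directly.
* Aggregation over items is the arithmetic mean (medians optional). The
  maximum-achievable curve takes each item's optimum before averaging.

## Problem sizes used by the checks

The bundled verification uses desk-scale inputs chosen to keep Monte-Carlo
error small relative to each assertion: $1024^2$ fields for noise moments,
50 random records across all 15 family/order combinations for perfect
reconstruction, $10^4$ random pairs for metric identities, 50 seeds for the
1D efficacy check, 20 seeds at $64^2$ for the 2D curve checks, and 500
replicates for type-I calibration.

## Known limitations

* The curve of best-achievable correlation against noise intensity is not
  strictly monotone at the destroyed end of the 2D schedule
  ($\eta \ge 0.9$, where salt-and-pepper density approaches 1): the
  per-item optimum is a maximum over 25 noisy, near-zero correlations, and
  that selection bias sets a small positive floor whose height varies
  between adjacent schedule points. The package reports what it measures;
  expect one to three inverted adjacent pairs in the tail of an otherwise
  cleanly decreasing curve.
* Universal-threshold shrinkage is not an effective salt-and-pepper filter
  (a median filter would be); at high densities all settings converge to
  similar low quality, which is informative about the protocol rather than
  about the wavelets.
* No stationary/undecimated transforms, level-dependent or SURE thresholds,
  or perceptual metrics (SSIM); these are outside the sweep's scope.
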