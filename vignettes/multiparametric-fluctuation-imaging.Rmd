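---
title: "Multi-parametric fluctuation imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-parametric fluctuation imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imfluct)
```

`imfluct` analyses a single camera-based TIRF image stack along several
independent axes — diffusion, particle number and brightness, oligomeric
state, and super-resolved structure — and uses the axes to cross-correct each
other. This vignette explains the models implemented, the parameters that
matter, the simulator used as ground truth, and the numerical and design
choices that were genuinely open.

## The camera FCS model

The intensity trace of one (binned) pixel fluctuates as fluorophores diffuse
through its observation area. Its normalised autocorrelation is fitted with

$$G(\tau) = \frac{1}{N}\,\frac{g(\tau)}{g(0)} + G_\infty,$$

$$g(\tau) = \left(\frac{\sqrt{4D\tau + \omega_{xy}^2}}{a\sqrt{\pi}}
\left(e^{-a^2/(4D\tau+\omega_{xy}^2)} - 1\right)
+ \operatorname{erf}\!\frac{a}{\sqrt{4D\tau+\omega_{xy}^2}}\right)^{2},$$

with `a` the object-plane pixel side in nm (camera pixel pitch / total
magnification, times the binning), $\omega_{xy}$ the 1/e² radius of the
Gaussian PSF, `N` the average particle number in the observation area, `D`
the diffusion coefficient, and $G_\infty$ a residual offset. `model_g()` is
verified in the test suite against an independent numerical double integral
of the pixel-pair Gaussian correlation kernel; at `a` = 240 nm and
$\omega_{xy}$ = 364 nm it gives $g(0) = 0.12056$, hence an effective
observation area $A_\mathrm{eff} = a^2/g(0) = 0.478\ \mu m^2$ and, at
$D = 2\ \mu m^2/s$, a transit time $A_\mathrm{eff}/(4D) = 59.7$ ms.

Key parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| camera pixel / magnification | 24 µm / ×100 | 240 nm object pixels |
| $\omega_{xy}$ | 364 nm | calibrated PSF 1/e² radius (561 nm channel) |
| correlator (p, q) | (16, 12) | multi-tau lag grid |
| bleach correction order | 8 | polynomial detrend per pixel |
| fitted lag range | 2 ms – 0.5 s | excludes the noisy long-lag tail |
| D acceptance window | 0.01–10 µm²/s | invalid-fit filter |

Restricting the fit to lags ≤ 0.5 s matters: the finite-trace correlation
estimator suppresses the ACF tail (the segment means it subtracts absorb slow
fluctuations), and fitting the full quasi-logarithmic grid biases D upward by
~10% on 40 s traces, whereas the capped range recovers simulated D to a few
percent.

## The multi-tau correlator

Block $b$ of the correlator averages $2^b$ frames per sample; block 0 carries
lags of 1..p frames, each later block p/2 lags. The estimator uses
*symmetric normalisation* — the means in numerator and denominator are taken
over the two overlapping trace segments — which reduces residual drift bias;
the estimator variant is a documented choice, since only the (p, q) scheme is
standard. The test suite pins the implementation to a naive
$O(T\tau)$ direct-sum oracle exactly at block-0 lags, and at binned lags to
the direct estimator on bin-averaged traces. Per-lag standard deviations come
from splitting the trace into 8 segments (SD across segment ACFs / √8);
they weight the nonlinear fits.

Photobleaching is corrected per pixel before correlation:
$F_c(t) = F(t)/\sqrt{f(t)/f(0)} + f(0)(1-\sqrt{f(t)/f(0)})$ with $f$ the
order-8 least-squares polynomial trend. The correction preserves the initial
mean and the local fluctuation-to-mean relation; order 0 is an exact
identity, and a non-positive fitted trend flags the pixel invalid rather than
propagating nonsense.

## Fitting

`fit_acf()` uses Levenberg–Marquardt least squares (bounds
D ∈ [10⁻³, 10²] µm²/s, N ∈ [10⁻³, 10⁶], G∞ ∈ [−0.5, 0.5]), initialised from
the ACF amplitude and half-decay lag, with two restarts at 0.1× and 10× the
initial D on non-convergence. The first lag channel is excluded as
shot-noise dominated. Two-component fits (amplitude-weighted sum of two
normalised one-component terms sharing the geometry) are attempted in map
fitting only where the one-component reduced χ² exceeds a threshold
(default behaviour: disabled in batch maps, available per pixel), with the
slow component labelled second. Validity requires convergence, a positive
amplitude, and D inside the acceptance window.

## PSF calibration and the diffusion law

For a freely diffusing calibration sample the fitted D must be independent of
spatial binning; an incorrect assumed PSF bends D systematically with
binning. `calibrate_psf()` scans a grid of candidate radii, fits the mean
per-pixel D at each binning, and picks the radius minimising the coefficient
of variation across binnings, requiring an interior minimum.

`diffusion_law()` computes, per square binning (default 1–5), the region mean
of per-pixel transit times $A_\mathrm{eff}/(4D)$ over valid pixels — the
per-pixel average was chosen (rather than fitting the region-mean ACF)
because pixel counts are the natural sample-size report for map data — and
fits an unweighted straight line (weighted optional). The intercept
classifies the diffusion mode: free within `z` SE of zero (default z = 2),
positive = confined/domain trapping, negative = meshwork. Two caveats are
deliberate: transit time is defined as $A_\mathrm{eff}/(4D)$ (an
$A_\mathrm{eff}/D$ axis rescales intercepts by 4 without changing sign or the
zero case; the convention is recorded in output metadata), and the 5-point
OLS intercept SE understates the uncertainty because the binnings reuse the
same data — classifications near the z·SE boundary should not be
over-interpreted.

## Number & Brightness and the oligomer algebra

With a dark-frame calibration (offset, read variance $\sigma_0^2$),
$N = (\langle I\rangle - \mathrm{offset})^2/(\sigma^2 - \sigma_0^2)$ and
$B = (\sigma^2-\sigma_0^2)/(\langle I\rangle - \mathrm{offset})$. In G1 mode
the lag-1 covariance of the trace replaces $\sigma^2 - \sigma_0^2$: shot and
read noise are uncorrelated between frames and drop out, so no read-noise
subtraction is needed. G1 mode assumes molecules stay correlated across one
(binned) frame — the transit time must be much longer than the frame time —
and the code warns when a supplied D says otherwise. The recommended regime
is 20 ms frames (sum-binning of 10 × 2 ms) over ≥ 40 s. Background pixels
are excluded with an intensity filter; the default is Otsu's threshold on
the mean image, since only "a suitable range" is standard practice and Otsu
is reproducible without user input.

Brightness ratios feed the binomial subunit-fluorescence model. Each subunit
of a k-mer is fluorescent with probability p, so the apparent brightness of a
pure k-mer relative to a monomer is $\langle q^2\rangle/\langle q\rangle$
with $q \sim \mathrm{Bin}(k, p)$, i.e. $1 + (k-1)p$. Consequently:

* a tandem-dimer/monomer ratio r gives `fluorescent_fraction()` p = r − 1;
* `dimer_fraction()` returns $m_e = (r-1)/p$, the fraction of *molecules*
  (subunits) residing in dimers. Note this is subunit-weighted: if m is the
  number fraction of dimer particles, $(r-1)/p = 2m/(1+m)$ — the two
  conventions agree at the boundaries (0 and 1) but differ in between, and
  both are exposed;
* `mixture_solve()` returns particle number fractions of a two-species
  mixture from $r = \sum f_k (k p(1-p) + k^2p^2) / \sum f_k\, k p$, with
  infeasible ratios reported against the pure-species bounds. Three-species
  mixtures are out of scope (they need additional measured brightnesses).

First-order error propagation from SE(r) and SE(p) accompanies the dimer
fraction; it is labelled as standard first-order propagation.

## Super-resolution: radiality/TRAC2 and SOFI

`radiality_frame()` magnifies each frame M-fold (default 5) and scores every
sub-pixel centre by gradient convergence: 2 × 6 points are sampled on a ring
of radius 0.5 original pixels; at each point the gradient (central
differences, Catmull–Rom bicubic interpolation — bit-exact equivalence with
other implementations is a non-goal, the invariants are what is tested)
defines a line whose perpendicular distance d from the centre contributes
sign(convergence) · max(0, 1 − d/r). The mean over samples, clipped at zero
and optionally intensity-weighted, is the radiality. Ring samples are placed
at half-step angular offsets to avoid axis lock. A border of
ceiling(ring radius) + 1 original pixels is zeroed (gradients there are
extrapolated), and the same crop should be applied to co-registered maps via
`crop_stack()`.

`srrf()` averages the stack into radiality frames (default 100 raw frames
each) and compresses the radiality time series per sub-pixel with the lag-1
temporal auto-cumulant TRAC2 $= |\langle\delta R_t\,\delta R_{t+1}\rangle|$
(mean mode available). With `normalize = TRUE` the global intensity scale is
divided out, making the output invariant under rescaling of the input.
A static noiseless structure has TRAC2 exactly zero — the method images
*fluctuating* structures, which is precisely what makes it filterable by
dynamics.

`sofi()` computes per-pixel temporal cumulants of the bleach-corrected trace:
order 2 is the variance, order 4 is $m_4 - 3m_2^2$ (absolute values
returned). Cumulants of Gaussian noise above order 2 vanish, and amplitudes
enter nonlinearly, sharpening structures at the cost of dynamic range. This
is textbook per-pixel cumulant SOFI, used as a comparison method; no
cross-cumulants or virtual pixels are computed (a radiality-plugin-based
SOFI variant with different ring parameters exists elsewhere and is not
reproduced here).

## The artifact-correction pipeline

Super-resolution from fluctuations produces false structures wherever
*anything* fluctuates (e.g. slow bright aggregates); FCS produces valid D
values also where no structure exists. The mutual correction is:

1. `tirf_mask()` — an intensity threshold (Otsu or user value) on the mean
   image retains the structure;
2. `d_histogram_threshold()` — the log₁₀ D histogram over the masked pixels
   (40 bins, 3-bin moving-average smoothing) is split at the central minimum
   between its two dominant peaks when the valley dips below 60% of the
   smaller peak; otherwise the configured fallback (0.2 µm²/s) is used with a
   warning;
3. `correct_superres()` — the super-resolution image is zeroed outside the
   up-sampled TIRF mask, then outside the D-filtered mask
   (valid ∧ D ≥ threshold). Masks are up-sampled by nearest-neighbour block
   replication (they are categorical). The function reports on-mask D
   mean/SD/COV before and after filtering; the pipeline is idempotent and
   preserves the inclusion chain raw ⊇ TIRF-masked ⊇ D-filtered.

An SNR below ~3 in the structure region makes the filtering unreliable;
`snr()` warns in that regime.

Map-level statistics: `map_correlation()` (Pearson on log₁₀ values by
default, pixels valid in both maps, non-positive values excluded with a
count — validity is intersected before binning the 2-D frequency table);
`profile_fwhm()` (Gaussian profile fit, FWHM = 2√(2 ln 2)·d);
`frc_resolution()` (Fourier ring correlation of odd/even-frame
reconstructions, resolution at the first crossing of the fixed 1/7
threshold — the field-standard criterion, chosen because no alternative is
specified for this workflow).

## The simulator: what it emulates and what it does not

`simulate_stack()` generates the measured data classes with known truth:

* free 2-D Brownian motion on the pixel grid with periodic boundaries and a
  fixed molecule count — concentrations stay stationary, as FCS requires;
* fibre binding as capture within a distance threshold (default one object
  pixel) of a line segment with exponential on/off waiting times discretised
  per frame; release and capture act on the state at the start of each frame
  so a released molecule takes at least one free step (binding rates are
  free parameters of the simulator, not literature values);
* binomially fluorescent k-mers: each subunit is on with probability p for
  the whole trace (maturation, not blinking), giving the 1 + (k−1)p
  brightness ratio by construction;
* detector: Poisson photon counts, optional EMCCD register modelled as
  Gamma(n, scale = gain) conditional on n photoelectrons (the excess noise
  factor ≈ 2 emerges), Gaussian read noise, offset;
* photobleaching as independent exponential lifetimes per fluorescent
  subunit.

Defaults follow the targeted acquisition geometry: 2 ms frames, 240 nm
object pixels, 128 × 128 px, 50 000 frames, ω = 364 nm. Densities and
per-fluorophore count rates are scientific choices (1 molecule/µm², 300
counts/frame — a bright membrane probe on an EMCCD), fixed once.

Not emulated: intra-frame motion blur (positions are sampled once per
frame), 3-D diffusion and the evanescent-field depth profile, dipole
orientation effects, fluorophore blinking photophysics, and chromatic
effects. Passing tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to every property of real data.

## Problem sizes used in validation

The test suite validates parameter recovery on seeded stacks of 16×16–32×32
pixels and 2 500–20 000 frames: map-mean D within 15% on 32 × 32 × 20 000
frames at D = 2 µm²/s with a diffusion-law intercept within 3 SE of zero;
the dimer/monomer brightness ratio within 5% of 1.55 at p = 0.55 on
32 × 32 × 5 000 × 20 ms stacks (D = 0.2 µm²/s, a typical membrane-receptor
mobility, sized so the seed-to-seed SD of the ratio is ~1.5%); and ≥ 95%
artefact removal with ≥ 95% fibre retention in the correction pipeline on a
28 × 28 × 8 000 fixture containing a binding fibre and a slow bright
cluster. These sizes give comfortable
statistical margins for the stated tolerances while keeping the default test
run fast.

## Known limitations

* The finite-trace correlation estimator biases the ACF tail slightly
  negative; fitted G∞ is zero only to ~1% of the amplitude, and diffusion-law
  intercepts inherit a few-millisecond systematic on short traces.
* Per-pixel D distributions are right-skewed at short trace lengths; map
  means converge from above as T grows.
* G1-mode N&B underestimates brightness when the transit time approaches the
  binned frame time (the decorrelation over one lag is then substantial).
* The diffusion-law intercept SE from 5 correlated binnings is optimistic;
  use the classification, not the SE, for inference, and prefer masks with
  many pixels.
* Two-component fits are only as identifiable as the lag range allows;
  the slow off-structure component is reported, never interpreted.
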