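# imfluct

Multi-parametric fluorescence fluctuation microscopy from a single camera
image stack.

A TIRF movie of a fluorescent sample — tens of thousands of frames at
millisecond exposure — contains far more than an average image. `imfluct`
extracts, from one and the same stack:

* **Imaging FCS diffusion maps.** Each pixel's intensity trace is
  bleach-corrected (polynomial detrend of order 8), autocorrelated on a
  multi-tau lag grid with correlator scheme (p, q) = (16, 12), and fitted
  with the camera FCS model

  G(τ) = (1/N) · g(τ)/g(0) + G∞,

  g(τ) = ( √(4Dτ + ω²)/(a√π) · (e^{−a²/(4Dτ+ω²)} − 1) + erf(a/√(4Dτ+ω²)) )²,

  where `a` is the (binned) object-plane pixel side, ω the 1/e² PSF radius,
  `N` the particle number in the observation area and `D` the diffusion
  coefficient. Fits with D outside 0.01–10 µm²/s are flagged invalid.
* **PSF calibration** by binning invariance: for a freely diffusing bilayer,
  D must not depend on pixel binning; the ω minimising the coefficient of
  variation of D across binnings is the calibrated PSF radius.
* **FCS diffusion law.** Transit time τ_d = A_eff/(4D) versus effective area
  A_eff = (binning·a)²/g(0) for square binnings 1–5; a zero intercept means
  free diffusion, positive means domain trapping, negative means meshwork
  corralling.
* **Number & Brightness (N&B)** with dark-frame calibration:
  N = (⟨I⟩−offset)²/(σ²−σ₀²), B = (σ²−σ₀²)/(⟨I⟩−offset); in G1 mode the
  lag-1 covariance replaces σ²−σ₀², rejecting shot and read noise.
* **Oligomer algebra under binomial subunit fluorescence.** If a fluorophore
  matures with probability p, a tandem dimer is only (1+p)× brighter than a
  monomer; a measured dimer/monomer ratio r gives p = r − 1, the dimer
  molecule fraction is m_e = (r−1)/p, and two-species k₁/k₂ mixtures solve
  r = Σf_k(kp(1−p)+k²p²) / Σf_k·kp.
* **Computational super-resolution**: an SRRF-style radiality transform on a
  5× sub-pixel grid (ring radius 0.5 px, 6 axes) compressed by the lag-1
  temporal auto-cumulant (TRAC2), and per-pixel SOFI cumulants of order 2
  and 4.
* **Mutual artifact correction**: the TIRF intensity mask and the
  D-thresholded diffusion map (default threshold 0.2 µm²/s, or the valley of
  a bimodal log₁₀ D histogram) strip false structures from the
  super-resolution image, while the super-resolution image delineates where
  the dynamics belong to fibres.
* **Map statistics**: log-log Pearson correlation between parameter maps,
  SNR of pixel regions, Gaussian FWHM profiles (FWHM = 2√(2 ln 2)·d), and
  Fourier ring correlation resolution at the 1/7 threshold.
* **A seeded TIRF simulator** (free and fibre-binding diffusion, binomially
  fluorescent k-mers, EMCCD gain/offset/read noise, photobleaching) with
  ground truth, so every stage is testable without external data.

## Worked example

```r
library(imfluct)

geom <- acquisition_geometry(camera_pixel_size_um = 24, magnification = 100,
                             psf_e2_radius_nm = 364)
effective_area(geom, 1)                      # [1] 0.4777815  (µm²)
transit_time(effective_area(geom, 1), 2)     # [1] 0.05972268 (s)

# simulate a freely diffusing membrane probe, then recover D per pixel
cfg <- sim_config(width = 32, height = 32, frames = 20000, frame_time = 0.002,
                  geometry = geom,
                  species = list(sim_species(D = 2, density = 1, epsilon = 300)),
                  seed = 7)
sim <- simulate_stack(cfg)
am  <- acf_map(sim$stack, correlator_scheme(16, 12), bleach_order = 8,
               lag_range = c(0.002, 0.5))
fit <- fit_acf_map(am)
fit$D
#> <parameter_map> D [um^2/s] 32 x 32, 1024/1024 valid; mean 2.043, sd 0.5499

dl <- diffusion_law(sim$stack, binnings = 1:5, lag_range = c(0.002, 0.5))
dl
#> <diffusion_law> intercept = 0.001855 +/- 0.001536 s (free), slope = 0.1303 s/um^2

# oligomer fractions from measured brightness ratios
fluorescent_fraction(1.55)                   # [1] 0.55
dimer_fraction(1.35, 0.55)$m_e               # [1] 0.6363636
mixture_solve(1.6, 0.55, c(1, 3))$fractions  #   f1        f3
                                             #   0.7142857 0.2857143
```

The recovered map mean (2.043 µm²/s) sits within ~2% of the simulated truth;
per-pixel scatter (~27%) reflects the finite 40 s trace. The diffusion-law
intercept is consistent with zero — free diffusion — on a 60–285 ms
transit-time scale; note that the 5-point ordinary least-squares SE somewhat
understates the uncertainty because the binnings reuse the same data, so
intercepts within a few SE of zero should be read as free.

A command-line front end is installed with the package
(`system.file("cli/imfluct", package = "imfluct")`), with subcommands
`simulate`, `fcs`, `dlaw`, `nandb`, `oligomer`, `srrf`, `sofi`, `correct`,
`corrmap`, `snr`, `frc`, `psf-calibrate`; every run writes a JSON manifest
of the resolved parameters, input hashes and seed.

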