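---
title: "Phase-encoded wide-field mapping and through-skull resolution estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-encoded wide-field mapping and through-skull resolution estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfmap)
```

# The measurement and its model

Wide-field intrinsic-signal imaging records the backscattered light
intensity $R$ from cortex (here, through the intact skull of an awake
marmoset) while sensory stimuli are presented. Neural activity drives a
local hemodynamic response; the attendant change in hemoglobin absorption
modulates $R$ by a permille-scale relative amount, the intrinsic signal
$\Delta R/R$. Whether activation makes $\Delta R/R$ negative or positive
depends on the illumination wavelength through the HbO/HbR molar
absorptivity ratio; `polarity_table()` carries the empirically determined
sign for the six wavelengths in use, and every analysis multiplies it out
first so that "more response" is always the same direction.

## Phase encoding

All mapping experiments except the category (face-patch) experiment are
phase encoded: a stimulus parameter cycles with period $T$ (tone pips
stepping over 6 octaves in 20 s; a polar-angle wedge sweeping at 0.05
rounds/s; interleaved air puffs, noise bursts and dot-speed ramps at
periods 22, 19.8 and 18 s in one 396 s parcellation session). A pixel
preferring the stimulus presented at cycle time $s$ responds with a
hemodynamic delay $\delta$, so its trace is modeled as

$$x(t) = \mathrm{pol}(\lambda)\, A \cos\!\big(2\pi (t - s - \delta)/T\big) + \varepsilon(t),$$

which is exactly what the session-long Fourier transform reads out:
`pixel_spectrum()` plus `extract_channel_response()` return $A$ (as
$2|c|/N$, so a unit cosine has amplitude 1) and the *raw phase time*
$(s+\delta) \bmod T$ at the channel's frequency bin. Session durations
are integer multiples of every cycle period, so each channel sits on an
exact bin and simultaneous channels are orthogonal; the construction of
`session_config()` enforces this and `extract_channel_response()` refuses
off-bin requests rather than silently accepting spectral leakage. No
windowing or detrending is applied: a constant offset lands in the DC bin
and does not touch the stimulus bins.

Frame timestamps sit at frame centers, and the extraction accounts for
the half-frame offset, so on noiseless exact-bin data phase recovery is
exact rather than half-a-frame biased.

## Hemodynamic delay

The raw phase confounds tuning $s$ with delay $\delta$. Running the same
stimulus forwards and time-reversed and assuming the pixel's delay is the
same in both sessions gives

$$\varphi_{\mathrm{fwd}} = (s + \delta) \bmod T, \qquad
  \varphi_{\mathrm{rev}} = (T - s + \delta) \bmod T,$$

so $\varphi_{\mathrm{fwd}} + \varphi_{\mathrm{rev}} \equiv 2\delta
\pmod T$. `combine_reversed_sessions()` solves this per pixel. The sum
determines $\delta$ only up to $T/2$; of the two candidates the one in
the physiologic window $[0, T/2)$ is taken (measured delays cluster at
3.2--4.4 s, far from $T/2 = 10$ s), and an optional acceptance range can
be supplied as a stronger disambiguator -- it relabels a pixel only when
exactly one candidate is acceptable. Delay statistics are summarized over
the top decile of pixels by response amplitude (`select_candidates()`,
ties broken by row-major order for determinism) inside the closed
acceptance interval 2.0--5.7 s (`summarize_delay()`); the per-subject
means of the published experiments average to 3.9 s (tonotopy) and 3.5 s
(polar-angle retinotopy), which are the `default_delay()` values used to
decode single sessions (3.7 s elsewhere).

## Rendering conventions

`render_hsv()` encodes tuning phase as hue on a cyclic wheel and
amplitude as saturation and value, clipped at the 99th percentile of
valid-pixel amplitudes by default (subject-specific percentiles and
absolute limits are `render_spec()` parameters). The hue wheel's zero
point and direction are configurable because the published wheels are
defined only pictorially. Tonotopy maps additionally invalidate pixels
phased into the silences or with out-of-range delays
(`tonotopy_validity()`). Multi-frequency summaries write each channel's
clipped amplitude into an RGB plane for pixels phased into that channel's
most-intense-stimulus window with 1 s tolerance on either side
(`render_rgb_summary()`); the retinotopy composite puts polar angle in
hue, eccentricity in saturation (center-preferring pixels render white)
and motion amplitude in value. Landscape assembly uses landmark-based
least-squares affine co-registration (`estimate_affine()` /
`apply_affine()`, bilinear for scalars, nearest-neighbor for masks) and
iso-t contours (`iso_t_contours()`) rather than any automatic feature
matching. Right-hemisphere mirroring is an explicit display flag, never a
silent data transformation.

## Trial-based statistics

For category experiments each trial is normalized to its first-2 s
baseline and polarity-compensated (`normalize_trials()`), a scalar
response is the 4--10 s window mean (`trial_response_values()`), and
group contrasts use the Welch $t$ statistic
$t = (\bar X_1 - \bar X_2)/\sqrt{s_1^2/N_1 + s_2^2/N_2}$ with sample
($n-1$) standard deviations (`welch_t_map()`). Maps are thresholded on
$t$ directly (2.0 and 3.4, i.e. two-tailed $p<0.05$ and $p<0.001$ at the
trial counts in use); no degrees of freedom, p-values or multiple-testing
correction are attached, matching how such maps are read. Note one
deliberate inconsistency inherited from the conventions being
reproduced: the SEM used for trace shading (`sem_trace()`) uses the
biased divide-by-$n$ variance, while Welch's $t$ uses $n-1$; both are
implemented exactly as defined and documented. The face-patch
differential map is the face mean minus the *maximum* of the other
categories' means, using the same response window (the window is assumed
shared since no separate one is defined).

# The synthetic-data generator

`synthesize_movie()` is the package's ground-truth instrument: per-pixel
preferred time, amplitude, delay and modality membership are planted and
the movie is built from the cosine response model above, summing channels
linearly and adding i.i.d. Gaussian noise per frame.

Design choices, and what they imply about test evidence:

* **Cosine kernel by default.** The analysis is a cosine fit, so a cosine
  plant makes recovery exact and lets round-trip tests assert tight
  numerical bounds. A `raised_cosine` bump (default width 4 s) exists for
  realism -- real responses are transient -- at the cost of a
  kernel-dependent attenuation of the fundamental amplitude.
* **Gaussian, not Poisson, noise at the $\Delta R/R$ level.** After
  4x16-fold spatiotemporal binning the shot-noise limit is well into the
  Gaussian regime, and the empirical noise floor is quantified as a
  relative sd anyway (`shot_noise_floor()` exposes the photon budget as
  an explicit input rather than guessing sensor constants).
* **Linear channel summation.** Simultaneous multi-frequency mapping
  assumes frequency-domain separability; orthogonal exact bins make this
  true for the planted model.

What the generator does *not* emulate: vascular artifacts, breathing and
heartbeat periodicities, slow drifts, motion, or skull-texture
inhomogeneity. Passing tests therefore demonstrate the correctness of
the analysis pipeline's arithmetic and its noise behavior under the
stated model, not robustness to structured physiological confounds.

# Photon transport and the lateral-resolution estimate

The through-skull point-spread question -- over what lateral scale does a
focal absorption change in gray matter influence the light collected at a
point on the skull -- is answered with a layered perturbation Monte
Carlo (`simulate_photons()`, `perturbation_profile()`).

* **Geometry.** A 10 mm cube of skull (0.5 mm, $n=1.56$), gray matter
  (1.3 mm) and white matter (8.2 mm, both $n=1.37$) in air; optical
  coefficients per wavelength from the shipped table
  (`optical_properties()`). Skull scattering follows
  $\mu_s'(\lambda) = 1533.01\,\lambda^{-0.65}$ mm$^{-1}$
  (`skull_mus_prime()`); brain absorption from a 3% blood volume
  fraction at 2 mM hemoglobin, 25% HbR / 75% HbO
  (`brain_absorption()`). The source table lists the power-law values in
  its $\mu_s$ column while naming them reduced coefficients; the
  tabulated numbers are treated as $\mu_s$ with $g$ applied separately,
  and the inconsistency is simply recorded rather than resolved.
* **Transport.** By reciprocity, photons are launched at the detection
  point, uniformly over the NA $\le$ 0.03 cone, and collected if they
  exit the top face within the same cone (angle-only collection -- the
  stated criterion names only the exit angle, which matches reciprocity
  with a point detector). Propagation is absorption-free with
  exponential step lengths, Henyey--Greenstein scattering with
  layer-specific $g$, and Snell refraction with unpolarized Fresnel
  reflectance (including total internal reflection) at every interface.
  Photons die when their cumulative path exceeds 300 mm, where any
  realistic Beer weight is below $10^{-30}$; there is no Russian
  roulette because weights are applied post hoc. Polarization is not
  tracked: the 0.5 mm skull exceeds the depolarization length
  $1/\mu_s'$ of green light, so photons reaching gray matter are
  depolarized regardless.
* **Perturbation weighting.** Each collected photon's per-layer path
  lengths give its Beer weight $W = e^{-\sum_i \mu_a(i) x(i)}$
  (`beer_weight()`). Raising one 0.033 mm gray-matter voxel column's
  absorption by 10% changes the detected intensity by
  $\sum_p W_p (1 - e^{-0.1 \mu_a x_v(p)})$ -- the exact exponential
  difference, identical to recomputing the full weight with the
  perturbed coefficient (a property the tests assert to $10^{-12}$); the
  linearized first-order shortcut is deliberately not used.

## Estimator variance at desk-scale budgets

Only $\sim 7 \times 10^{-4}$ of launched photons survive the narrow
collection cone, and their Beer weights are heavy-tailed, so at a
desk-scale budget of $10^7$ launched photons the raw per-voxel profile is
noisy exactly where it matters -- near the axis, where few trajectories
cross any single 0.033 mm column. Two measures address this without
touching the physics:

1. **Azimuthal averaging during scoring.** Launch and collection are
   axially symmetric about the optical axis, so any rotation of a
   collected trajectory is an equally probable one. Each trajectory is
   scored against `n_rotations` (default 32) stratified rotations of the
   center voxel row, a conditional Monte Carlo average over an exact
   symmetry of the problem. (The square lateral walls break the symmetry
   only for trajectories that reach them, whose near-axis contributions
   are negligible.)
2. **Radial folding for the FWHM readout.** The FWHM is interpolated at
   half maximum on the azimuthally folded radial profile, binned at 5
   voxels (0.165 mm, about a quarter of the expected width), rather than
   on the raw per-voxel profile whose single-voxel maximum is an
   extreme-value statistic below $\sim 10^8$ photons. The bin width
   slightly flattens the central cusp (biasing FWHM marginally upward)
   in exchange for stable per-bin means; $\sigma$, an integral quantity,
   is computed from the raw normalized profile. The raw profile and the
   folded profile are both returned.

At $10^7$ photons (the problem size used by the acceptance script and
the resolution test; about 8--9 minutes on one CPU) the green-light
profile's FWHM evaluates to approximately 0.6 mm with a seed-to-seed
spread of a few hundredths of a millimeter, consistent with the
0.60--0.70 mm bracket that the empirical skull-diffusion comparison
produces independently.

`defocus_tolerance()` is the companion geometric-optics closed form
$h \ge D n / (2\,\mathrm{NA})$: with NA 0.03 a target must lie 5 mm from
the focal plane before its blur reaches 0.3 mm, half the functional
resolution scale -- which is why a curved skull surface can be mapped in
one field of view.

# Cross-resolution map comparison

To ask what effective resolution one map has relative to a sharper map
of the same cortex, `diffuse_map()` blurs the sharper map in the complex
plane ($A e^{i 2\pi s/T}$, so mixed opposing phases cancel as physical
mixing would), with a kernel obtained by radially interpolating a
simulated sensitivity profile and rescaling its offset axis to a target
FWHM. Border effects are removed by renormalizing with the convolved
all-ones map, making constant fields exact fixed points; a target at or
below the pixel pitch is below the sampling resolution and returns the
map unchanged. `scan_diffusion_scales()` repeats this over a grid of
scales and fits two models on candidate pixels (amplitude thresholds in
both maps, valid tuning, optional region mask): a no-intercept linear
model between amplitudes and a linear model between tunings on the
octave scale ($\log_2 f/440$). The $r^2$-maximizing scales are the
effective-resolution estimates. Fits are ordinary least squares by
default in the scan (the closed forms serve as oracles); a robust
bisquare IRLS mode (`MASS::rlm`) is available and agrees with OLS on
clean data.

# Numerical choices and degenerate inputs

* Invalid pixels (zero/negative baselines, zero amplitude) become NA and
  propagate; they are masked, never silently imputed.
* `sem_trace()` with one repetition returns 0, as its formula dictates;
  `welch_t_map()` masks pixels where both group variances vanish.
* Candidate-selection ties break by row-major pixel order; acceptance
  ranges are closed intervals.
* The movie TIFF writer rescales into the unit interval (recording the
  scale in the JSON sidecar) because the underlying writer clamps values
  outside it; NA pixels are encoded as exact zeros.
* The photon simulator uses its own counter-seeded xoshiro256++ stream:
  results are bit-reproducible for a given seed and independent of R's
  RNG state.
* Problem sizes in the test suite (synthetic grids of $10^2$--$10^3$
  pixels, $2 \times 10^5$--$10^7$ photons) were chosen as the smallest
  that make each assertion sharp at its stated tolerance.

# Known limitations

* The delay model is a single phase lag per pixel; no full hemodynamic
  response function is deconvolved.
* Only the fundamental of each stimulation frequency is analyzed.
* The transport model omits polarization, the dura, skull-thickness
  variation and curvature; its resolution estimate is for the idealized
  flat three-layer stack.
* Real-data confounds (vessels, motion, physiological rhythms) are out
  of the generator's scope, as noted above.
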