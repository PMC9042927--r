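# wfmap

Analysis toolkit for **wide-field intrinsic-signal optical imaging**,
built around the through-skull mapping workflow: phase-encoded Fourier
mapping of periodic sensory stimulation, hemodynamic-delay cancellation
with temporally mirrored session pairs, multi-modality parcellation,
HSV/RGB tuning-map rendering and landmark-based map co-registration,
trial-based category statistics (Welch *t* maps, differential maps), and
a layered-tissue perturbation Monte Carlo that predicts the method's
lateral resolution. A synthetic-movie generator with planted per-pixel
ground truth backs every analysis stage with testable expectations.

Intended users: systems neuroscientists and imaging methodologists who
record stimulus-locked wide-field movies (through skull, thinned skull or
cranial windows) and want a tested, scriptable implementation of the
standard phase-encoding analysis chain and of the optical physics that
sets its resolution.

## The model in brief

A pixel preferring the stimulus presented at cycle time $s$ (period $T$)
responds with hemodynamic delay $\delta$ and wavelength-dependent
polarity:

$$x(t) \;=\; \mathrm{pol}(\lambda)\, A \cos\!\big(2\pi(t-s-\delta)/T\big) + \varepsilon(t).$$

The session-long Fourier transform at the stimulation frequency returns
amplitude $A$ and raw phase $(s+\delta) \bmod T$. Pairing a session with
its time-reversed twin gives
$\varphi_\mathrm{fwd} + \varphi_\mathrm{rev} \equiv 2\delta \pmod T$,
which separates tuning from delay per pixel. Trial-based contrasts use
Welch's statistic
$t = (\bar X_1 - \bar X_2)\,/\,\sqrt{s_1^2/N_1 + s_2^2/N_2}$.

The resolution question — over what lateral scale does a focal
absorption change in gray matter affect light collected at a point on
the skull — is answered by reciprocity Monte Carlo: photons launched at
the detection point within the NA 0.03 cone through skull / gray / white
layers (Henyey–Greenstein scattering, Fresnel/Snell boundaries,
absorption-free propagation), Beer-weighted post hoc with
$W = e^{-\sum_i \mu_a(i) x(i)}$, and re-weighted under a 10% absorption
perturbation per 0.033 mm gray-matter voxel column. The normalized
lateral profile of the intensity change is the sensitivity profile; its
FWHM is the resolution estimate (≈ 0.6 mm for green light through a
0.5 mm skull).

## Worked example

Plant a tonotopic gradient with a 3.9 s hemodynamic delay on a 30 × 40
patch, synthesize the upward and downward 400 s sessions at 0.5 ‰
per-frame noise, and recover the delay and tuning map:

```r
library(wfmap)

up   <- tone_sequence(440, 73, +1)          # 73 pips, +1 semitone each
down <- reverse_tone_sequence(up)
cfg_up   <- session_config(build_tone_channel(up),   wavelength_nm = 530)
cfg_down <- session_config(build_tone_channel(down), wavelength_nm = 530)

nr <- 30; nc <- 40
pref <- matrix(rep(seq(3, 17, length.out = nc), each = nr), nr, nc)
amp  <- matrix(1e-3, nr, nc)                # 1 permille responses
mk <- function(pref, seed)
  synthesize_movie(
    ground_truth(list(tones = list(preferred_time_s = pref,
                                   amplitude = amp)), delay_s = 3.9),
    cfg_up, noise_sd_permille = 0.5, seed = seed)
mov_up   <- mk(pref, seed = 1)
mov_down <- mk((20 - pref) %% 20, seed = 2)

ch  <- cfg_up$channels[[1]]
fwd <- extract_channel_response(pixel_spectrum(mov_up), ch)
rev <- extract_channel_response(pixel_spectrum(mov_down), ch)
tm  <- combine_reversed_sessions(fwd, rev)

mask <- select_candidates(tm, 0.10)         # top decile by amplitude
summarize_delay(tm$delay_s, mask, accept_range = c(2.0, 5.7))
img <- render_hsv(tm, render_spec(percentile = 99))
```

Output:

```
mean hemodynamic delay: 3.90 s over 120 candidate pixels
median tuning-phase error: 0.025 s
rendered map: 30 x 40 RGB, 100% of pixels valid
```

The planted 3.9 s delay is recovered exactly to two decimals from the
mirrored pair, the tuning phases are accurate to ~1/8 frame despite the
noise, and the HSV map encodes phase as hue and amplitude as
saturation/value clipped at the 99th percentile.

The photon-transport side runs the same way:

```r
med <- medium_stack(530)                    # skull/gray/white at 530 nm
ph  <- simulate_photons(med, n_photons = 1e7, seed = 1)
pr  <- perturbation_profile(ph)             # 10% voxel perturbation
pr$fwhm_mm                                  # lateral resolution, mm
```

A thin CLI over these functions is installed at
`inst/scripts/wfmap` (`wfmap schedule|simulate|parcellate|delay|mc`).

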