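# shared fixtures, all generated in code

# a single-channel session at the standard tonotopy timing
std_session <- function(n_cycles = 20, frame_rate_hz = 5,
                        wavelength_nm = 530, label = "tones") {
  ch <- build_tone_channel(tone_sequence(), n_cycles = n_cycles,
                           label = label)
  session_config(ch, frame_rate_hz = frame_rate_hz,
                 wavelength_nm = wavelength_nm)
}

# plant uniform-random preferred times and a delay map on an nr x nc grid
random_truth <- function(nr, nc, period_s = 20, delay = 3.9,
                         amplitude = 1e-3, label = "tones", seed = 42) {
  set.seed(seed)
  s <- matrix(runif(nr * nc, 0, period_s), nr, nc)
  d <- if (is.matrix(delay)) delay else matrix(delay, nr, nc)
  ground_truth(
    channels = setNames(list(list(preferred_time_s = s,
                                  amplitude = matrix(amplitude, nr, nc))),
                        label),
    delay_s = d)
}

# forward/reverse mirrored sessions for planted (s, delta): the reversed
# session prefers (T - s) mod T with the same per-pixel delay
mirrored_response_maps <- function(s, delta, period_s = 20,
                                   amplitude = 1e-3, frame_rate_hz = 5,
                                   n_cycles = 20) {
  nr <- nrow(s); nc <- ncol(s)
  cfg <- std_session(n_cycles = n_cycles, frame_rate_hz = frame_rate_hz)
  ch <- cfg$channels[[1]]
  mk <- function(pref) {
    tr <- ground_truth(
      channels = list(tones = list(preferred_time_s = pref,
                                   amplitude = matrix(amplitude, nr, nc))),
      delay_s = delta)
    mov <- synthesize_movie(tr, cfg, noise_sd_permille = 0)
    extract_channel_response(pixel_spectrum(mov), ch)
  }
  list(fwd = mk(s), rev = mk((period_s - s) %% period_s), config = cfg)
}

# hand-made tuning map
mk_tuning_map <- function(phase, amp, period_s = 20, delay = NULL) {
  tuning_map(phase, amp, period_s, delay_s = delay)
}

# synthetic Gaussian lateral sensitivity profile with a known FWHM
gauss_profile <- function(fwhm_mm = 0.63, pitch = 0.033, half_mm = 2.5) {
  off <- seq(-half_mm, half_mm, by = pitch)
  sens <- exp(-4 * log(2) * (off / fwhm_mm)^2)
  structure(list(profile = data.frame(offset_mm = off,
                                      delta_r = sens, sensitivity = sens),
                 fwhm_mm = fwhm_mm,
                 sigma_mm = fwhm_mm / (2 * sqrt(2 * log(2)))),
            class = "wf_sensitivity_profile")
}

# minimal hand-built photon set for Beer-weight algebra tests
fake_photons <- function(layer_paths, voxel = NULL, pitch = 0.033,
                         voxel_layer = 2L) {
  structure(
    list(layer_paths = layer_paths,
         voxel = voxel %||% data.frame(photon = integer(), rot = integer(),
                                       ix = integer(), path_mm = numeric()),
         n_launched = nrow(layer_paths), n_collected = nrow(layer_paths),
         n_escaped = 0, n_terminated = 0, na = 0.03, seed = 0,
         voxel_layer = voxel_layer, voxel_pitch_mm = pitch,
         n_rotations = 1L,
         medium = medium_stack(530)),
    class = "wf_photons")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
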