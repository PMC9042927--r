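#' Intrinsic-signal polarity by wavelength
#'
#' Whether increased cortical activity raises or lowers backscattered
#' intensity depends on the illumination wavelength through the HbO/HbR
#' molar absorptivity ratio: wavelengths that emphasize the stimulus-evoked
#' HbO increase are absorbed more during the response (negative dR/R),
#' wavelengths that emphasize the HbR decrease less (positive dR/R). The
#' empirically determined signs for the six tested wavelengths are
#' negative for 470 (blue), 530 (green) and 850 nm (NIR), positive for
#' 625 (red) and 730 nm (far-red), and ambiguous-but-presumably-positive
#' for 590 nm (amber).
#'
#' @return data.frame with columns `wavelength_nm`, `sign`, `ambiguous`.
#' @export
polarity_table <- function() {
  data.frame(
    wavelength_nm = c(470, 530, 590, 625, 730, 850),
    sign          = c(-1L, -1L, +1L, +1L, +1L, -1L),
    ambiguous     = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
}

#' @rdname polarity_table
#' @param wavelength_nm one of the tabulated wavelengths.
#' @export
polarity_sign <- function(wavelength_nm) {
  tab <- polarity_table()
  i <- match(wavelength_nm, tab$wavelength_nm)
  if (is.na(i)) stop("no tabulated polarity for ", wavelength_nm, " nm")
  tab$sign[i]
}

#' Per-pixel spectrum of a relative movie
#'
#' Discrete Fourier transform of every pixel trace along time. Bin `k`
#' (0-based) corresponds to frequency `k / duration`; a channel repeating
#' `n_cycles` times within the session therefore lands exactly on bin
#' `n_cycles`. No windowing or detrending is applied: the constant offset
#' lands in the DC bin and is harmless, and session durations are exact
#' multiples of every cycle period so there is no leakage to suppress.
#'
#' @param movie a relative [movie()].
#' @return object of class `wf_spectrum` holding the complex coefficient
#'   array (frequency bins x rows x cols) plus timing metadata.
#' @export
pixel_spectrum <- function(movie) {
  if (movie$kind != "relative")
    stop("`movie` must be of kind 'relative' (see to_relative())")
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, nrow = d[1])
  na_pix <- colSums(is.na(flat)) > 0
  flat[, na_pix] <- 0  # masked pixels carry no spectrum; re-flagged below
  co <- stats::mvfft(flat)
  co[, na_pix] <- NA_complex_
  structure(
    list(coef = array(co, dim = d), n_frames = d[1],
         frame_rate_hz = movie$frame_rate_hz,
         duration_s = d[1] / movie$frame_rate_hz,
         wavelength_nm = movie$wavelength_nm),
    class = "wf_spectrum")
}

#' Extract a channel's response map from a pixel spectrum
#'
#' Reads the complex coefficient at the channel's stimulation frequency,
#' multiplies by the signal polarity, and converts to amplitude and phase:
#' `amplitude = 2|c|/N` (so a unit cosine yields amplitude 1, making
#' dR/R amplitudes directly comparable to trace excursions) and
#' `raw_phase_time` in seconds within the cycle, defined so that a
#' noise-free polarity-compensated cosine peaking at within-cycle time `t0`
#' yields `raw_phase_time = t0`. Frame-center timestamps are accounted for,
#' so recovery on noiseless exact-bin data is exact. The channel frequency
#' must be an exact spectral bin; anything else would silently corrupt
#' phases through leakage and is an error.
#'
#' @param spectrum a [pixel_spectrum()].
#' @param channel a [stimulus_channel()].
#' @param polarity +1 or -1; defaults to the tabulated sign for the
#'   spectrum's wavelength.
#' @return object of class `wf_response_map`: `amplitude`, `phase_time_s`
#'   (both rows x cols), `period_s`, `label`, `valid`.
#' @export
extract_channel_response <- function(spectrum, channel, polarity = NULL) {
  Tc <- channel$cycle_period_s
  k <- spectrum$duration_s / Tc
  if (abs(k - round(k)) > 1e-6)
    stop("channel '", channel$label, "' frequency ", signif(1 / Tc, 6),
         " Hz is not an exact spectral bin (duration ",
         spectrum$duration_s, " s); refusing to extract a leaky phase")
  k <- as.integer(round(k))
  if (k < 1L || k >= spectrum$n_frames %/% 2L)
    stop("channel frequency outside the resolvable band")
  if (is.null(polarity)) {
    if (is.null(spectrum$wavelength_nm))
      stop("no polarity given and the spectrum has no wavelength")
    polarity <- polarity_sign(spectrum$wavelength_nm)
  }
  co <- polarity * array(spectrum$coef[k + 1L, , ],
                         dim = dim(spectrum$coef)[2:3])
  N <- spectrum$n_frames
  amplitude <- 2 * Mod(co) / N
  dt <- 1 / spectrum$frame_rate_hz
  # cosine peaking at t0 sampled at frame centers has arg(c) = 2*pi*f*(dt/2 - t0)
  phase <- (dt / 2 - Arg(co) * Tc / (2 * pi)) %% Tc
  valid <- is.finite(amplitude) & amplitude > 0
  phase[!valid] <- NA_real_
  structure(
    list(amplitude = amplitude, phase_time_s = phase, period_s = Tc,
         label = channel$label, polarity_compensated = TRUE,
         valid = valid),
    class = "wf_response_map")
}

#' @export
print.wf_response_map <- function(x, ...) {
  cat(sprintf("<wf_response_map> '%s' %d x %d, T = %gs, %d valid px\n",
              x$label, nrow(x$amplitude), ncol(x$amplitude), x$period_s,
              sum(x$valid)))
  invisible(x)
}

#' Default hemodynamic delays for single-session analyses
#'
#' Group-average delays derived from mirrored-session pairs: 3.9 s for
#' tonotopy, 3.5 s for retinotopy polar-angle mapping, and 3.7 s for all
#' other single-session tuning analyses.
#'
#' @param experiment `"tonotopy"`, `"retinotopy_polar"` or `"other"`.
#' @export
default_delay <- function(experiment = c("other", "tonotopy",
                                         "retinotopy_polar")) {
  switch(match.arg(experiment),
         tonotopy = 3.9, retinotopy_polar = 3.5, other = 3.7)
}

#' Compensate a fixed hemodynamic delay
#'
#' Subtracts a scalar hemodynamic delay from the raw response phase,
#' modulo the cycle period, turning a response-phase map into a tuning
#' (preferred-stimulus-time) map.
#'
#' @param map a polarity-compensated [extract_channel_response()] map.
#' @param delay_s delay to subtract in seconds (see [default_delay()]).
#' @return object of class `wf_tuning_map` with `tuning_phase_s`,
#'   `amplitude`, `delay_s`, `period_s`, `valid`.
#' @export
compensate_delay <- function(map, delay_s = default_delay("other")) {
  if (!isTRUE(map$polarity_compensated))
    stop("map must be polarity-compensated before delay compensation")
  tuning_map(tuning_phase_s = (map$phase_time_s - delay_s) %% map$period_s,
             amplitude = map$amplitude, period_s = map$period_s,
             delay_s = delay_s, valid = map$valid, label = map$label)
}

#' Construct a tuning map
#'
#' Per-pixel preferred-stimulus time within the cycle, response amplitude,
#' optional hemodynamic delay (scalar or per-pixel), and validity mask.
#'
#' @param tuning_phase_s,amplitude rows x cols numeric matrices.
#' @param period_s cycle period (s).
#' @param delay_s scalar or matrix of delays, or NULL.
#' @param valid logical matrix; defaults to finite amplitude > 0.
#' @param label channel label.
#' @export
tuning_map <- function(tuning_phase_s, amplitude, period_s, delay_s = NULL,
                       valid = NULL, label = "") {
  if (!all(dim(tuning_phase_s) == dim(amplitude)))
    stop("phase and amplitude geometries differ")
  if (is.null(valid))
    valid <- is.finite(amplitude) & amplitude > 0 &
             is.finite(tuning_phase_s)
  structure(
    list(tuning_phase_s = tuning_phase_s, amplitude = amplitude,
         period_s = period_s, delay_s = delay_s, valid = valid,
         label = label),
    class = "wf_tuning_map")
}

#' @export
print.wf_tuning_map <- function(x, ...) {
  cat(sprintf("<wf_tuning_map> '%s' %d x %d, T = %gs, %d valid px\n",
              x$label, nrow(x$amplitude), ncol(x$amplitude), x$period_s,
              sum(x$valid)))
  invisible(x)
}

#' Simultaneous multi-modality parcellation
#'
#' Extracts one response map per channel from a single session movie.
#' Because each channel's stimulation frequency is a distinct exact
#' spectral bin, the channels do not interfere in the noise-free limit
#' (orthogonality of Fourier bins): one session suffices to map several
#' modalities simultaneously.
#'
#' @param movie a relative [movie()] of the session.
#' @param config the [session_config()] describing the channels.
#' @param delay_s optional fixed delay passed on to [compensate_delay()];
#'   `NULL` returns raw response-phase maps.
#' @return named list of `wf_response_map`s (or `wf_tuning_map`s when
#'   `delay_s` is given), one per channel.
#' @export
parcellate <- function(movie, config, delay_s = NULL) {
  bins <- vapply(config$channels, function(ch)
    round(config$duration_s / ch$cycle_period_s), numeric(1))
  if (anyDuplicated(bins))
    stop("two channels share a spectral bin; their periods are not distinct")
  nf <- dim(movie$frames)[1]
  if (abs(nf / movie$frame_rate_hz - config$duration_s) > 1e-6)
    stop("movie duration does not match the session configuration")
  spec <- pixel_spectrum(movie)
  pol <- polarity_sign(config$wavelength_nm)
  maps <- lapply(config$channels, function(ch) {
    m <- extract_channel_response(spec, ch, polarity = pol)
    if (!is.null(delay_s)) m <- compensate_delay(m, delay_s)
    m
  })
  names(maps) <- vapply(config$channels, `[[`, "", "label")
  maps
}
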