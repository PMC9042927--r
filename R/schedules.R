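#' Stimulus channel of a phase-encoded session
#'
#' One periodically repeating stimulus stream: a cycle period, a cycle
#' count, and a within-cycle event timeline. The event `level` is an
#' abstract per-channel scalar (tone frequency in Hz, polar angle in
#' degrees, eccentricity band midpoint, puff target id); `weight` marks
#' stimulus intensity so summary-mask rendering can find the peak-stimulus
#' window generically. For swept stimuli an optional `level_at(t)` function
#' gives the swept parameter as a function of within-cycle time.
#'
#' @param label channel name.
#' @param cycle_period_s cycle period in seconds.
#' @param n_cycles number of cycles in the session.
#' @param events data.frame with columns `onset_s`, `duration_s`, `level`
#'   and optionally `weight` (defaults to 1); onsets are within-cycle.
#' @param level_at optional function of within-cycle time -> stimulus level.
#' @return object of class `wf_channel`.
#' @export
stimulus_channel <- function(label, cycle_period_s, n_cycles,
                             events = NULL, level_at = NULL) {
  if (cycle_period_s <= 0) stop("cycle period must be positive")
  if (n_cycles < 1) stop("need at least one cycle")
  if (is.null(events))
    events <- data.frame(onset_s = numeric(), duration_s = numeric(),
                         level = numeric(), weight = numeric())
  if (is.null(events$weight)) events$weight <- rep(1, nrow(events))
  if (nrow(events) &&
      any(events$onset_s + events$duration_s > cycle_period_s + 1e-9))
    stop("event extends past the cycle period in channel '", label, "'")
  structure(
    list(label = label, cycle_period_s = cycle_period_s,
         n_cycles = n_cycles, events = events, level_at = level_at),
    class = "wf_channel")
}

#' Session configuration
#'
#' Groups the channels of one recording session with the acquisition
#' parameters. Construction asserts that the session duration is an exact
#' integer multiple of every channel's cycle period, which guarantees each
#' channel's stimulation frequency falls on an exact spectral bin of the
#' session-long Fourier transform (bin spacing `1/duration`).
#'
#' @param channels list of [stimulus_channel()]s.
#' @param frame_rate_hz acquisition frame rate (after binning).
#' @param duration_s session duration in seconds; defaults to the common
#'   `n_cycles * cycle_period_s` of the channels.
#' @param wavelength_nm illumination wavelength (drives signal polarity).
#' @return object of class `wf_session`.
#' @export
session_config <- function(channels, frame_rate_hz = 5,
                           duration_s = NULL, wavelength_nm = 530) {
  if (inherits(channels, "wf_channel")) channels <- list(channels)
  durs <- vapply(channels, function(ch) ch$n_cycles * ch$cycle_period_s,
                 numeric(1))
  if (is.null(duration_s)) duration_s <- durs[1]
  if (any(abs(durs - duration_s) > 1e-6))
    stop("channel durations differ from the session duration: ",
         paste(sprintf("%s=%gs", vapply(channels, `[[`, "", "label"), durs),
               collapse = ", "),
         " vs session ", duration_s, "s")
  # each channel frequency must be an integer harmonic of 1/duration
  for (ch in channels) {
    k <- duration_s / ch$cycle_period_s
    if (abs(k - round(k)) > 1e-6)
      stop("channel '", ch$label, "' frequency is not an exact spectral bin")
  }
  structure(
    list(channels = channels, frame_rate_hz = frame_rate_hz,
         duration_s = duration_s, wavelength_nm = wavelength_nm),
    class = "wf_session")
}

#' @export
print.wf_session <- function(x, ...) {
  cat(sprintf("<wf_session> %gs @ %g fps, %g nm, %d channel(s)\n",
              x$duration_s, x$frame_rate_hz, x$wavelength_nm,
              length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  %s: T = %gs x %d cycles\n", ch$label, ch$cycle_period_s,
                ch$n_cycles))
  invisible(x)
}

#' Pure-tone pip sequence in geometric semitone steps
#'
#' Pip `k` (1-based) has frequency `start_hz * 2^((k-1) * step/12)` and
#' center time `pre_silence + (k-1)*pip_duration + pip_duration/2` within
#' the trial. The standard tonotopy trial is 2.7 s silence + 73 pips of
#' 0.2 s + 2.7 s silence = 20 s, spanning 6 octaves (440 Hz to 28,160 Hz
#' upward at +1 semitone per pip).
#'
#' @param start_hz frequency of the first pip (Hz).
#' @param n_pips number of pips.
#' @param step_semitones signed semitone step between consecutive pips.
#' @param pip_duration_s pip duration in seconds.
#' @param pre_silence_s,post_silence_s flanking silences in seconds.
#' @return object of class `wf_tone_sequence` with fields plus computed
#'   `frequencies_hz`, `center_times_s`, `trial_duration_s`, `tone_window_s`.
#' @export
tone_sequence <- function(start_hz = 440, n_pips = 73, step_semitones = 1,
                          pip_duration_s = 0.2, pre_silence_s = 2.7,
                          post_silence_s = 2.7) {
  if (start_hz <= 0) stop("start frequency must be positive")
  if (n_pips < 1) stop("need at least one pip")
  k <- seq_len(n_pips) - 1
  freqs <- start_hz * 2^(k * step_semitones / 12)
  centers <- pre_silence_s + k * pip_duration_s + pip_duration_s / 2
  dur <- pre_silence_s + n_pips * pip_duration_s + post_silence_s
  structure(
    list(start_hz = start_hz, n_pips = n_pips,
         step_semitones = step_semitones, pip_duration_s = pip_duration_s,
         pre_silence_s = pre_silence_s, post_silence_s = post_silence_s,
         frequencies_hz = freqs, center_times_s = centers,
         trial_duration_s = dur,
         tone_window_s = c(pre_silence_s, pre_silence_s +
                             n_pips * pip_duration_s)),
    class = "wf_tone_sequence")
}

#' Reverse a tone sequence in time (upward <-> downward trial)
#' @param seq a [tone_sequence()].
#' @export
reverse_tone_sequence <- function(seq) {
  tone_sequence(seq$frequencies_hz[seq$n_pips], seq$n_pips,
                -seq$step_semitones, seq$pip_duration_s,
                seq$post_silence_s, seq$pre_silence_s)
}

#' Tonotopy channel from a tone sequence
#'
#' Wraps a pip sequence into a [stimulus_channel()] whose events are the
#' pips (level = frequency in Hz) and whose `level_at` maps within-cycle
#' time to the instantaneous pip frequency (NA in the silences).
#'
#' @param seq a [tone_sequence()].
#' @param n_cycles cycles per session (default 20 -> a 400 s session).
#' @param label channel label.
#' @export
build_tone_channel <- function(seq, n_cycles = 20, label = "tones") {
  ev <- data.frame(onset_s = seq$center_times_s - seq$pip_duration_s / 2,
                   duration_s = seq$pip_duration_s,
                   level = seq$frequencies_hz, weight = 1)
  lv <- function(t) {
    t <- t %% seq$trial_duration_s
    k <- floor((t - seq$pre_silence_s) / seq$pip_duration_s)
    out <- rep(NA_real_, length(t))
    ok <- k >= 0 & k < seq$n_pips
    out[ok] <- seq$frequencies_hz[k[ok] + 1]
    out
  }
  stimulus_channel(label, seq$trial_duration_s, n_cycles, ev, level_at = lv)
}

#' Multi-modality parcellation schedule
#'
#' A single session drives three modalities at distinct cycle periods so
#' that each lands on its own spectral bin: air-puff trains (somatosensory),
#' noise-burst trains (auditory) and a moving-dot speed ramp (visual), each
#' stimulus train centered in its cycle. The default periods (22, 19.8,
#' 18) s repeated for (18, 20, 22) cycles share a common 396 s session.
#'
#' @param periods_s cycle periods per channel, seconds.
#' @param n_cycles cycles per channel; `periods_s * n_cycles` must agree.
#' @param stim_durations_s duration of the centered stimulus train in each
#'   cycle (the visual entry is the full ramp envelope; its plateau --
#'   the most intense stimulus -- is marked with weight 1, the ramps 0.5).
#' @param labels channel labels.
#' @param frame_rate_hz,wavelength_nm acquisition parameters.
#' @return a [session_config()].
#' @export
build_parcellation_schedule <- function(periods_s = c(22, 19.8, 18),
                                        n_cycles = c(18, 20, 22),
                                        stim_durations_s = c(6, 9.8, 14),
                                        labels = c("SOM", "AUD", "VIS"),
                                        frame_rate_hz = 5,
                                        wavelength_nm = 530) {
  durs <- periods_s * n_cycles
  if (any(abs(durs - durs[1]) > 1e-6))
    stop("inconsistent channel durations: ",
         paste(sprintf("%s = %g x %d = %gs", labels, periods_s, n_cycles,
                       durs), collapse = ", "))
  chans <- vector("list", length(periods_s))
  for (i in seq_along(periods_s)) {
    Tc <- periods_s[i]; sd_ <- stim_durations_s[i]
    onset <- (Tc - sd_) / 2
    ev <- if (identical(labels[i], "VIS") && abs(Tc - 18) < 1e-9) {
      # standard 18 s speed ramp: 2 s still, up 5 s, plateau 4 s at peak
      # speed, down 5 s, 2 s still (weights mark the plateau as the most
      # intense window for RGB masking)
      data.frame(onset_s = c(2, 7, 11), duration_s = c(5, 4, 5),
                 level = c(8, 16, 8), weight = c(0.5, 1, 0.5))
    } else {
      data.frame(onset_s = onset, duration_s = sd_, level = 1, weight = 1)
    }
    chans[[i]] <- stimulus_channel(labels[i], Tc, n_cycles[i], ev)
  }
  session_config(chans, frame_rate_hz, durs[1], wavelength_nm)
}

#' Two-site somatotopy schedule
#'
#' Oral and facial air-puff trains at distinct periods: 19 cycles of 23 s
#' (oral) and 23 cycles of 19 s (facial) sharing a 437 s session, each 4 s
#' puff train centered in its cycle.
#'
#' @inheritParams build_parcellation_schedule
#' @export
build_somatotopy_schedule <- function(periods_s = c(23, 19),
                                      n_cycles = c(19, 23),
                                      stim_durations_s = c(4, 4),
                                      labels = c("oral", "facial"),
                                      frame_rate_hz = 5,
                                      wavelength_nm = 530) {
  build_parcellation_schedule(periods_s, n_cycles, stim_durations_s,
                              labels, frame_rate_hz, wavelength_nm)
}

#' Retinotopy sweep channel
#'
#' Phase-encoded retinotopy channels. For polar-angle sweeps the level is
#' the polar angle in degrees clockwise from 12 o'clock as seen by the
#' subject (the convention is stated here because published maps define it
#' only pictorially): `level(t) = +-360 * t / T`, starting at 12 o'clock at
#' each cycle onset, i.e. 0.05 rounds/s for the standard 20 s cycle. For
#' eccentricity the inner and outer limits of the moving-dot annulus are
#' cosine-modulated from (5, 15) deg at cycle start to (0, 5) deg at
#' mid-cycle; `level_at` returns the band midpoint and the band limits are
#' available via `attr(, "band_at")`.
#'
#' @param kind `"eccentricity"`, `"polar_cw"` or `"polar_ccw"`.
#' @param cycle_period_s cycle period (default 20 s).
#' @param n_cycles cycles per session (default 20).
#' @export
build_sweep_schedule <- function(kind = c("eccentricity", "polar_cw",
                                          "polar_ccw"),
                                 cycle_period_s = 20, n_cycles = 20) {
  kind <- match.arg(kind)
  if (cycle_period_s <= 0) stop("cycle period must be positive")
  Tc <- cycle_period_s
  if (kind %in% c("polar_cw", "polar_ccw")) {
    sgn <- if (kind == "polar_cw") 1 else -1
    lv <- function(t) (sgn * 360 * (t %% Tc) / Tc) %% 360
    ev <- data.frame(onset_s = 0, duration_s = Tc, level = 0, weight = 1)
    ch <- stimulus_channel(kind, Tc, n_cycles, ev, level_at = lv)
  } else {
    outer_at <- function(t) 10 + 5 * cos(2 * pi * (t %% Tc) / Tc)
    inner_at <- function(t) 2.5 + 2.5 * cos(2 * pi * (t %% Tc) / Tc)
    lv <- function(t) (inner_at(t) + outer_at(t)) / 2
    ev <- data.frame(onset_s = 0, duration_s = Tc, level = 10, weight = 1)
    ch <- stimulus_channel(kind, Tc, n_cycles, ev, level_at = lv)
    attr(ch, "band_at") <- function(t) cbind(inner = inner_at(t),
                                             outer = outer_at(t))
  }
  ch
}

#' Within-cycle window of the most intense stimulation
#'
#' The time range spanned by the channel's maximum-weight events; used by
#' [render_rgb_summary()] to mask pixels whose tuning phase falls in the
#' peak-stimulus window.
#'
#' @param channel a [stimulus_channel()].
#' @return `c(start, end)` seconds within the cycle.
#' @export
most_intense_window <- function(channel) {
  ev <- channel$events
  if (nrow(ev) == 0L) stop("channel '", channel$label, "' has no events")
  top <- ev[ev$weight >= max(ev$weight) - 1e-12, , drop = FALSE]
  c(min(top$onset_s), max(top$onset_s + top$duration_s))
}

#' Serialize a session configuration to JSON
#' @param config a [session_config()].
#' @param path output path.
#' @export
write_session_json <- function(config, path) {
  obj <- list(
    frame_rate_hz = config$frame_rate_hz, duration_s = config$duration_s,
    wavelength_nm = config$wavelength_nm,
    channels = lapply(config$channels, function(ch)
      list(label = ch$label, cycle_period_s = ch$cycle_period_s,
           n_cycles = ch$n_cycles, events = ch$events)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  chans <- lapply(obj$channels, function(ch) {
    ev <- do.call(rbind, lapply(ch$events, as.data.frame))
    stimulus_channel(ch$label, ch$cycle_period_s, ch$n_cycles, ev)
  })
  session_config(chans, obj$frame_rate_hz, obj$duration_s,
                 obj$wavelength_nm)
}
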