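#' Candidate pixels for cross-resolution map comparison
#'
#' A loose filter for pixels entering the linear models comparing two
#' tuning maps of the same cortex at different effective resolutions
#' (e.g. through-skull vs through-window): a pixel must show a moderate
#' response amplitude in both maps (defaults 0.2 permille through-skull,
#' 1.5 permille through-window), be validly tuned to the stimulus (not to
#' silence) in both, and lie inside an optional region mask.
#'
#' @param map_a,map_b [tuning_map()]s on the same pixel grid (a = the
#'   lower-amplitude map, e.g. through-skull).
#' @param thresholds `c(thr_a, thr_b)` amplitude thresholds in dR/R units
#'   (defaults `c(0.2e-3, 1.5e-3)`).
#' @param region_mask optional logical matrix.
#' @return logical matrix.
#' @export
candidate_filter <- function(map_a, map_b,
                             thresholds = c(0.2e-3, 1.5e-3),
                             region_mask = NULL) {
  if (!all(dim(map_a$amplitude) == dim(map_b$amplitude)))
    stop("map geometries differ")
  keep <- map_a$valid & map_b$valid &
    !is.na(map_a$amplitude) & map_a$amplitude > thresholds[1] &
    !is.na(map_b$amplitude) & map_b$amplitude > thresholds[2]
  if (!is.null(region_mask)) keep <- keep & region_mask
  keep & !is.na(keep)
}

# radially interpolated 2-D kernel from a 1-D lateral sensitivity
# profile, with the offset axis rescaled so the kernel FWHM equals
# `target_fwhm_mm`; normalized to unit sum
profile_kernel <- function(profile, target_fwhm_mm, pixel_pitch_mm) {
  prof <- profile$profile
  base_fwhm <- profile$fwhm_mm
  if (!is.finite(base_fwhm) || base_fwhm <= 0)
    stop("kernel profile has no finite FWHM")
  scale <- target_fwhm_mm / base_fwhm
  r_max <- max(abs(prof$offset_mm)) * scale
  half_px <- max(1L, ceiling(r_max / pixel_pitch_mm))
  d <- seq(-half_px, half_px) * pixel_pitch_mm
  rr <- sqrt(outer(d^2, d^2, "+"))
  # fold the two-sided profile into a radial one (average the sides)
  pos <- prof$offset_mm >= 0
  xs <- c(rev(-prof$offset_mm[!pos]), prof$offset_mm[pos])
  ys <- c(rev(prof$sensitivity[!pos]), prof$sensitivity[pos])
  rad <- sort(unique(abs(xs)))
  val <- vapply(rad, function(r) mean(ys[abs(abs(xs) - r) < 1e-12]),
                numeric(1))
  k <- matrix(stats::approx(rad * scale, val, xout = as.vector(rr),
                            yleft = val[1], yright = 0, rule = 2)$y,
              nrow = nrow(rr))
  k[rr > r_max] <- 0
  k / sum(k)
}

#' Diffuse a complex tuning map at a target FWHM scale
#'
#' Emulates optical blurring of a tuning map by convolving it in the
#' complex plane: each pixel becomes `amplitude * exp(i*2*pi*phase/T)`,
#' the complex field is convolved with a 2-D kernel obtained by radially
#' interpolating a simulated lateral sensitivity profile and rescaling
#' its offset axis to the target FWHM, and amplitude/phase are read back
#' as modulus/argument. Convolving in the complex plane is what physical
#' mixing does: opposing phases cancel, so fine phase structure is lost
#' faster than amplitude. Border effects are removed by renormalizing
#' with the convolved all-ones map, which also makes any constant complex
#' map an exact fixed point. A target at or below the pixel pitch is
#' below the sampling resolution and returns the map unchanged.
#'
#' @param map a [tuning_map()].
#' @param profile a [perturbation_profile()] (or compatible) sensitivity
#'   profile serving as the kernel shape.
#' @param target_fwhm_mm kernel FWHM after rescaling, mm (> 0).
#' @param pixel_pitch_mm physical size of a map pixel, mm.
#' @return a [tuning_map()] with diffused amplitude and phase.
#' @export
diffuse_map <- function(map, profile, target_fwhm_mm, pixel_pitch_mm) {
  if (target_fwhm_mm <= 0) stop("target FWHM must be positive")
  if (target_fwhm_mm <= pixel_pitch_mm) return(map)
  Tc <- map$period_s
  amp <- map$amplitude
  amp[!map$valid | !is.finite(amp)] <- 0
  ph <- map$tuning_phase_s
  ph[!is.finite(ph)] <- 0
  z <- amp * exp(1i * 2 * pi * ph / Tc)
  k <- profile_kernel(profile, target_fwhm_mm, pixel_pitch_mm)
  num <- conv2_same(z, k)
  den <- conv2_same(matrix(1, nrow(z), ncol(z)), k)
  zs <- num / den
  new_amp <- Mod(zs)
  new_ph <- (Arg(zs) * Tc / (2 * pi)) %% Tc
  tuning_map(new_ph, new_amp, Tc, delay_s = map$delay_s,
             valid = map$valid, label = map$label)
}

# zero-padded FFT convolution returning the central ("same") part
conv2_same <- function(x, k) {
  nr <- nrow(x) + nrow(k) - 1L
  nc <- ncol(x) + ncol(k) - 1L
  px <- matrix(0i, nr, nc); px[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  pk <- matrix(0i, nr, nc); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- stats::fft(stats::fft(px) * stats::fft(pk), inverse = TRUE) /
    (nr * nc)
  r0 <- (nrow(k) - 1L) %/% 2L
  c0 <- (ncol(k) - 1L) %/% 2L
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))]
}

#' No-intercept linear model between paired response amplitudes
#'
#' Fits `y = slope * x` (no constant term) between the amplitudes of the
#' two maps on candidate pixels, by default with a robust
#' iteratively-reweighted fit (bisquare weights via [MASS::rlm()]); set
#' `robust = FALSE` for the ordinary least-squares closed form
#' `sum(xy)/sum(x^2)`. Reports the slope, the F statistic of the fitted
#' term and the no-intercept coefficient of determination
#' `r2 = 1 - SS_res / sum(y^2)`.
#'
#' @param x,y numeric vectors (e.g. through-window and through-skull
#'   amplitudes on candidate pixels).
#' @param robust use a robust bisquare fit.
#' @return list with `slope`, `F`, `r2`, `n`.
#' @export
fit_amplitude_model <- function(x, y, robust = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 paired points")
  slope <- if (robust) {
    fit <- MASS::rlm(y ~ x - 1, psi = MASS::psi.bisquare, maxit = 100)
    unname(stats::coef(fit)[1])
  } else {
    sum(x * y) / sum(x * x)
  }
  res <- y - slope * x
  ssr <- sum(res^2)
  r2 <- 1 - ssr / sum(y^2)
  Fst <- (sum((slope * x)^2) / 1) / (ssr / (n - 1))
  list(slope = slope, F = Fst, r2 = r2, n = n)
}

#' Octave conversion of tone frequencies
#'
#' Octaves above the reference (default 440 Hz): `log2(f / ref)`.
#' @param freq_hz frequencies in Hz.
#' @param ref_hz reference frequency.
#' @export
freq_to_octave <- function(freq_hz, ref_hz = 440) log2(freq_hz / ref_hz)

#' Map a tuning phase to the octave of the pip sounding at that time
#'
#' Continuous version of the pip sequence's time-frequency staircase: the
#' phase (seconds within the trial) is mapped through the pip centers to
#' octaves above the sequence start, clipped to the sequence's range.
#'
#' @param phase_s tuning phases in trial time, seconds.
#' @param seq a [tone_sequence()].
#' @return octaves above 440 Hz.
#' @export
phase_to_octave <- function(phase_s, seq) {
  oct_per_s <- seq$step_semitones / (12 * seq$pip_duration_s)
  oct0 <- freq_to_octave(seq$start_hz)
  oct <- oct0 + (phase_s - seq$pre_silence_s - seq$pip_duration_s / 2) *
    oct_per_s
  rng <- range(freq_to_octave(seq$frequencies_hz))
  pmin(pmax(oct, rng[1]), rng[2])
}

#' Linear model between paired tunings on the octave scale
#'
#' Fits `y = slope * x + intercept` between the two maps' tuning
#' frequencies expressed in octaves above 440 Hz, robustly by default
#' (bisquare IRLS), with the ordinary least-squares path available for
#' verification. Reports slope, intercept and the usual centered `r2`.
#'
#' @param x,y tunings in octaves (see [freq_to_octave()],
#'   [phase_to_octave()]).
#' @param robust use a robust bisquare fit.
#' @return list with `slope`, `intercept`, `r2`, `n`.
#' @export
fit_tuning_model <- function(x, y, robust = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired points")
  co <- if (robust) {
    fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
    stats::coef(fit)
  } else {
    stats::coef(stats::lm(y ~ x))
  }
  pred <- co[1] + co[2] * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = unname(co[2]), intercept = unname(co[1]), r2 = r2, n = n)
}

#' Scan diffusion scales to estimate an effective resolution
#'
#' Diffuses the higher-resolution map at each candidate FWHM scale
#' ([diffuse_map()]) and asks how well the diffused map explains the
#' lower-resolution map through the two linear models: the no-intercept
#' amplitude model and the octave-scale tuning model, both restricted to
#' candidate pixels. The scale maximizing `r2` is the estimated effective
#' diffusion (resolution) scale, reported separately for amplitude and
#' tuning.
#'
#' @param map_high the higher-resolution map (diffused; e.g.
#'   through-window).
#' @param map_low the lower-resolution map (explained; e.g.
#'   through-skull).
#' @param scales_mm candidate kernel FWHMs, mm.
#' @param profile kernel shape (a [perturbation_profile()] result).
#' @param pixel_pitch_mm map pixel size, mm.
#' @param thresholds,region_mask passed to [candidate_filter()].
#' @param tone_seq optional [tone_sequence()]: when given, tuning phases
#'   are converted to octaves through the pip staircase before the tuning
#'   model; otherwise raw phases are used.
#' @param robust robust fits (see the model functions).
#' @return object of class `wf_diffusion_scan`: data.frame `scan`
#'   (`scale_mm`, `r2_amplitude`, `r2_tuning`, `slope_amplitude`,
#'   `slope_tuning`, `intercept_tuning`), `best_scale_amplitude_mm`,
#'   `best_scale_tuning_mm`, `n_candidates`.
#' @export
scan_diffusion_scales <- function(map_high, map_low, scales_mm, profile,
                                  pixel_pitch_mm,
                                  thresholds = c(0.2e-3, 1.5e-3),
                                  region_mask = NULL, tone_seq = NULL,
                                  robust = FALSE) {
  keep <- candidate_filter(map_low, map_high, thresholds, region_mask)
  if (!any(keep)) stop("no candidate pixels")
  tune_of <- function(m)
    if (is.null(tone_seq)) m$tuning_phase_s[keep]
    else phase_to_octave(m$tuning_phase_s[keep], tone_seq)
  y_amp <- map_low$amplitude[keep]
  y_tun <- tune_of(map_low)
  rows <- lapply(scales_mm, function(sc) {
    dif <- diffuse_map(map_high, profile, sc, pixel_pitch_mm)
    fa <- fit_amplitude_model(dif$amplitude[keep], y_amp, robust = robust)
    ft <- fit_tuning_model(tune_of(dif), y_tun, robust = robust)
    data.frame(scale_mm = sc, r2_amplitude = fa$r2, r2_tuning = ft$r2,
               slope_amplitude = fa$slope, slope_tuning = ft$slope,
               intercept_tuning = ft$intercept)
  })
  scan <- do.call(rbind, rows)
  structure(
    list(scan = scan,
         best_scale_amplitude_mm = scan$scale_mm[which.max(scan$r2_amplitude)],
         best_scale_tuning_mm = scan$scale_mm[which.max(scan$r2_tuning)],
         n_candidates = sum(keep)),
    class = "wf_diffusion_scan")
}

#' @export
print.wf_diffusion_scan <- function(x, ...) {
  cat(sprintf(paste0("<wf_diffusion_scan> %d scales, %d candidate px; best",
                     " scale: amplitude %.2f mm, tuning %.2f mm\n"),
              nrow(x$scan), x$n_candidates, x$best_scale_amplitude_mm,
              x$best_scale_tuning_mm))
  invisible(x)
}
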