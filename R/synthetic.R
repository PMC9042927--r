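#' Planted ground truth for synthetic movies
#'
#' Per-pixel maps of preferred stimulus time, response amplitude and
#' hemodynamic delay for each channel of a session, plus the response
#' kernel shape. Setting a pixel's amplitude to zero in a channel removes
#' that modality there, which is how disjoint modality regions are planted.
#'
#' @param channels named list, one entry per channel, each a list with
#'   matrices `preferred_time_s` (seconds within that channel's cycle) and
#'   `amplitude` (dR/R, >= 0).
#' @param delay_s hemodynamic delay: scalar or rows x cols matrix, seconds.
#' @param kernel `"cosine"` (pure cosine at the channel frequency, which
#'   the cosine-fit analysis recovers exactly) or `"raised_cosine"` (a
#'   transient bump of width `kernel_width_s` peaking at the preferred
#'   time; more realistic, with a documented amplitude attenuation at the
#'   fundamental).
#' @param kernel_width_s full width of the raised-cosine bump in seconds.
#' @return object of class `wf_ground_truth`.
#' @export
ground_truth <- function(channels, delay_s = 0,
                         kernel = c("cosine", "raised_cosine"),
                         kernel_width_s = 4) {
  kernel <- match.arg(kernel)
  geo <- dim(channels[[1]]$amplitude)
  for (ch in channels) {
    if (!all(dim(ch$amplitude) == geo) ||
        !all(dim(ch$preferred_time_s) == geo))
      stop("all ground-truth maps must share one geometry")
    if (any(ch$amplitude < 0, na.rm = TRUE))
      stop("amplitudes must be >= 0")
  }
  if (is.matrix(delay_s) && !all(dim(delay_s) == geo))
    stop("delay map geometry mismatch")
  structure(
    list(channels = channels, delay_s = delay_s, kernel = kernel,
         kernel_width_s = kernel_width_s, geometry = geo),
    class = "wf_ground_truth")
}

# raised-cosine bump of full width `w`, peak 1 at u = 0, wrapped into
# [-T/2, T/2); zero-mean is NOT enforced (the DC lands in the 0 bin)
raised_cosine_kernel <- function(u, Tc, w) {
  u <- ((u + Tc / 2) %% Tc) - Tc / 2
  ifelse(abs(u) <= w / 2, 0.5 * (1 + cos(2 * pi * u / w)), 0)
}

#' Synthesize a phase-encoded session movie with planted ground truth
#'
#' Builds a relative (dR/R) movie whose pixel traces follow the periodic
#' response model underlying phase-encoded analysis: for each channel with
#' cycle period `T`, the trace is
#' `polarity(lambda) * A * kernel((t - s - delta) mod T)` summed over
#' channels (simultaneous stimulation assumes frequency-domain
#' separability), plus i.i.d. Gaussian noise per frame. The cosine kernel
#' is `cos(2*pi*(t - s - delta)/T)`, peaking where the stimulus the pixel
#' prefers occurred `delta` seconds earlier -- the hemodynamically delayed
#' response. Noise is Gaussian at the dR/R level: after spatiotemporal
#' binning, photon shot noise is well approximated as Gaussian and is
#' quantified as a relative sd.
#'
#' @param truth a [ground_truth()]; channel names must match the config's.
#' @param config a [session_config()].
#' @param noise_sd_permille per-frame Gaussian noise sd in permille of R.
#' @param seed integer seed; the output is deterministic given it.
#' @return a relative [movie()].
#' @export
synthesize_movie <- function(truth, config, noise_sd_permille = 0,
                             seed = 1L) {
  if (noise_sd_permille < 0) stop("noise sd must be >= 0")
  geo <- truth$geometry
  n <- as.integer(round(config$duration_s * config$frame_rate_hz))
  tt <- (seq_len(n) - 0.5) / config$frame_rate_hz
  pol <- polarity_sign(config$wavelength_nm)
  npx <- prod(geo)
  sig <- matrix(0, nrow = n, ncol = npx)
  delta <- if (is.matrix(truth$delay_s)) as.vector(truth$delay_s)
           else rep(truth$delay_s, npx)
  for (ch in config$channels) {
    g <- truth$channels[[ch$label]]
    if (is.null(g)) next
    Tc <- ch$cycle_period_s
    A <- as.vector(g$amplitude)
    s <- as.vector(g$preferred_time_s)
    active <- which(A > 0)
    if (!length(active)) next
    if (truth$kernel == "cosine") {
      # cos(2*pi*(t-s-d)/T) = Re( e^{i 2 pi t/T} * e^{-i 2 pi (s+d)/T} )
      et <- exp(1i * 2 * pi * tt / Tc)
      ep <- A[active] * exp(-1i * 2 * pi * (s[active] + delta[active]) / Tc)
      sig[, active] <- sig[, active] + pol * Re(outer(et, ep))
    } else {
      u <- outer(tt, s[active] + delta[active], "-")
      k <- raised_cosine_kernel(u, Tc, truth$kernel_width_s)
      sig[, active] <- sig[, active] +
        pol * sweep(k, 2, A[active], "*")
    }
  }
  if (noise_sd_permille > 0) {
    noise <- with_seed(seed,
      matrix(rnorm(n * npx, sd = noise_sd_permille * 1e-3), nrow = n))
    sig <- sig + noise
  }
  movie(array(sig, dim = c(n, geo)), config$frame_rate_hz,
        kind = "relative", wavelength_nm = config$wavelength_nm)
}

#' Theoretical shot-noise floor of a relative measurement
#'
#' Under a Poisson process assumption for incoherent photon arrivals, the
#' relative sd of a saved pixel value integrating `N` photoelectrons over
#' `n` repetitions is `1 / sqrt(N * n)`. The sensor photon budget is an
#' explicit input: the floor is only as good as the assumed full-well and
#' binning budget.
#'
#' @param photoelectrons_per_saved_pixel_frame photoelectrons accumulated
#'   into one saved (binned) pixel frame.
#' @param n_repetitions number of averaged repetitions.
#' @return dimensionless relative sd.
#' @export
shot_noise_floor <- function(photoelectrons_per_saved_pixel_frame,
                             n_repetitions = 1) {
  if (photoelectrons_per_saved_pixel_frame <= 0)
    stop("photoelectron count must be positive")
  if (n_repetitions <= 0) stop("repetition count must be positive")
  1 / sqrt(photoelectrons_per_saved_pixel_frame * n_repetitions)
}
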