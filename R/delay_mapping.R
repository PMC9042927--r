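#' Disentangle tuning phase from hemodynamic delay with mirrored sessions
#'
#' A pixel's raw response phase confounds its preferred-stimulus time `s`
#' with its hemodynamic delay `delta`. Presenting the same stimulus
#' sequence forwards and time-reversed (upward/downward tone sequences,
#' clockwise/counterclockwise sweeps) and assuming the delay is identical
#' in both sessions gives the per-pixel model
#' `phi_fwd = (s + delta) mod T` and `phi_rev = (T - s + delta) mod T`,
#' so `phi_fwd + phi_rev = 2*delta (mod T)`. The sum determines `delta`
#' only up to an additive `T/2`; of the pair `{delta0, delta0 + T/2}` the
#' candidate inside the physiologic window `[0, T/2)` is taken by default
#' (for the standard 20 s cycles that window is 0-10 s, far above the
#' 3.2-4.4 s where measured delays cluster). Supplying `accept_range`
#' switches on the stronger disambiguation: if `delta0` is outside the
#' range but `delta0 + T/2` is inside, the latter is chosen.
#'
#' The tuning phase is reported on the forward session's timeline,
#' `s = (phi_fwd - delta) mod T`, and the amplitude is the mean of the two
#' sessions' amplitudes. Exchanging the two arguments leaves `delta`
#' unchanged and maps `s -> (T - s) mod T` (time-reversal symmetry).
#'
#' @param fwd,rev polarity-compensated [extract_channel_response()] maps of
#'   the forward and reversed sessions (same geometry and period).
#' @param accept_range optional `c(lo, hi)` seconds used only to
#'   disambiguate the `T/2` pair (see Details); it does not filter pixels.
#' @return a [tuning_map()] carrying a per-pixel `delay_s` matrix.
#' @export
combine_reversed_sessions <- function(fwd, rev, accept_range = NULL) {
  if (!isTRUE(fwd$polarity_compensated) || !isTRUE(rev$polarity_compensated))
    stop("both maps must be polarity-compensated")
  if (abs(fwd$period_s - rev$period_s) > 1e-9)
    stop("cycle periods differ between sessions")
  if (!all(dim(fwd$amplitude) == dim(rev$amplitude)))
    stop("map geometries differ between sessions")
  Tc <- fwd$period_s
  delta <- ((fwd$phase_time_s + rev$phase_time_s) %% Tc) / 2  # in [0, T/2)
  if (!is.null(accept_range)) {
    alt <- delta + Tc / 2
    swap <- !is.na(delta) &
      (delta < accept_range[1] | delta > accept_range[2]) &
      alt >= accept_range[1] & alt <= accept_range[2]
    delta[swap] <- alt[swap]
  }
  s <- (fwd$phase_time_s - delta) %% Tc
  amp <- (fwd$amplitude + rev$amplitude) / 2
  valid <- fwd$valid & rev$valid & is.finite(delta)
  tuning_map(tuning_phase_s = s, amplitude = amp, period_s = Tc,
             delay_s = delta, valid = valid,
             label = paste0(fwd$label, "+", rev$label))
}

#' Select the most responsive candidate pixels
#'
#' The mask of the top `fraction` of valid pixels ranked by response
#' amplitude (`ceiling(fraction * n_valid)` pixels). Delay statistics are
#' summarized over these candidates only, because phase and delay
#' estimates are meaningless where there is no response. Ties are broken
#' deterministically by row-major pixel order.
#'
#' @param map a [tuning_map()] (or any object with `amplitude` and `valid`
#'   matrices).
#' @param fraction fraction of valid pixels to keep, in (0, 1]; default
#'   0.10 (the top decile).
#' @return logical matrix mask.
#' @export
select_candidates <- function(map, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  amp <- map$amplitude
  valid <- map$valid & is.finite(amp)
  n_valid <- sum(valid)
  if (n_valid == 0L) stop("map has no valid pixels")
  k <- ceiling(fraction * n_valid)
  # column-major storage; rank by amplitude, ties by row-major pixel index
  idx <- which(valid)
  rmaj <- (row(amp)[idx] - 1L) * ncol(amp) + col(amp)[idx]
  ord <- idx[order(-amp[idx], rmaj)]
  mask <- matrix(FALSE, nrow(amp), ncol(amp))
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Summarize hemodynamic delays over candidate pixels
#'
#' Arithmetic mean of the delays of candidate pixels that fall inside the
#' empirically acceptable delay range (endpoints inclusive; the canonical
#' range is 2.0-5.7 s), plus a histogram of all candidate delays for
#' inspection. If no candidate falls in range, an error is raised carrying
#' the diagnostic histogram.
#'
#' @param delays numeric vector or matrix of per-pixel delays (s), e.g.
#'   the `delay_s` field of [combine_reversed_sessions()].
#' @param mask optional logical mask (from [select_candidates()]).
#' @param accept_range closed acceptance interval `c(lo, hi)` in seconds.
#' @param bin_width_s histogram bin width.
#' @return list with `mean_delay_s`, `n_in_range`, `n_candidates` and a
#'   `histogram` data.frame (`mid_s`, `count`).
#' @export
summarize_delay <- function(delays, mask = NULL,
                            accept_range = c(2.0, 5.7),
                            bin_width_s = 0.25) {
  d <- if (!is.null(mask)) delays[mask] else as.vector(delays)
  d <- d[is.finite(d)]
  if (length(d) == 0L) stop("no candidate delays to summarize")
  breaks <- seq(0, max(d, accept_range[2]) + bin_width_s, by = bin_width_s)
  h <- hist(d, breaks = breaks, plot = FALSE)
  histo <- data.frame(mid_s = h$mids, count = h$counts)
  inr <- d >= accept_range[1] & d <= accept_range[2]
  if (!any(inr)) {
    msg <- paste0("no candidate delay inside [", accept_range[1], ", ",
                  accept_range[2], "] s; candidate histogram:\n",
                  paste(sprintf("  %.2fs: %d", histo$mid_s, histo$count),
                        collapse = "\n"))
    stop(msg)
  }
  list(mean_delay_s = mean(d[inr]), n_in_range = sum(inr),
       n_candidates = length(d), histogram = histo)
}

#' @importFrom graphics hist
NULL
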