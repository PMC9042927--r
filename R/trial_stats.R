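#' Cut a raw movie into baseline-normalized trials
#'
#' For trial-based (non-phase-encoded) experiments each trial trace is
#' normalized to its own pre-stimulus baseline: per trial and pixel,
#' `(raw - B)/B` where `B` is the mean raw intensity over the baseline
#' window (default the first 2 s of the trial), then multiplied by the
#' wavelength's signal polarity so that a stronger response is a larger
#' (more positive) value regardless of wavelength.
#'
#' @param movie a raw [movie()].
#' @param trial_onsets_s trial start times, seconds from session start.
#' @param trial_duration_s trial length in seconds; trials must not
#'   overlap nor extend past the movie end.
#' @param baseline_window `c(start, end)` seconds within the trial.
#' @param polarity +1 or -1; defaults to the movie wavelength's sign.
#' @return object of class `wf_trial_set`: `data` is a 4-D array
#'   (trials x frames-per-trial x rows x cols) of polarity-compensated
#'   dR/R, plus timing metadata.
#' @export
normalize_trials <- function(movie, trial_onsets_s, trial_duration_s,
                             baseline_window = c(0, 2), polarity = NULL) {
  if (movie$kind != "raw") stop("`movie` must be of kind 'raw'")
  if (is.null(polarity)) {
    if (is.null(movie$wavelength_nm))
      stop("no polarity given and the movie has no wavelength")
    polarity <- polarity_sign(movie$wavelength_nm)
  }
  fr <- movie$frame_rate_hz
  d <- dim(movie$frames)
  npt <- as.integer(round(trial_duration_s * fr))
  on_f <- as.integer(round(trial_onsets_s * fr))  # 0-based start frames
  ord <- order(on_f)
  if (any(diff(on_f[ord]) < npt)) stop("trials overlap")
  if (any(on_f < 0L) || any(on_f + npt > d[1]))
    stop("a trial extends past the movie end")
  tloc <- (seq_len(npt) - 0.5) / fr  # frame centers, trial-relative
  bsel <- which(tloc >= baseline_window[1] & tloc < baseline_window[2])
  if (!length(bsel)) stop("baseline window contains no frames")
  flat <- matrix(movie$frames, nrow = d[1])
  nt <- length(on_f)
  out <- array(NA_real_, c(nt, npt, d[2], d[3]))
  for (i in seq_len(nt)) {
    blk <- flat[on_f[i] + seq_len(npt), , drop = FALSE]
    B <- colMeans(blk[bsel, , drop = FALSE])
    B[!is.finite(B) | B <= 0] <- NA_real_
    out[i, , , ] <- polarity * sweep(sweep(blk, 2, B, "-"), 2, B, "/")
  }
  structure(
    list(data = out, frame_rate_hz = fr, trial_duration_s = trial_duration_s,
         baseline_window = baseline_window, polarity = polarity),
    class = "wf_trial_set")
}

#' Per-trial, per-pixel response values
#'
#' The mean dR/R over the response window of each trial (default 4-10 s
#' after the first stimulus frame onset), the scalar that feeds the t-value
#' and differential maps.
#'
#' @param set a [normalize_trials()] trial set.
#' @param window `c(start, end)` seconds within the trial.
#' @return numeric array trials x rows x cols.
#' @export
trial_response_values <- function(set, window = c(4, 10)) {
  npt <- dim(set$data)[2]
  tloc <- (seq_len(npt) - 0.5) / set$frame_rate_hz
  if (window[1] < 0 || window[2] > set$trial_duration_s)
    stop("response window outside the trial")
  sel <- which(tloc >= window[1] & tloc <= window[2])
  if (!length(sel)) stop("response window contains no frames")
  apply(set$data[, sel, , , drop = FALSE], c(1, 3, 4), mean)
}

#' Pixelwise Welch t-value map
#'
#' For each pixel, the t statistic of Welch's unequal-variance t-test
#' between the two groups of single-trial response values:
#' `t = (mean1 - mean2) / sqrt(s1^2/N1 + s2^2/N2)` with sample (n-1)
#' standard deviations. No degrees of freedom or p-values are attached:
#' maps are thresholded directly on t, and at the trial counts in routine
#' use (n > 100) t > 2.0 and t > 3.4 correspond to two-tailed p < 0.05 and
#' p < 0.001. Pixels where both group variances vanish have an undefined t
#' and are masked (NA).
#'
#' @param group1,group2 arrays trials x rows x cols of response values
#'   (from [trial_response_values()]), at least 2 trials each.
#' @return object of class `wf_t_map`: `t` matrix, `n1`, `n2`.
#' @export
welch_t_map <- function(group1, group2) {
  n1 <- dim(group1)[1]; n2 <- dim(group2)[1]
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 trials")
  m1 <- apply(group1, c(2, 3), mean); m2 <- apply(group2, c(2, 3), mean)
  v1 <- apply(group1, c(2, 3), stats::var)
  v2 <- apply(group2, c(2, 3), stats::var)
  se <- sqrt(v1 / n1 + v2 / n2)
  tval <- (m1 - m2) / se
  tval[se == 0] <- NA_real_
  structure(list(t = tval, n1 = n1, n2 = n2), class = "wf_t_map")
}

#' Face-versus-best-other differential map
#'
#' Per pixel, the mean response to the target category minus the maximum
#' of the mean responses to every other category. A positive value means
#' the pixel responds more strongly to the target than to any competitor
#' -- the defining property of a category-selective patch. The same
#' response-window values used for the t maps are used here.
#'
#' @param category_values named list of trials x rows x cols arrays, one
#'   per category (at least 2 categories).
#' @param target name of the category of interest (default `"face"`).
#' @return numeric rows x cols matrix.
#' @export
differential_map <- function(category_values, target = "face") {
  if (length(category_values) < 2L) stop("need at least 2 categories")
  if (!target %in% names(category_values))
    stop("target category '", target, "' not found")
  means <- lapply(category_values, function(a) apply(a, c(2, 3), mean))
  others <- means[setdiff(names(means), target)]
  best_other <- Reduce(pmax, others)
  means[[target]] - best_other
}
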