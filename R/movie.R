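#' Wide-field imaging movie
#'
#' A movie is a 3-D intensity stack (time x rows x cols) together with its
#' frame rate and a flag saying whether the values are raw camera intensities
#' or relative intensity changes (dR/R, dimensionless). Frame timestamps are
#' taken at frame centers: frame `k` (1-based) covers
#' `[(k-1)/rate, k/rate)` seconds and is stamped at `(k - 0.5)/rate`.
#'
#' Relative movies carry permille-scale signals in vivo; a loose sanity bound
#' of |dR/R| < 0.2 is enforced at construction to catch raw stacks passed in
#' by mistake. Invalid pixels (e.g. zero-baseline) are carried as NA and
#' propagate through all downstream maps.
#'
#' @param frames 3-D numeric array, time x rows x cols.
#' @param frame_rate_hz frames per second.
#' @param kind `"raw"` or `"relative"`.
#' @param wavelength_nm optional illumination wavelength (needed for
#'   polarity compensation downstream).
#' @return An object of class `wf_movie`.
#' @export
movie <- function(frames, frame_rate_hz, kind = c("raw", "relative"),
                  wavelength_nm = NULL) {
  kind <- match.arg(kind)
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (time x rows x cols)")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be positive")
  if (any(is.infinite(frames)))
    stop("movie contains non-finite (infinite) values")
  if (kind == "relative") {
    mx <- max(abs(frames), na.rm = TRUE)
    if (is.finite(mx) && mx >= 0.2)
      stop("relative movie has |dR/R| >= 0.2; real intrinsic signals are ",
           "permille-scale -- was a raw movie passed as relative?")
  }
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz, kind = kind,
         wavelength_nm = wavelength_nm),
    class = "wf_movie")
}

#' @export
print.wf_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<wf_movie> %d frames of %d x %d @ %g fps (%s%s)\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$kind,
              if (!is.null(x$wavelength_nm))
                sprintf(", %g nm", x$wavelength_nm) else ""))
  invisible(x)
}

#' @export
dim.wf_movie <- function(x) dim(x$frames)

#' Frame-center timestamps of a movie, in seconds from session start.
#' @param movie a [movie()].
#' @return numeric vector of length `n_frames`.
#' @export
frame_times <- function(movie) {
  n <- dim(movie$frames)[1]
  (seq_len(n) - 0.5) / movie$frame_rate_hz
}

#' Normalize a raw movie to relative intensity change (dR/R)
#'
#' Per pixel, `(raw(t) - B) / B` where the baseline `B` is the session-mean
#' intensity, the mean over a pre-stimulus window, or the per-pixel maximum
#' over the session -- the three baseline conventions in routine use. Since
#' dR/R is permille-scale, the choice makes a negligible difference to the
#' quantified relative change; the options exist for exact reproducibility.
#'
#' Pixels whose baseline is zero or negative cannot be normalized; they are
#' flagged invalid (all-NA trace), not raised as an error, because chamber
#' edges and specular pixels exist in real data.
#'
#' @param movie a raw [movie()].
#' @param baseline_mode `"session_mean"`, `"prestim_mean"` or `"trial_max"`.
#' @param window for `"prestim_mean"` (and optionally `"trial_max"`), the
#'   `c(start, end)` time interval in seconds over which the baseline is
#'   taken; frames whose center time falls in `[start, end)` are used.
#' @return a relative [movie()].
#' @export
to_relative <- function(movie,
                        baseline_mode = c("session_mean", "prestim_mean",
                                          "trial_max"),
                        window = NULL) {
  baseline_mode <- match.arg(baseline_mode)
  if (movie$kind != "raw") stop("`movie` must be of kind 'raw'")
  fr <- movie$frames
  d <- dim(fr)
  tt <- frame_times(movie)
  sel <- if (!is.null(window)) which(tt >= window[1] & tt < window[2])
         else seq_len(d[1])
  if (baseline_mode == "prestim_mean" && is.null(window))
    stop("baseline_mode 'prestim_mean' requires `window`")
  if (length(sel) == 0L) stop("baseline window contains no frames")
  flat <- matrix(fr, nrow = d[1])
  B <- switch(baseline_mode,
              session_mean = colMeans(flat),
              prestim_mean = colMeans(flat[sel, , drop = FALSE]),
              trial_max    = apply(flat[sel, , drop = FALSE], 2, max))
  bad <- !is.finite(B) | B <= 0
  B[bad] <- NA_real_
  rel <- sweep(sweep(flat, 2, B, "-"), 2, B, "/")
  out <- array(rel, dim = d)
  movie(out, movie$frame_rate_hz, kind = "relative",
        wavelength_nm = movie$wavelength_nm)
}

#' Bin a movie spatially and/or temporally by block means
#'
#' Acquisition at full camera resolution (e.g. 1920 x 1200 @ 80 fps) is
#' stored binned (480 x 300 @ 5 fps, i.e. spatial factor 4 and temporal
#' factor 16). Binning takes block means, which conserves the global mean
#' and is scale-invariant for dR/R movies; the frame rate is divided by
#' the temporal factor.
#'
#' @param movie a [movie()].
#' @param spatial_factor,temporal_factor positive integer factors; every
#'   binned dimension must divide exactly.
#' @return a binned [movie()].
#' @export
bin_movie <- function(movie, spatial_factor = 1L, temporal_factor = 1L) {
  sf <- as.integer(spatial_factor); tf <- as.integer(temporal_factor)
  if (sf < 1L || tf < 1L) stop("binning factors must be >= 1")
  d <- dim(movie$frames)
  if (d[1] %% tf != 0L)
    stop(sprintf("time axis (%d frames) not divisible by temporal_factor %d",
                 d[1], tf))
  if (d[2] %% sf != 0L)
    stop(sprintf("row axis (%d) not divisible by spatial_factor %d", d[2], sf))
  if (d[3] %% sf != 0L)
    stop(sprintf("col axis (%d) not divisible by spatial_factor %d", d[3], sf))
  if (sf == 1L && tf == 1L) return(movie)
  a <- movie$frames
  dn <- c(tf, d[1] %/% tf, sf, d[2] %/% sf, sf, d[3] %/% sf)
  dim(a) <- dn
  out <- apply(a, c(2L, 4L, 6L), mean)
  movie(out, movie$frame_rate_hz / tf, kind = movie$kind,
        wavelength_nm = movie$wavelength_nm)
}

#' Mean and SEM traces over repeated cycles
#'
#' Given a stack of repeated cycles (`n_cycles` x `n_time`), returns the
#' per-timepoint mean and the standard error of the mean defined as
#' `sqrt((E[X^2] - E[X]^2) / n)`. Note this uses the biased (divide-by-n)
#' variance, not the `n - 1` sample convention: it is implemented verbatim
#' as the quantity it reproduces (so SEM is exactly 0 at n = 1), and
#' differs from `sd(x)/sqrt(n)` by a factor `sqrt((n-1)/n)`.
#'
#' @param cycle_stack numeric matrix, cycles x time.
#' @return list with `mean` and `sem` numeric vectors.
#' @export
sem_trace <- function(cycle_stack) {
  if (is.null(dim(cycle_stack))) cycle_stack <- matrix(cycle_stack, nrow = 1)
  n <- nrow(cycle_stack)
  if (n < 1L) stop("need at least one cycle")
  m  <- colMeans(cycle_stack)
  m2 <- colMeans(cycle_stack^2)
  list(mean = m, sem = sqrt(pmax(m2 - m^2, 0) / n))
}

#' Write / read a movie as multi-page TIFF plus a JSON sidecar
#'
#' The frames are stored as 32-bit float grayscale TIFF pages. Because
#' the TIFF writer only stores values in the unit interval, the data are
#' affinely rescaled into (0, 1] on write and the scale recorded in the
#' `<path>.json` sidecar together with frame rate, kind and wavelength;
#' invalid (NA) pixels are encoded as exactly 0 and restored on read.
#' Round trips are exact to float32 precision. For bit-exact storage use
#' [saveRDS()] on the object.
#'
#' @param movie a [movie()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$frames)
  lo <- min(movie$frames, na.rm = TRUE)
  hi <- max(movie$frames, na.rm = TRUE)
  span <- if (hi > lo) hi - lo else 1
  enc <- 0.001 + 0.999 * (movie$frames - lo) / span
  enc[is.na(enc)] <- 0
  pages <- lapply(seq_len(d[1]), function(k) enc[k, , ])
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  meta <- list(frame_rate_hz = movie$frame_rate_hz, kind = movie$kind,
               wavelength_nm = movie$wavelength_nm,
               scale_lo = lo, scale_hi = hi)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  d <- dim(pages[[1]])
  fr <- array(NA_real_, c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) fr[k, , ] <- pages[[k]]
  span <- if (meta$scale_hi > meta$scale_lo)
    meta$scale_hi - meta$scale_lo else 1
  dec <- (fr - 0.001) / 0.999 * span + meta$scale_lo
  dec[fr == 0] <- NA_real_
  movie(dec, meta$frame_rate_hz, kind = meta$kind,
        wavelength_nm = meta$wavelength_nm %||% NULL)
}
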