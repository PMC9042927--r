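#' Rendering specification for tuning maps
#'
#' Controls the amplitude upper display limit and the hue wheel. The
#' default upper limit is the 99th percentile of valid-pixel amplitudes
#' (per-subject overrides such as 97th/95th/93rd percentiles, or an
#' absolute dR/R value, are parameters, not hard-coded cases). The hue
#' wheel maps tuning phase 0 to `hue_offset` (default 0 = red) and runs
#' through the rainbow with increasing phase; published wheels are defined
#' only pictorially, so any cyclic wheel is acceptable and configurable.
#'
#' @param percentile upper-limit percentile in (0, 100].
#' @param absolute optional absolute upper limit (overrides `percentile`).
#' @param hue_offset hue of phase 0, in [0, 1).
#' @param hue_direction +1 or -1, direction of increasing phase on the wheel.
#' @export
render_spec <- function(percentile = 99, absolute = NULL, hue_offset = 0,
                        hue_direction = 1) {
  if (is.null(absolute) && (percentile <= 0 || percentile > 100))
    stop("percentile must be in (0, 100]")
  structure(list(percentile = percentile, absolute = absolute,
                 hue_offset = hue_offset, hue_direction = hue_direction),
            class = "wf_render_spec")
}

amplitude_upper <- function(amplitude, valid, spec) {
  if (!is.null(spec$absolute)) return(spec$absolute)
  vals <- amplitude[valid & is.finite(amplitude)]
  if (!length(vals)) return(NA_real_)
  stats::quantile(vals, spec$percentile / 100, names = FALSE)
}

#' Render a tuning map in HSV space
#'
#' Tuning phase is encoded in the hue channel (cyclic: phases differing by
#' a full period get the same color) and response amplitude in both the
#' saturation and value channels, clipped at the upper display limit so
#' that a pixel at the limit is fully saturated and bright. Invalid pixels
#' get saturation 0 (gray-scale).
#'
#' @param map a [tuning_map()].
#' @param spec a [render_spec()].
#' @return rows x cols x 3 RGB array in the unit interval.
#' @export
render_hsv <- function(map, spec = render_spec()) {
  amp <- map$amplitude
  valid <- map$valid
  if (!any(valid)) {
    warning("all pixels invalid; returning a gray image")
    return(array(0.5, c(dim(amp), 3)))
  }
  upper <- amplitude_upper(amp, valid, spec)
  v <- pmin(pmax(amp / upper, 0), 1)
  v[!is.finite(v)] <- 0
  s <- v
  s[!valid] <- 0
  h <- (spec$hue_offset +
          spec$hue_direction * map$tuning_phase_s / map$period_s) %% 1
  h[!is.finite(h)] <- 0
  rgb_from_hsv(h, s, v)
}

rgb_from_hsv <- function(h, s, v) {
  d <- dim(h)
  cols <- grDevices::hsv(as.vector(h), as.vector(s), as.vector(v))
  m <- grDevices::col2rgb(cols) / 255
  out <- array(0, c(d, 3))
  out[, , 1] <- m[1, ]; out[, , 2] <- m[2, ]; out[, , 3] <- m[3, ]
  out
}

#' Tonotopy validity mask
#'
#' Pixels whose tuning phase falls outside the time range of the tone pip
#' sequence (they "prefer" silence) or whose hemodynamic delay falls
#' outside the acceptable range are invalid and are zeroed in the
#' saturation channel when rendered. For the standard trial the tone
#' window is 2.7-17.3 s.
#'
#' @param map a [tuning_map()] (with per-pixel `delay_s` if delay
#'   filtering is wanted).
#' @param tone_window `c(start, end)` of the pip sequence in trial time.
#' @param accept_range closed hemodynamic-delay acceptance interval (s),
#'   or NULL to skip delay filtering.
#' @return logical matrix.
#' @export
tonotopy_validity <- function(map, tone_window = c(2.7, 17.3),
                              accept_range = c(2.0, 5.7)) {
  ok <- map$valid &
    map$tuning_phase_s >= tone_window[1] &
    map$tuning_phase_s <= tone_window[2]
  if (!is.null(accept_range) && is.matrix(map$delay_s))
    ok <- ok & map$delay_s >= accept_range[1] & map$delay_s <= accept_range[2]
  ok & !is.na(ok)
}

#' Composite retinotopy rendering
#'
#' Polar-angle tuning in the hue channel, eccentricity tuning in the
#' saturation channel (center-preferring -> 0, i.e. white; periphery ->
#' 1), and motion-response amplitude in the value channel. A pixel tuned
#' to the central visual field and responsive to motion therefore renders
#' bright white. Eccentricity phase is mapped by circular distance from
#' mid-cycle (when only the center contains moving dots) to cycle start
#' (periphery).
#'
#' @param polar,ecc [tuning_map()]s of polar angle and eccentricity.
#' @param motion a response or tuning map whose amplitude drives the value
#'   channel.
#' @param spec a [render_spec()] for the motion amplitude upper limit.
#' @return rows x cols x 3 RGB array.
#' @export
render_retinotopy_composite <- function(polar, ecc, motion,
                                        spec = render_spec()) {
  if (!all(dim(polar$amplitude) == dim(ecc$amplitude)) ||
      !all(dim(polar$amplitude) == dim(motion$amplitude)))
    stop("map geometries differ")
  h <- (spec$hue_offset + polar$tuning_phase_s / polar$period_s) %% 1
  h[!is.finite(h)] <- 0
  Tc <- ecc$period_s
  dmid <- abs(((ecc$tuning_phase_s - Tc / 2) %% Tc))
  dmid <- pmin(dmid, Tc - dmid)          # circular distance from mid-cycle
  s <- dmid / (Tc / 2)
  s[!is.finite(s)] <- 0
  upper <- amplitude_upper(motion$amplitude,
                           motion$valid %||% is.finite(motion$amplitude),
                           spec)
  v <- pmin(pmax(motion$amplitude / upper, 0), 1)
  v[!is.finite(v)] <- 0
  rgb_from_hsv(h, s, v)
}

#' RGB summary of a multi-frequency session
#'
#' For each channel a mask keeps the pixels whose tuning phase falls in
#' the channel's most-intense-stimulus window widened by a tolerance
#' (default 1 s at either side); masked pixels have their clipped
#' amplitude written into that channel's RGB plane. With at most three
#' channels the planes are assigned in list order (R, G, B).
#'
#' @param maps list of up to 3 [tuning_map()]s.
#' @param channels matching list of [stimulus_channel()]s (for the
#'   peak-stimulus windows, see [most_intense_window()]).
#' @param tolerance_s phase tolerance on either side of the window.
#' @param spec a [render_spec()]; the upper limit is computed per channel.
#' @return rows x cols x 3 RGB array.
#' @export
render_rgb_summary <- function(maps, channels, tolerance_s = 1.0,
                               spec = render_spec()) {
  if (length(maps) > 3L) stop("RGB planes exhausted: at most 3 channels")
  if (length(maps) != length(channels))
    stop("`maps` and `channels` lengths differ")
  d <- dim(maps[[1]]$amplitude)
  out <- array(0, c(d, 3))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    win <- most_intense_window(channels[[i]])
    lo <- win[1] - tolerance_s; hi <- win[2] + tolerance_s
    ph <- m$tuning_phase_s %% m$period_s
    inwin <- !is.na(ph) & ph >= lo & ph <= hi & m$valid
    upper <- amplitude_upper(m$amplitude, m$valid, spec)
    v <- pmin(pmax(m$amplitude / upper, 0), 1)
    v[!is.finite(v) | !inwin] <- 0
    out[, , i] <- v
  }
  out
}

#' Landmark-based affine estimation and application
#'
#' Least-squares 2-D affine transform mapping source landmark coordinates
#' onto destination coordinates (at least 3 non-collinear pairs), used to
#' co-register maps from different experiments onto a common template
#' before assembling a functional landscape. Application resamples by
#' inverse mapping with bilinear interpolation for scalar planes and
#' nearest-neighbor for masks.
#'
#' @param src,dst n x 2 matrices of (row, col) landmark coordinates.
#' @return `estimate_affine`: a 2 x 3 matrix `A` such that
#'   `dst ~ A %*% c(row, col, 1)`, of class `wf_affine`.
#' @export
estimate_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3L || nrow(dst) != nrow(src))
    stop("need >= 3 landmark pairs")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L)
    stop("landmarks are collinear; the affine transform is degenerate")
  coef <- qr.solve(X, dst)            # 3 x 2
  A <- t(coef)                        # 2 x 3
  if (abs(det(A[, 1:2])) < 1e-12)
    stop("estimated transform is singular")
  structure(A, class = "wf_affine")
}

#' @rdname estimate_affine
#' @param plane numeric (or logical mask) matrix to resample.
#' @param transform a `wf_affine` from [estimate_affine()] (source ->
#'   destination convention).
#' @param target_dim `c(rows, cols)` of the output; defaults to the input.
#' @param interp `"bilinear"` or `"nearest"`; masks default to nearest.
#' @export
apply_affine <- function(plane, transform, target_dim = dim(plane),
                         interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  is_mask <- is.logical(plane)
  if (is_mask) { interp <- "nearest"; plane <- plane * 1 }
  A <- unclass(transform)
  L <- A[, 1:2]; b <- A[, 3]
  Li <- solve(L)
  gr <- as.matrix(expand.grid(r = seq_len(target_dim[1]) - 1,
                              c = seq_len(target_dim[2]) - 1))
  srcc <- t(Li %*% (t(gr) - b))       # source (row, col), 0-based
  out <- matrix(NA_real_, target_dim[1], target_dim[2])
  if (interp == "nearest") {
    ri <- round(srcc[, 1]) + 1; ci <- round(srcc[, 2]) + 1
    ok <- ri >= 1 & ri <= nrow(plane) & ci >= 1 & ci <= ncol(plane)
    out[cbind(gr[ok, 1] + 1, gr[ok, 2] + 1)] <- plane[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(srcc[, 1]); c0 <- floor(srcc[, 2])
    fr <- srcc[, 1] - r0;   fc <- srcc[, 2] - c0
    ok <- r0 >= 0 & r0 <= nrow(plane) - 2 & c0 >= 0 & c0 <= ncol(plane) - 2
    i <- which(ok)
    r1 <- r0[i] + 1; c1 <- c0[i] + 1
    v <- (1 - fr[i]) * (1 - fc[i]) * plane[cbind(r1, c1)] +
         (1 - fr[i]) * fc[i]       * plane[cbind(r1, c1 + 1)] +
         fr[i]       * (1 - fc[i]) * plane[cbind(r1 + 1, c1)] +
         fr[i]       * fc[i]       * plane[cbind(r1 + 1, c1 + 1)]
    out[cbind(gr[i, 1] + 1, gr[i, 2] + 1)] <- v
  }
  if (is_mask) out <- !is.na(out) & out >= 0.5
  out
}

#' Iso-t-value contour lines
#'
#' Marching-squares contours of a t-value map at the given levels (the
#' conventional display levels are 2.0 and 3.4, i.e. two-tailed p < 0.05
#' and p < 0.001 at large n), for overlaying t maps on a functional
#' landscape.
#'
#' @param tmap a [welch_t_map()] result or a bare numeric matrix.
#' @param levels numeric t levels.
#' @return list of contours, each a data.frame with `row`, `col` (0-based
#'   pixel coordinates) and a `level` attribute.
#' @export
iso_t_contours <- function(tmap, levels = c(2.0, 3.4)) {
  z <- if (inherits(tmap, "wf_t_map")) tmap$t else tmap
  if (diff(range(z[is.finite(z)])) == 0) return(list())
  z[!is.finite(z)] <- min(z[is.finite(z)], 0) - 1
  cl <- grDevices::contourLines(x = seq_len(nrow(z)) - 1,
                                y = seq_len(ncol(z)) - 1,
                                z = z, levels = levels)
  lapply(cl, function(li) {
    df <- data.frame(row = li$x, col = li$y)
    attr(df, "level") <- li$level
    df
  })
}

#' Write an RGB array as PNG
#' @param rgb rows x cols x 3 array in the unit interval.
#' @param path output path.
#' @export
write_map_png <- function(rgb, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is needed to write PNG files")
  png::writePNG(rgb, path)
  invisible(path)
}
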