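test_that("HSV rendering clips at the percentile upper limit", {
  nr <- 10; nc <- 10
  amp <- matrix(seq_len(100) * 1e-5, nr, nc)
  tm <- mk_tuning_map(matrix(5, nr, nc), amp)
  img <- render_hsv(tm, render_spec(percentile = 99))
  upper <- quantile(amp, 0.99, names = FALSE)
  # a pixel exactly at the upper limit is fully saturated and bright
  amp2 <- amp; amp2[1, 1] <- upper
  img2 <- render_hsv(mk_tuning_map(matrix(0, nr, nc), amp2),
                     render_spec(percentile = 99))
  expect_equal(img2[1, 1, ], c(1, 0, 0))  # phase 0 -> pure red at full V
  # about 1% of pixels clipped
  v <- pmin(amp / upper, 1)
  expect_lte(abs(sum(v >= 1) - 0.01 * 100), 1)
})

test_that("zero amplitude renders black; cyclic phases share a hue", {
  amp <- matrix(c(0, 1e-3, 1e-3, 1e-3), 2, 2)
  ph <- matrix(c(0, 3, 23, 3), 2, 2)  # 3 and 23 differ by exactly T
  tm <- tuning_map(ph %% 20, amp, 20,
                   valid = matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  img <- render_hsv(tm, render_spec(absolute = 1e-3))
  expect_equal(img[1, 1, ], c(0, 0, 0))
  expect_equal(img[2, 1, ], img[1, 2, ])  # same hue after wrapping
})

test_that("rendering is monotone in amplitude", {
  set.seed(8)
  amp <- matrix(runif(64, 0, 2e-3), 8, 8)
  tm <- mk_tuning_map(matrix(4, 8, 8), amp)
  spec <- render_spec(absolute = 1.5e-3)
  img <- render_hsv(tm, spec)
  amp2 <- amp * 1.2
  img2 <- render_hsv(mk_tuning_map(matrix(4, 8, 8), amp2), spec)
  # value channel (max of rgb) never decreases
  v1 <- apply(img, c(1, 2), max)
  v2 <- apply(img2, c(1, 2), max)
  expect_true(all(v2 >= v1 - 1e-12))
})

test_that("an all-invalid map warns and renders gray", {
  tm <- tuning_map(matrix(1, 2, 2), matrix(1e-3, 2, 2), 20,
                   valid = matrix(FALSE, 2, 2))
  expect_warning(img <- render_hsv(tm), "invalid")
  expect_true(all(img == 0.5))
})

test_that("tonotopy validity applies the tone window and delay range", {
  ph <- matrix(c(1.0, 5.0, 5.0, 18.0), 2, 2)
  dl <- matrix(c(3.9, 3.9, 6.5, 3.9), 2, 2)
  tm <- tuning_map(ph, matrix(1e-3, 2, 2), 20, delay_s = dl)
  ok <- tonotopy_validity(tm)
  expect_false(ok[1, 1])  # phased in the pre-silence
  expect_true(ok[2, 1])   # in window, delay acceptable
  expect_false(ok[1, 2])  # delay out of range
  expect_false(ok[2, 2])  # phased in the post-silence
})

test_that("retinotopy composite maps center tuning to white, no motion to black", {
  Tc <- 20
  polar <- mk_tuning_map(matrix(0, 2, 2), matrix(1e-3, 2, 2))
  ecc_center <- mk_tuning_map(matrix(Tc / 2, 2, 2), matrix(1e-3, 2, 2))
  motion <- mk_tuning_map(matrix(1e-3, 2, 2), matrix(1e-3, 2, 2))
  img <- render_retinotopy_composite(polar, ecc_center, motion,
                                     render_spec(absolute = 1e-3))
  expect_equal(img[1, 1, ], c(1, 1, 1))  # bright white

  m0 <- mk_tuning_map(matrix(1e-3, 2, 2), matrix(0, 2, 2))
  img0 <- render_retinotopy_composite(polar, ecc_center, m0,
                                      render_spec(absolute = 1e-3))
  expect_equal(img0[1, 1, ], c(0, 0, 0))

  # periphery tuning (phase 0) at 12 o'clock: fully saturated reference hue
  ecc_peri <- mk_tuning_map(matrix(0, 2, 2), matrix(1e-3, 2, 2))
  imgp <- render_retinotopy_composite(polar, ecc_peri, motion,
                                      render_spec(absolute = 1e-3))
  expect_equal(imgp[1, 1, ], c(1, 0, 0))  # hue 0 at saturation 1
})

test_that("RGB summary masks phases to the peak-stimulus window", {
  cfg <- build_parcellation_schedule()
  vis <- cfg$channels[[3]]           # plateau window 7-11 s
  amp <- matrix(1e-3, 1, 3)
  ph <- matrix(c(9, 12.5, 6.5), 1, 3)  # center, 1.5 s late, within 1 s tol
  tm <- mk_tuning_map(ph, amp, period_s = 18)
  img <- render_rgb_summary(list(tm), list(vis),
                            spec = render_spec(absolute = 1e-3))
  expect_gt(img[1, 1, 1], 0)   # at stimulus center: included
  expect_equal(img[1, 2, 1], 0)  # phased 1.5 s after offset: excluded
  expect_gt(img[1, 3, 1], 0)   # within the 1 s tolerance

  expect_error(render_rgb_summary(rep(list(tm), 4), rep(list(vis), 4)),
               "RGB planes")
})

test_that("disjoint planted regions give unmixed RGB colors", {
  cfg <- build_parcellation_schedule(frame_rate_hz = 5)
  nr <- 4; nc <- 6
  region <- function(cols) { a <- matrix(0, nr, nc); a[, cols] <- 1e-3; a }
  maps <- list(tuning_map(matrix(11, nr, nc), region(1:2), 22,
                          valid = region(1:2) > 0),
               tuning_map(matrix(9.9, nr, nc), region(3:4), 19.8,
                          valid = region(3:4) > 0),
               tuning_map(matrix(9, nr, nc), region(5:6), 18,
                          valid = region(5:6) > 0))
  img <- render_rgb_summary(maps, cfg$channels,
                            spec = render_spec(absolute = 1e-3))
  nonzero <- apply(img > 0, c(1, 2), sum)
  expect_true(all(nonzero <= 1))        # no mixed-color pixels
  expect_true(all(img[, 1:2, 1] > 0))   # each region in its own plane
  expect_true(all(img[, 3:4, 2] > 0))
  expect_true(all(img[, 5:6, 3] > 0))
})

test_that("affine estimation recovers identity, translation, and inverts", {
  src <- cbind(c(0, 10, 0, 7), c(0, 0, 12, 5))
  idt <- estimate_affine(src, src)
  expect_equal(unclass(idt), cbind(diag(2), c(0, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)

  shift <- estimate_affine(src, src + rep(c(3, -2), each = 4))
  expect_equal(unclass(shift)[, 3], c(3, -2), tolerance = 1e-12)

  set.seed(12)
  A <- cbind(matrix(c(1.1, 0.2, -0.1, 0.9), 2), c(4, -3))
  dst <- t(A[, 1:2] %*% t(src) + A[, 3])
  est <- estimate_affine(src, dst)
  expect_lt(max(abs(unclass(est) - A)), 1e-9)
  # round trip through the inverse transform
  back <- estimate_affine(dst, src)
  rt <- t(unclass(back)[, 1:2] %*% t(dst) + unclass(back)[, 3])
  expect_lt(max(abs(rt - src)), 1e-9)

  col <- cbind(1:4, 2 * (1:4))  # collinear
  expect_error(estimate_affine(col, col), "collinear")
})

test_that("affine application resamples planes and masks sensibly", {
  plane <- outer(1:20, 1:20, function(r, c) r + 0.5 * c)
  tr <- structure(cbind(diag(2), c(2, 3)), class = "wf_affine")
  out <- apply_affine(plane, tr)
  # pure translation of a linear field: interior shifts exactly
  expect_equal(out[10, 10], plane[8, 7], tolerance = 1e-9)

  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  mout <- apply_affine(mask, tr)
  n0 <- sum(mask); n1 <- sum(mout, na.rm = TRUE)
  expect_lte(abs(n1 - n0) / n0, 0.02)
})

test_that("iso-t contours behave at degenerate and regular fields", {
  expect_length(iso_t_contours(matrix(1, 10, 10), levels = 2), 0)

  r <- sqrt(outer((1:30 - 15)^2, (1:30 - 15)^2, "+"))
  z <- 5 * exp(-(r / 6)^2)
  cl <- iso_t_contours(z, levels = 2)
  expect_gte(length(cl), 1)
  ring <- cl[[1]]
  # closed loop around the peak
  expect_equal(ring[1, ], ring[nrow(ring), ], tolerance = 1e-9,
               ignore_attr = TRUE)
  rad <- sqrt((ring$row - 14)^2 + (ring$col - 14)^2)
  expect_lt(diff(range(rad)), 1)  # circular ring
  expect_length(iso_t_contours(z, levels = 10), 0)  # above the max
})
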