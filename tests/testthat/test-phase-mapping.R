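brute_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

test_that("pixel spectrum equals direct-summation DFT", {
  set.seed(21)
  x <- rnorm(32)
  mov <- movie(array(x * 1e-3, c(32, 1, 1)), 1, "relative")
  co <- pixel_spectrum(mov)$coef[, 1, 1]
  expect_lt(max(Mod(co - brute_dft(x * 1e-3))), 1e-10)
})

test_that("an exact-bin cosine concentrates in its bin; constants in DC", {
  fps <- 5; dur <- 80; Tc <- 20
  tt <- (seq_len(fps * dur) - 0.5) / fps
  x <- 1e-3 * cos(2 * pi * tt / Tc)
  mov <- movie(array(x, c(length(x), 1, 1)), fps, "relative")
  sp <- pixel_spectrum(mov)
  amps <- 2 * Mod(sp$coef[, 1, 1]) / length(x)
  k <- dur / Tc  # bin index of the stimulation frequency
  expect_equal(amps[k + 1], 1e-3, tolerance = 1e-12)
  expect_lt(max(amps[-c(1, k + 1, length(x) + 1 - k)]), 1e-15)

  const <- movie(array(2e-3, c(50, 1, 1)), fps, "relative")
  ac <- Mod(pixel_spectrum(const)$coef[-1, 1, 1])
  expect_lt(max(ac), 1e-15)
})

test_that("channel extraction recovers planted phase and amplitude", {
  cfg <- std_session(n_cycles = 3)
  tr <- ground_truth(
    channels = list(tones = list(preferred_time_s = matrix(5, 2, 2),
                                 amplitude = matrix(2e-3, 2, 2))),
    delay_s = 0)
  mov <- synthesize_movie(tr, cfg, noise_sd_permille = 0)
  rm_ <- extract_channel_response(pixel_spectrum(mov), cfg$channels[[1]])
  expect_equal(as.vector(rm_$phase_time_s), rep(5, 4), tolerance = 1e-9)
  expect_equal(as.vector(rm_$amplitude), rep(2e-3, 4), tolerance = 1e-9)
})

test_that("an uncompensated polarity flip shifts the phase by half a cycle", {
  cfg <- std_session(n_cycles = 2)
  tr <- ground_truth(
    channels = list(tones = list(preferred_time_s = matrix(5, 1, 1),
                                 amplitude = matrix(1e-3, 1, 1))),
    delay_s = 0)
  mov <- synthesize_movie(tr, cfg, noise_sd_permille = 0)
  sp <- pixel_spectrum(mov)
  good <- extract_channel_response(sp, cfg$channels[[1]], polarity = -1)
  flipped <- extract_channel_response(sp, cfg$channels[[1]], polarity = +1)
  expect_equal((flipped$phase_time_s - good$phase_time_s) %% 20,
               matrix(10, 1, 1), tolerance = 1e-9)
})

test_that("off-bin channel frequencies are refused", {
  cfg <- std_session(n_cycles = 2)
  tr <- random_truth(2, 2)
  mov <- synthesize_movie(tr, cfg, noise_sd_permille = 0)
  sp <- pixel_spectrum(mov)
  odd <- stimulus_channel("odd", cycle_period_s = 13, n_cycles = 2)
  expect_error(extract_channel_response(sp, odd, polarity = -1), "bin")
})

test_that("a zero trace yields zero amplitude and a masked phase", {
  cfg <- std_session(n_cycles = 1)
  mov <- synthesize_movie(random_truth(2, 2, amplitude = 0), cfg, 0)
  rm_ <- extract_channel_response(pixel_spectrum(mov), cfg$channels[[1]])
  expect_true(all(rm_$amplitude == 0))
  expect_true(all(is.na(rm_$phase_time_s)))
  expect_true(all(!rm_$valid))
})

test_that("delay compensation subtracts modulo the cycle period", {
  mk <- function(phase, Tc) {
    structure(list(amplitude = matrix(1e-3, 1, 1),
                   phase_time_s = matrix(phase, 1, 1), period_s = Tc,
                   label = "x", polarity_compensated = TRUE,
                   valid = matrix(TRUE, 1, 1)),
              class = "wf_response_map")
  }
  expect_equal(compensate_delay(mk(8.9, 20), 3.9)$tuning_phase_s[1, 1], 5.0)
  expect_equal(compensate_delay(mk(1.0, 18), 3.7)$tuning_phase_s[1, 1], 15.3)
  expect_equal(compensate_delay(mk(4.2, 20), 0)$tuning_phase_s[1, 1], 4.2)
  expect_equal(default_delay("tonotopy"), 3.9)
  expect_equal(default_delay("retinotopy_polar"), 3.5)
  expect_equal(default_delay(), 3.7)
})

test_that("parcellation separates disjoint modality regions", {
  cfg <- build_parcellation_schedule(frame_rate_hz = 5)
  nr <- 6; nc <- 9
  region <- function(cols) {
    a <- matrix(0, nr, nc); a[, cols] <- 1e-3; a
  }
  pref <- matrix(5, nr, nc)
  tr <- ground_truth(
    channels = list(SOM = list(preferred_time_s = pref,
                               amplitude = region(1:3)),
                    AUD = list(preferred_time_s = pref,
                               amplitude = region(4:6)),
                    VIS = list(preferred_time_s = pref,
                               amplitude = region(7:9))),
    delay_s = 3.7)
  mov <- synthesize_movie(tr, cfg, noise_sd_permille = 0)
  maps <- parcellate(mov, cfg)
  regions <- list(SOM = 1:3, AUD = 4:6, VIS = 7:9)
  for (lab in names(regions)) {
    inside <- maps[[lab]]$amplitude[, regions[[lab]]]
    outside <- maps[[lab]]$amplitude[, setdiff(1:9, regions[[lab]])]
    expect_gt(min(inside), 100 * max(max(outside), 1e-15))
  }
})

test_that("channels sharing a bin are refused", {
  ch1 <- stimulus_channel("a", 20, 20)
  ch2 <- stimulus_channel("b", 20, 20)
  cfg <- session_config(list(ch1, ch2), duration_s = 400)
  mov <- synthesize_movie(random_truth(2, 2, label = "a"), cfg, 0)
  expect_error(parcellate(mov, cfg), "share a spectral bin")
})

test_that("Parseval holds and amplitude ignores constant offsets", {
  fps <- 5; dur <- 40; Tc <- 20
  tt <- (seq_len(fps * dur) - 0.5) / fps
  x <- 1e-3 * cos(2 * pi * (tt - 3) / Tc)
  mov <- movie(array(x, c(length(x), 1, 1)), fps, "relative")
  sp <- pixel_spectrum(mov)
  n <- length(x)
  amps <- 2 * Mod(sp$coef[2:(n / 2), 1, 1]) / n
  v <- mean(x^2) - mean(x)^2
  expect_equal(sum(amps^2), 2 * v, tolerance = 1e-9)

  ch <- stimulus_channel("c", Tc, dur / Tc)
  cfg_amp <- function(offset) {
    m <- movie(array(x + offset, c(n, 1, 1)), fps, "relative")
    extract_channel_response(pixel_spectrum(m), ch, polarity = -1)$amplitude
  }
  expect_equal(cfg_amp(0), cfg_amp(5e-3), tolerance = 1e-12)
})

test_that("phase recovery on noiseless random plants is sub-frame", {
  nr <- 10; nc <- 10
  set.seed(9)
  s <- matrix(runif(nr * nc, 0, 20), nr, nc)
  d <- matrix(runif(nr * nc, 0, 8), nr, nc)
  cfg <- std_session(n_cycles = 2)
  tr <- ground_truth(
    channels = list(tones = list(preferred_time_s = s,
                                 amplitude = matrix(1e-3, nr, nc))),
    delay_s = d)
  mov <- synthesize_movie(tr, cfg, noise_sd_permille = 0)
  rm_ <- extract_channel_response(pixel_spectrum(mov), cfg$channels[[1]])
  err <- abs((rm_$phase_time_s - (s + d)) %% 20)
  err <- pmin(err, 20 - err)
  expect_lt(max(err), 0.5 / 5)
})

test_that("polarity table matches the tested wavelengths", {
  tab <- polarity_table()
  expect_equal(tab$sign, c(-1, -1, 1, 1, 1, -1))
  expect_true(tab$ambiguous[tab$wavelength_nm == 590])
  expect_equal(polarity_sign(530), -1)
  expect_error(polarity_sign(600), "no tabulated polarity")
})
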