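test_that("the skull scattering power law reproduces the tabulated column", {
  tab <- optical_properties()
  sk <- tab[tab$tissue == "skull", ]
  # agreement to the printed 2 d.p. (one table entry, 730 nm, is off by a
  # single unit in its last digit from its own power law)
  expect_true(all(abs(skull_mus_prime(sk$wavelength_nm) - sk$mu_s_mm)
                  <= 0.011))
  expect_equal(round(skull_mus_prime(530), 2), 25.99)
  expect_equal(round(skull_mus_prime(470), 2), 28.10)
  expect_equal(round(skull_mus_prime(850), 2), 19.12)
})

test_that("scattering closed forms", {
  expect_equal(reduced_scattering(10, 0.9), 1.0)
  expect_equal(reduced_scattering(7, 0), 7)
  musp <- reduced_scattering(25.99, 0.92)
  expect_equal(musp, 2.0792)
  expect_equal(depolarization_length(musp), 1 / 2.0792, tolerance = 1e-12)
  expect_equal(mean_free_path(25.99), 1 / 25.99)
})

test_that("blood-based brain absorption has the right limits", {
  expect_equal(brain_absorption(3e4, 4e4, blood_volume_fraction = 0), 0)
  # isosbestic: independent of the HbR/HbO split
  expect_equal(brain_absorption(39000, 39000, hbr_fraction = 0.25),
               brain_absorption(39000, 39000, hbr_fraction = 0.75))
  # back-solve the effective extinction from the tabulated 530 nm value,
  # then the forward computation reproduces it
  target <- optical_properties()
  target <- target[target$wavelength_nm == 530 &
                     target$tissue == "gray", "mu_a_mm"]
  eps_eff <- target * 10 / (0.03 * log(10) * 2e-3)
  expect_equal(brain_absorption(eps_eff, eps_eff), target,
               tolerance = 1e-12)
  expect_error(brain_absorption(-1, 10), "non-negative")
})

test_that("defocus tolerance follows h = D n / (2 NA)", {
  expect_equal(defocus_tolerance(0.30, 1, 0.03), 5.0)
  expect_equal(defocus_tolerance(0), 0)
  expect_equal(defocus_tolerance(0.3, 1, 0.06),
               defocus_tolerance(0.3, 1, 0.03) / 2)
})

test_that("medium stack carries the tabulated layer properties", {
  med <- medium_stack(530)
  expect_equal(vapply(med$layers, `[[`, numeric(1), "thickness_mm"),
               c(0.5, 1.3, 8.2))
  expect_equal(med$layers[[1]]$n, 1.56)
  expect_equal(med$layers[[2]]$mu_a, 0.638)
  expect_equal(med$layers[[3]]$g, 0.810)
  expect_error(medium_stack(555), "no tabulated")
  expect_error(medium_stack(530, thicknesses_mm = c(1, 1, 1)), "sum")
})

test_that("Beer weights follow the exponential identities", {
  lp <- rbind(c(1, 0, 0), c(0.5, 2, 3))
  ph <- fake_photons(lp)
  expect_equal(beer_weight(ph, c(0, 0, 0)), c(1, 1))
  expect_equal(beer_weight(ph, c(0.638, 0, 0))[1], exp(-0.638))
  # doubling every path squares the weight
  ph2 <- fake_photons(2 * lp)
  mu <- c(0.1137, 0.638, 0.638)
  expect_equal(beer_weight(ph2, mu), beer_weight(ph, mu)^2,
               tolerance = 1e-12)
  # additivity in mu_a
  expect_equal(beer_weight(ph, mu) * beer_weight(ph, 2 * mu),
               beer_weight(ph, 3 * mu), tolerance = 1e-12)
})

test_that("every launched photon is accounted for exactly once", {
  med <- medium_stack(530)
  ph <- simulate_photons(med, n_photons = 2e4, seed = 3, n_rotations = 1)
  expect_equal(ph$n_collected + ph$n_escaped + ph$n_terminated, 2e4)
  expect_true(all(ph$layer_paths >= 0))
  # collected exit directions are inside the NA cone
  sines <- sqrt(ph$exit_dirs[, 1]^2 + ph$exit_dirs[, 2]^2)
  expect_true(all(sines <= 0.03 + 1e-12))
})

test_that("simulation is deterministic per seed", {
  med <- medium_stack(530)
  a <- simulate_photons(med, n_photons = 5e3, seed = 9, n_rotations = 2)
  b <- simulate_photons(med, n_photons = 5e3, seed = 9, n_rotations = 2)
  c <- simulate_photons(med, n_photons = 5e3, seed = 10, n_rotations = 2)
  expect_identical(a$layer_paths, b$layer_paths)
  expect_identical(a$voxel, b$voxel)
  expect_false(identical(a$n_collected, c$n_collected) &&
                 identical(a$layer_paths, c$layer_paths))
})

test_that("a scattering-free slab is ballistic: nothing comes back", {
  med <- structure(
    list(layers = list(optical_layer("clear", 10, 0, 1e-9, 0, 1.0)),
         cube_mm = 10, ambient_n = 1.0, wavelength_nm = NA),
    class = "wf_medium")
  ph <- simulate_photons(med, n_photons = 1e3, seed = 1, voxel_layer = 1L,
                         n_rotations = 1)
  expect_equal(ph$n_collected, 0)
  expect_equal(ph$n_escaped, 1e3)
  expect_error(perturbation_profile(ph, mu_a = 0.1), "no collected")
})

test_that("strongly forward scattering collects almost nothing", {
  med <- structure(
    list(layers = list(optical_layer("fwd", 10, 0, 0.2, 0.999, 1.0)),
         cube_mm = 10, ambient_n = 1.0, wavelength_nm = NA),
    class = "wf_medium")
  ph <- simulate_photons(med, n_photons = 5e3, seed = 2, voxel_layer = 1L,
                         n_rotations = 1)
  expect_lt(ph$n_collected / 5e3, 0.01)
})

test_that("perturbation equals brute-force Beer recomputation", {
  med <- medium_stack(530)
  ph <- simulate_photons(med, n_photons = 2e5, seed = 7, n_rotations = 1)
  expect_gt(nrow(ph$voxel), 50)
  mu <- vapply(med$layers, `[[`, numeric(1), "mu_a")
  pf <- 0.10
  pr <- perturbation_profile(ph, mu, perturb_fraction = pf)
  # brute force: full Eq.-1 weight with the voxel's mu_a raised by 10%,
  # subtracted from the unperturbed weight, summed per voxel column
  W <- beer_weight(ph, mu)
  ixs <- sort(unique(ph$voxel$ix))
  brute <- vapply(ixs, function(ix) {
    rows <- ph$voxel[ph$voxel$ix == ix, ]
    lp <- ph$layer_paths[rows$photon, , drop = FALSE]
    # perturbed gray path: (x_gray - x_v) at mu_a + x_v at 1.1 mu_a
    w_base <- exp(-(lp %*% mu))
    w_pert <- exp(-(lp %*% mu) - pf * mu[2] * rows$path_mm)
    sum(w_base - w_pert)
  }, numeric(1))
  got <- pr$profile$delta_r[match(ixs * ph$voxel_pitch_mm,
                                  pr$profile$offset_mm)]
  expect_lt(max(abs(got - brute)), 1e-12)
})

test_that("collection statistics are stable across seeds", {
  med <- medium_stack(530)
  stats <- lapply(1:3, function(s)
    simulate_photons(med, n_photons = 3e5, seed = s, n_rotations = 1))
  frac <- vapply(stats, function(p) p$n_collected / p$n_launched,
                 numeric(1))
  skull <- vapply(stats, function(p) mean(p$layer_paths[, "skull"]),
                  numeric(1))
  # binomial MC standard error on the collected fraction
  se_frac <- sqrt(mean(frac) * (1 - mean(frac)) / 3e5)
  expect_lt(max(abs(frac - mean(frac))), 3 * se_frac * 2)
  expect_lt(max(abs(skull - mean(skull))) / mean(skull), 0.2)
})
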