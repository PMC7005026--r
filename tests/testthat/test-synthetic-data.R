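# Generators: determinism, geometry, closed-form agreement, input checks.

test_that("bilayer generator is deterministic, mirrored, and geometric", {
  spec <- bilayer_gen_spec(lipids_per_leaflet = 100, area_per_lipid = 64,
                           thermal_noise_sd = 0, seed = 42)
  t1 <- generate_bilayer(spec, n_frames = 1)
  t2 <- generate_bilayer(spec, n_frames = 1)
  expect_identical(t1$frames[[1]], t2$frames[[1]])
  # 100 lipids at 64 A^2 -> 80 A lateral box edge
  expect_equal(t1$box[1], 80)
  expect_equal(t1$box[2], 80)
  # noise-free leaflet mirror symmetry: the lower leaflet is the upper
  # leaflet with z negated
  up <- t1$atoms$leaflet == "upper"
  lo <- t1$atoms$leaflet == "lower"
  p <- t1$frames[[1]]
  expect_equal(p[lo, 1:2], p[up, 1:2], ignore_attr = TRUE)
  expect_equal(p[lo, 3], -p[up, 3], ignore_attr = TRUE)
})

test_that("bilayer atom count is conserved across frames and seeds vary noise", {
  spec <- bilayer_gen_spec(lipids_per_leaflet = 9, thermal_noise_sd = 0.4,
                           seed = 5)
  traj <- generate_bilayer(spec, n_frames = 4)
  n <- vapply(traj$frames, nrow, integer(1))
  expect_true(all(n == n[1]))
  expect_false(identical(traj$frames[[1]], traj$frames[[2]]))
  # same seed reproduces every frame bit for bit
  again <- generate_bilayer(spec, n_frames = 4)
  expect_identical(traj$frames, again$frames)
})

test_that("straight chains fill the 3-10 A sensor band more than kinked ones", {
  t_straight <- quick_bilayer(0)
  t_kinked <- quick_bilayer(1)
  b_straight <- band_statistic(voxel_density(center_and_wrap(t_straight)))
  b_kinked <- band_statistic(voxel_density(center_and_wrap(t_kinked)))
  expect_gt(b_straight$mean, b_kinked$mean)
  expect_gt(b_kinked$mean, 0)  # cis-analog tails still reach the band
})

test_that("bilayer generator rejects non-physical specifications", {
  expect_error(bilayer_gen_spec(0), "lipids_per_leaflet")
  expect_error(bilayer_gen_spec(10, area_per_lipid = -1), "area_per_lipid")
  expect_error(bilayer_gen_spec(10, fraction_kinked_chains = 1.5), "fraction")
  expect_error(bilayer_gen_spec(10, thermal_noise_sd = -0.1), "noise")
  expect_error(generate_bilayer(bilayer_gen_spec(10), n_frames = 0),
               "n_frames")
})

test_that("dimer generator honors degenerate weights and rejects bad specs", {
  spec <- dimer_gen_spec(c(1, 0, 0), angular_sd = 0, n_frames = 50, seed = 3)
  d <- generate_dimer(spec)
  series <- analyze_dimer(d)
  expect_true(all(series$state == "facing-facing"))
  expect_error(dimer_gen_spec(c(0.6, 0.6, 0.2)), "sum to 1")
  expect_error(dimer_gen_spec(c(0.5, 0.3, 0.2), n_frames = 0), "n_frames")
})

test_that("dimer state mixture is recovered within binomial error", {
  w <- c(0.5, 0.3, 0.2)
  n <- 10000
  d <- generate_dimer(dimer_gen_spec(w, n_frames = n, seed = 17))
  pops <- state_populations(analyze_dimer(d), n_boot = 50, seed = 1)
  se <- sqrt(w * (1 - w) / n)
  expect_true(all(abs(pops$fraction - w) <= 3 * se))
})

test_that("emission spectrum generator peaks where told and is reproducible", {
  s <- generate_emission_spectrum(list(c(525, 10, 2)),
                                  grid = seq(450, 650, 1))
  expect_equal(s$wavelength[which.max(s$intensity)], 525)
  a <- generate_emission_spectrum(list(c(430, 10, 1)), noise_sd = 0.05,
                                  seed = 9)
  b <- generate_emission_spectrum(list(c(430, 10, 1)), noise_sd = 0.05,
                                  seed = 9)
  expect_identical(a$intensity, b$intensity)
  expect_true(all(a$intensity >= 0))
  expect_error(generate_emission_spectrum(list()), "empty")
})

test_that("FCS generator matches the 2D+triplet closed form exactly", {
  lag <- 10^seq(-6, 0, length.out = 60)
  cv <- generate_fcs_curve(N = 10, tau_D = 1e-3, T = 0, lag_grid = lag)
  expect_equal(cv$G, 1 / 10 / (1 + lag / 1e-3))
  # tau = tau_D, T = 0 -> G = 1/(2N)
  cv2 <- generate_fcs_curve(N = 5, tau_D = 1e-3, T = 0,
                            lag_grid = c(1e-5, 1e-3, 1e-1))
  expect_equal(cv2$G[2], 1 / (2 * 5))
  # with triplet: the closed form at every lag
  cv3 <- generate_fcs_curve(N = 8, tau_D = 2e-3, T = 0.15, tau_T = 4e-6,
                            lag_grid = lag)
  expect_equal(cv3$G, (1 + 0.15 / 0.85 * exp(-lag / 4e-6)) / 8 /
                 (1 + lag / 2e-3))
  expect_error(generate_fcs_curve(10, 1e-3, T = 1), "T")
})

test_that("EPR generator reproduces constructed amplitudes and broadening trend", {
  s <- generate_epr_spectrum(broadening = 0, amplitudes = c(0.5, 1.0, 0.3))
  expect_equal(epr_proximity_index(s), 0.5, tolerance = 1e-3)
  idx <- vapply(c(0, 0.25, 0.5, 1), function(b)
    epr_proximity_index(generate_epr_spectrum(b, c(0.5, 1.0, 0.3))),
    numeric(1))
  expect_true(all(diff(idx) < 0))
  expect_error(generate_epr_spectrum(field_grid = c(1, 1, 2)), "increasing")
  expect_error(
    epr_proximity_index(generate_epr_spectrum(0, c(0.5, 0, 0.3))),
    "unresolvable|not positive")
})
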