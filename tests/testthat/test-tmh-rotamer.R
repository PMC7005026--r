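# Helix axes, sensor azimuths, state classification and populations.

rotation_matrix <- function(ax, ang) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

test_that("helix axis recovers line, helix, and rotated orientations", {
  line <- cbind(0, 0, seq(0, 10, length.out = 8))
  ax <- helix_axis(line)
  expect_equal(abs(sum(ax$axis * c(0, 0, 1))), 1, tolerance = 1e-12)
  expect_equal(sum(ax$axis * c(0, 0, 1)), 1)   # oriented N -> C
  # ideal helix: axis within 1 degree of z
  h <- memprofiler:::.ideal_helix(30)
  axh <- helix_axis(h)
  ang <- acos(abs(sum(axh$axis * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
  # equivariance under rotation
  R <- rotation_matrix(c(1, 2, 0.5), 0.9)
  axr <- helix_axis(h %*% t(R))
  expect_equal(as.numeric(R %*% axh$axis), axr$axis, tolerance = 1e-9)
  expect_error(helix_axis(h[1:3, ]), "n >= 4")
})

test_that("sensor azimuth matches analytic constructions", {
  # helix A around z at origin, partner axis along +x; choose the helix
  # phase so the sensor residue sits at a prescribed lab azimuth
  # 36 residues = an integer number of turns, so the helix centroid lies
  # on the axis and the construction is exact up to the axis fit
  make_frame <- function(target_deg, sensor = 15, n = 36) {
    alpha0 <- (sensor - 1) * 100 * pi / 180
    A <- memprofiler:::.ideal_helix(n, phase = target_deg * pi / 180 - alpha0)
    B <- memprofiler:::.ideal_helix(n)
    B[, 1] <- B[, 1] + 9
    list(A = A, B = B)
  }
  for (target in c(0, 90, 180, -90)) {
    phi <- sensor_azimuth(make_frame(target), 1, 15)
    delta <- (phi - target + 180) %% 360 - 180
    expect_lt(abs(delta), 2)
  }
  # rigid rotation of the whole frame leaves azimuths unchanged
  fr <- make_frame(37)
  R <- rotation_matrix(c(0.3, 1, 2), 1.2)
  fr_rot <- list(A = fr$A %*% t(R), B = fr$B %*% t(R))
  expect_equal(sensor_azimuth(fr_rot, 1, 15), sensor_azimuth(fr, 1, 15),
               tolerance = 1e-6)
})

test_that("state classification partitions the azimuth plane", {
  expect_equal(classify_state(0, 0), "facing-facing")
  expect_equal(classify_state(180, 180), "away-away")
  expect_equal(classify_state(0, 180), "mixed")
  expect_equal(classify_state(90, 90), "mixed")
  expect_equal(classify_state(-170, 150), "away-away")
  # vectorized and threshold-sensitive
  expect_equal(classify_state(c(50, 70), c(50, 70), facing_threshold = 60),
               c("facing-facing", "mixed"))
})

test_that("populations sum to one, ignore frame order, and bound the truth", {
  d <- generate_dimer(dimer_gen_spec(c(0.5, 0.3, 0.2), n_frames = 10000,
                                     seed = 23))
  series <- analyze_dimer(d)
  pops <- state_populations(series, n_boot = 100, seed = 4)
  expect_equal(sum(pops$fraction), 1)
  w <- c(0.5, 0.3, 0.2)
  se <- sqrt(w * (1 - w) / nrow(series))
  expect_true(all(abs(pops$fraction - w) <= 3 * se))
  expect_true(all(pops$ci_lo <= pops$fraction & pops$fraction <= pops$ci_hi))
  # plain estimator is exchangeable over frames
  perm <- series[sample(nrow(series)), ]
  pops_perm <- state_populations(perm, n_boot = 10, seed = 4)
  expect_equal(pops_perm$fraction, pops$fraction)
})

test_that("degenerate population input is handled", {
  d <- generate_dimer(dimer_gen_spec(c(1, 0, 0), angular_sd = 0,
                                     n_frames = 20, seed = 1))
  series <- analyze_dimer(d)
  pops <- state_populations(series, n_boot = 50, seed = 2)
  expect_equal(pops$fraction, c(1, 0, 0))
  expect_equal(pops$ci_lo, pops$ci_hi)   # zero-width CI
  expect_error(state_populations(series, n_boot = 0), "n_boot")
})

test_that("mixture recovery holds across many seeds", {
  w <- c(0.6, 0.25, 0.15)
  n <- 2000
  se <- sqrt(w * (1 - w) / n)
  hits <- vapply(1:20, function(s) {
    d <- generate_dimer(dimer_gen_spec(w, n_frames = n, seed = s))
    pops <- state_populations(analyze_dimer(d), n_boot = 1, seed = 1)
    all(abs(pops$fraction - w) <= 3 * se)
  }, logical(1))
  expect_gte(sum(hits), 19)
})
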