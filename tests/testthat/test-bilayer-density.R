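# Voxel maps: binning oracle, mass conservation, projections, differences.

test_that("voxel density matches brute-force binning on random points", {
  set.seed(101)
  n <- 10000
  box <- c(10, 10, 10)
  pos <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, -5, 5))
  traj <- make_point_traj(pos, box)
  map <- voxel_density(traj, voxel_edge = 1)
  # independent oracle: per-voxel counting loop over the 1000 voxels
  oracle <- array(0, dim = c(10, 10, 10))
  zs <- pos[, 3] + 5
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    oracle[i, j, k] <- sum(pos[, 1] >= i - 1 & pos[, 1] < i &
                             pos[, 2] >= j - 1 & pos[, 2] < j &
                             zs >= k - 1 & zs < k)
  }
  expect_identical(map$density * 1^3, oracle)
  # mean density n / box volume, integral = atom count
  expect_equal(mean(map$density), n / prod(box))
  expect_equal(sum(map$density) * map$voxel_edge^3, n)
})

test_that("density integral conserves the mean atom count per frame", {
  traj <- center_and_wrap(quick_bilayer(0.5, n_frames = 3, noise = 0.4))
  map <- voxel_density(traj)
  integral <- sum(map$density) * map$voxel_edge^3
  expect_lt(abs(integral - map$n_atoms_mean) / map$n_atoms_mean, 1e-6)
})

test_that("duplicating frames leaves the averaged map unchanged", {
  traj <- center_and_wrap(quick_bilayer(0, n_frames = 2, noise = 0.3))
  doubled <- bilayer_trajectory(c(traj$frames, traj$frames), traj$box,
                                traj$atoms, traj$label)
  expect_equal(voxel_density(traj)$density, voxel_density(doubled)$density)
})

test_that("center_and_wrap recenters, wraps, and is idempotent", {
  traj <- quick_bilayer(0, n_frames = 1)
  shifted <- traj
  shifted$frames[[1]][, 3] <- shifted$frames[[1]][, 3] + 5
  shifted$frames[[1]][, 1] <- shifted$frames[[1]][, 1] + traj$box[1] + 1
  cw <- center_and_wrap(shifted)
  hg_up <- traj$atoms$role == "headgroup" & traj$atoms$leaflet == "upper"
  hg_lo <- traj$atoms$role == "headgroup" & traj$atoms$leaflet == "lower"
  p <- cw$frames[[1]]
  expect_equal((mean(p[hg_up, 3]) + mean(p[hg_lo, 3])) / 2, 0,
               tolerance = 1e-9)
  expect_true(all(p[, 1] >= 0 & p[, 1] < traj$box[1]))
  # atom pushed past the box face comes back near the origin
  expect_equal(p[, 1], (traj$frames[[1]][, 1] + 1) %% traj$box[1])
  # idempotence
  cw2 <- center_and_wrap(cw)
  expect_equal(cw2$frames[[1]], cw$frames[[1]], tolerance = 1e-9)
  # a leaflet without headgroups cannot define a midplane
  broken <- traj
  broken$atoms$role[broken$atoms$role == "headgroup" &
                      broken$atoms$leaflet == "lower"] <- "glycerol"
  expect_error(center_and_wrap(broken), "headgroup")
})

test_that("depth x lateral projection preserves the mean and y-invariance", {
  set.seed(7)
  pos <- cbind(runif(500, 0, 8), runif(500, 0, 8), runif(500, -4, 4))
  map <- voxel_density(make_point_traj(pos, c(8, 8, 8)))
  proj <- project_depth_lateral(map)
  expect_equal(mean(proj$density), mean(map$density))
  expect_equal(dim(proj$density), dim(map$density)[c(3, 1)])
  # a map constant in y projects to any y-slice
  mapc <- map
  xz <- matrix(seq_len(8 * 8), 8, 8)      # arbitrary x-z pattern
  mapc$density <- aperm(array(xz, dim = c(8, 8, 8)), c(1, 3, 2))
  projc <- project_depth_lateral(mapc)
  expect_equal(projc$density, t(mapc$density[, 1, ]))
})

test_that("depth profile peaks at the headgroups and dips at the center", {
  traj <- center_and_wrap(quick_bilayer(0, n_frames = 2, noise = 0.2))
  map <- voxel_density(traj)
  prof <- depth_profile(map, symmetrize = TRUE)
  headband <- prof$density[prof$z >= 17 & prof$z <= 26]
  center <- prof$density[prof$z <= 2]
  expect_gt(max(prof$density), 0)
  expect_gt(mean(headband), mean(center))
  # mirror-symmetric noise-free map: symmetrized equals folded raw profile
  traj0 <- center_and_wrap(quick_bilayer(0, n_frames = 1, noise = 0))
  map0 <- voxel_density(traj0)
  raw <- depth_profile(map0)
  sym <- depth_profile(map0, symmetrize = TRUE)
  folded <- (raw$density[raw$z > 0][order(raw$z[raw$z > 0])] +
               raw$density[raw$z < 0][order(raw$z[raw$z < 0],
                                            decreasing = TRUE)]) / 2
  expect_equal(sym$density, folded)
})

test_that("difference maps are zero on self, antisymmetric, and band-positive", {
  t_sat <- center_and_wrap(quick_bilayer(0))
  t_cis <- center_and_wrap(quick_bilayer(1))
  m_sat <- voxel_density(t_sat); m_cis <- voxel_density(t_cis)
  self <- difference_map(m_sat, m_sat)
  expect_true(all(self$density == 0))
  expect_equal(band_statistic(self)$mean, 0)
  expect_equal(band_statistic(self)$sd, 0)
  d_ab <- difference_map(m_sat, m_cis)
  d_ba <- difference_map(m_cis, m_sat)
  expect_equal(d_ab$density, -d_ba$density)
  expect_gt(band_statistic(d_ab)$mean, 0)
  bad <- voxel_density(t_cis, voxel_edge = 2)
  expect_error(difference_map(m_sat, bad), "voxel edges")
})

test_that("band statistic handles uniform maps and orders a saturation series", {
  pos <- as.matrix(expand.grid(x = 0:9 + 0.5, y = 0:9 + 0.5,
                               z = -5:4 + 0.5))
  map <- voxel_density(make_point_traj(pos, c(10, 10, 10)))
  bs <- band_statistic(map, z_min = 1, z_max = 4)
  expect_equal(bs$mean, 1)
  expect_equal(bs$sd, 0)
  expect_error(band_statistic(map, z_min = 3, z_max = 30), "grid")
  expect_error(band_statistic(map, z_min = 4, z_max = 3), "z_min")
  # fraction of kinked chains down, band density up -- monotonically
  series <- vapply(c(1, 0.5, 0), function(fr) {
    band_statistic(voxel_density(center_and_wrap(
      quick_bilayer(fr, n_frames = 2, noise = 0.2))))$mean
  }, numeric(1))
  expect_true(all(diff(series) > 0))
})
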