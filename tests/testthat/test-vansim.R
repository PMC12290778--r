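# Whole-volume vascular-network simulation.

test_that("an empty scene yields a flat tissue signal", {
  cl <- array(FALSE, c(10, 10, 10))
  v <- vessel_volume(cl, array(0, dim(cl)), array(0L, dim(cl)), 0.4)
  sc <- macro_van_scene(v, sim_params(), working_voxel = 0.4,
                        fmri_voxel = 4)
  expect_equal(max(abs(build_susceptibility_volume(sc, 0))), 0)
  run <- simulate_van_timeseries(sc, n_frames = 9)
  expect_equal(diff(range(run$signals)), 0)
  expect_equal(max(run$fbv), 0)
})

test_that("the susceptibility volume follows the oscillating drives", {
  p <- sim_params()
  v <- straight_vessel(c(20, 20, 20), voxel_size = 0.2, diameter = 1,
                       label = 2L)
  sc <- macro_van_scene(v, p, working_voxel = 0.2, fmri_voxel = 4)
  # venous oscillation is periodic: t = 0 and t = 10 s are identical
  expect_identical(build_susceptibility_volume(sc, 0),
                   build_susceptibility_volume(sc, 10))
  # susceptibility scales linearly with the oxygenation difference
  chi0 <- build_susceptibility_volume(sc, 0)
  p2 <- sim_params(y_v = 0.725)                 # halves (y_tissue - y_v)
  sc2 <- macro_van_scene(v, p2, working_voxel = 0.2, fmri_voxel = 4)
  expect_equal(build_susceptibility_volume(sc2, 0), chi0 / 2,
               tolerance = 1e-12)
  # arterial radius modulation: at the drive peak the masked volume
  # grows by roughly the requested fBV swing (+15% at sin = +1, up to
  # lattice quantization of the tube cross-section)
  va <- straight_vessel(c(32, 32, 32), voxel_size = 0.1, diameter = 1,
                        label = 1L)
  sca <- macro_van_scene(va, p, working_voxel = 0.1, fmri_voxel = 3.2)
  n_base <- sum(build_susceptibility_volume(sca, 0) != 0)
  n_peak <- sum(build_susceptibility_volume(sca, 2.5) != 0)
  expect_gt(n_peak, n_base)
  expect_equal(n_peak / n_base, 1.15, tolerance = 0.08)
})

test_that("simulated runs are bitwise deterministic", {
  v <- straight_vessel(c(20, 20, 20), voxel_size = 0.2, diameter = 1)
  sc1 <- macro_van_scene(v, sim_params(), working_voxel = 0.2,
                         fmri_voxel = 4)
  sc2 <- macro_van_scene(v, sim_params(), working_voxel = 0.2,
                         fmri_voxel = 4)
  r1 <- simulate_van_timeseries(sc1, n_frames = 7)
  r2 <- simulate_van_timeseries(sc2, n_frames = 7)
  expect_identical(r1$signals, r2$signals)
})

test_that("a single venous vessel matches the 3D cylinder model", {
  p <- sim_params()
  v <- straight_vessel(c(20, 20, 20), voxel_size = 0.2, diameter = 1)
  sc <- macro_van_scene(v, p, working_voxel = 0.2, fmri_voxel = 4)
  run <- simulate_van_timeseries(sc, n_frames = 10)
  ts3 <- simulate_voxel_timeseries("cyl3d", radius = 0.5, theta = 0,
                                   vessel = "vein", params = p,
                                   n_frames = 10, n = 20, ext = 3)
  expect_lt(max(abs(run$signals[1, 1, 1, ] / ts3$values - 1)), 0.03)
})

test_that("fluctuations die off far from the vasculature", {
  p <- sim_params()
  # vessel along y in the first fMRI voxel of a 7-voxel strip
  dims <- c(112, 16, 16)                        # 28 x 4 x 4 mm at 0.25 mm
  cl <- array(FALSE, dims)
  cl[8, , 8] <- TRUE                            # x = 1.875 mm, z = 1.875 mm
  di <- array(0, dims); di[cl] <- 1
  la <- array(0L, dims); la[cl] <- 2L
  v <- vessel_volume(cl, di, la, 0.25)
  sc <- macro_van_scene(v, p, working_voxel = 0.25, fmri_voxel = 4)
  run <- simulate_van_timeseries(sc, n_frames = 12)
  rs <- apply(run$signals, 1:3, function(x) rsfa(x)$rsfa)
  peak <- max(rs[run$fbv > 0])
  # voxels three or more fMRI voxels away: below 1% of the peak
  expect_lt(max(rs[4:7, 1, 1]), 0.01 * peak)
})

test_that("venous voxels share the common driver before noise", {
  p <- sim_params()
  cl <- array(FALSE, c(40, 40, 20))
  cl[10, 10, ] <- TRUE; cl[30, 28, ] <- TRUE    # two parallel veins
  di <- array(0, dim(cl)); di[cl] <- 1
  la <- array(0L, dim(cl)); la[cl] <- 2L
  v <- vessel_volume(cl, di, la, 0.2)
  sc <- macro_van_scene(v, p, working_voxel = 0.2, fmri_voxel = 4)
  run <- simulate_van_timeseries(sc, n_frames = 40)
  tab <- pairwise_fc_table(run, list(vein = run$class_frac$vein > 0))
  expect_true(all(abs(tab$r) > 0.99))
})

test_that("block aggregation follows complex-mean semantics", {
  # uniform phase: magnitude equals the weight mean
  cplx <- array(complex(modulus = 0.8, argument = 0.3), c(4, 4, 4))
  expect_equal(aggregate_to_fmri_grid(cplx, 4)[1, 1, 1], 0.8)
  # half the block at phase 0, half at pi: cancellation
  cplx2 <- array(complex(modulus = 1, argument = 0), c(4, 4, 4))
  cplx2[1:2, , ] <- complex(modulus = 1, argument = pi)
  expect_lt(aggregate_to_fmri_grid(cplx2, 4)[1, 1, 1], 1e-12)
  # block size 1 is the identity on magnitudes
  set.seed(3)
  z <- array(complex(real = rnorm(8), imaginary = rnorm(8)), c(2, 2, 2))
  expect_equal(aggregate_to_fmri_grid(z, 1), Mod(z))
  expect_error(aggregate_to_fmri_grid(cplx, 3), "divisible")
})

test_that("the memory guard refuses oversized scenes", {
  v <- straight_vessel(c(20, 20, 20), voxel_size = 0.2, diameter = 1)
  sc <- macro_van_scene(v, sim_params(), working_voxel = 0.2,
                        fmri_voxel = 4, mem_cap_gb = 1e-4)
  expect_error(simulate_van_timeseries(sc, n_frames = 2), "GiB cap")
})
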