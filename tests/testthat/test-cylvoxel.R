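# Single-voxel 2D/3D cylinder simulators and complex-mean signal
# formation.

test_that("the 2D voxel realizes the requested geometry", {
  p <- sim_params()
  v <- build_2d_voxel(0.05, pi / 2, 0.6, p, n = 400)
  # a = L * sqrt(fbv / pi)
  expect_equal(v$radius_a, 0.504627, tolerance = 1e-5)
  expect_equal(v$fbv_realized, 0.05, tolerance = 0.01)
  # analytic field at exterior sub-voxels equals the closed form exactly
  g <- cylinder_geometry(v$radius_a, pi / 2)
  xs <- centred_coords(400, 4 / 400)
  i <- 330; j <- 200                            # a point outside the disc
  r <- sqrt(xs[i]^2 + xs[j]^2)
  phi <- atan2(xs[j], xs[i])
  expect_equal(v$field[i, j],
               cylinder_field_offset(r, phi, g, 0.6, p), tolerance = 1e-12)
  # tiny fbv: the intravascular mask empties and the field vanishes
  v0 <- build_2d_voxel(1e-5, pi / 2, 0.6, p, n = 200)
  expect_equal(sum(v0$iv_mask), 0)
  expect_lt(max(abs(v0$field)), 5e-8)
  expect_error(build_2d_voxel(1.2, pi / 2, 0.6, p), "between 0 and 1")
})

test_that("clipped-disc construction preserves the requested fBV above pi/4", {
  p <- sim_params()
  for (fbv in c(0.8, 0.9)) {
    v <- build_2d_voxel(fbv, pi / 2, 0.6, p, n = 1000)
    expect_equal(v$fbv_realized, fbv, tolerance = 0.005)
  }
})

test_that("complex-mean signal formation has the right limits", {
  p <- sim_params()
  # zero field, single compartment: no dephasing
  z <- matrix(0, 10, 10)
  expect_equal(voxel_signal(z, z > 1, 0.6, p)$s_t2prime, 1)
  # uniform non-zero field: a global phase has unit magnitude
  expect_equal(voxel_signal(z + 3e-7, z > 1, 0.6, p)$s_t2prime, 1)
  # two equal compartments at phases 0 and pi cancel
  ph_pi <- pi / (p$gamma * p$b0 * p$te)
  f <- matrix(c(rep(0, 50), rep(ph_pi, 50)), 10, 10)
  expect_lt(voxel_signal(f, f > 1, 0.6, p)$s_t2prime, 1e-12)
  # s equals mean weight times s_t2prime for a single compartment
  sig <- voxel_signal(z + 3e-7, z > 1, 0.6, p)
  expect_equal(sig$s, sig$mean_weight)
})

test_that("r2prime inverts the dephasing definition", {
  expect_equal(r2prime(1, 0.027), 0)
  expect_equal(r2prime(exp(-0.27), 0.027), 10)
  s <- seq(0.9, 0.2, by = -0.1)
  expect_true(all(diff(r2prime(s, 0.027)) > 0))
  expect_error(r2prime(0, 0.027), "positive")
})

test_that("2D and 3D models agree at perpendicular orientation", {
  p <- sim_params()
  fbv <- 0.05
  a <- 4 * sqrt(fbv / pi)
  v3 <- build_3d_voxel(a, pi / 2, 0, 0.6, p, n = 48, ext = 3)
  s3 <- voxel_signal(v3$field, v3$iv_mask, 0.6, p)
  v2 <- build_2d_voxel(fbv, pi / 2, 0.6, p, n = 800)
  s2 <- voxel_signal(v2$field, v2$iv_mask, 0.6, p)
  expect_lt(abs(s3$s_t2prime / s2$s_t2prime - 1), 0.03)
})

test_that("3D realized fBV grows with obliquity as the path lengthens", {
  # axis-aligned: the analytic area fraction
  f0 <- realized_fbv_3d(0.5, 0, 0, n = 100)
  expect_equal(f0, pi * 0.25 / 16, tolerance = 0.02)
  # voxelized against exact line-clipping quadrature
  f45 <- realized_fbv_3d(0.5, pi / 4, 0, n = 100)
  expect_equal(f45, oblique_cylinder_fbv(pi / 4, radius = 0.5),
               tolerance = 0.03)
  # thin-vessel limit of the 45-degree ratio approaches sqrt(2)
  ratio <- oblique_cylinder_fbv(pi / 4) / oblique_cylinder_fbv(0)
  expect_equal(ratio, sqrt(2), tolerance = 0.01)
  # azimuth obliquity is equivalent by symmetry
  expect_equal(oblique_cylinder_fbv(pi / 2, pi / 4),
               oblique_cylinder_fbv(pi / 4), tolerance = 1e-6)
  expect_error(build_3d_voxel(1e-4, 0, 0, 0.6, sim_params(), n = 20),
               "sub-voxel")
})

test_that("voxel time series are deterministic and periodic", {
  p <- sim_params()
  # zero-amplitude oscillation: constant series, zero RSFA
  ts0 <- simulate_voxel_timeseries(
    "cyl2d", fbv = 0.2, vessel = "vein", params = p, n_frames = 12,
    n = 200, osc = oscillation_spec("venous_y", 0.6,
                                    peak_to_peak_fraction = 0))
  expect_equal(diff(range(ts0$values)), 0)
  expect_equal(rsfa(ts0)$rsfa, 0)
  # the 0.1 Hz drive at TR 2.2 s repeats after exactly 50 frames
  ts <- simulate_voxel_timeseries("cyl2d", fbv = 0.2, vessel = "vein",
                                  params = p, n_frames = 52, n = 200)
  expect_equal(ts$values[1], ts$values[51], tolerance = 1e-12)
  expect_equal(ts$values[2], ts$values[52], tolerance = 1e-12)
  expect_gt(min(ts$values), 0)
  # dominant spectral component sits at the drive frequency
  sp <- Mod(fft(ts$values[1:50] - mean(ts$values[1:50])))[2:25]
  freqs <- (1:24) / (50 * p$tr)
  expect_equal(freqs[which.max(sp)], 0.1, tolerance = 0.01)
})

test_that("arterial voxels oscillate fBV and venous voxels oxygenation", {
  p <- sim_params()
  tsa <- simulate_voxel_timeseries("cyl2d", fbv = 0.3, vessel = "artery",
                                   params = p, n_frames = 10, n = 200)
  expect_equal(tsa$meta$osc$target, "arterial_fbv")
  expect_equal(tsa$meta$osc$baseline, 0.3)
  tsv <- simulate_voxel_timeseries("cyl2d", fbv = 0.3, vessel = "vein",
                                   params = p, n_frames = 10, n = 200)
  expect_equal(tsv$meta$osc$target, "venous_y")
  expect_equal(tsv$meta$osc$baseline, p$y_v)
  # 3D venous series responds to the drive
  ts3 <- simulate_voxel_timeseries("cyl3d", radius = 0.5, vessel = "vein",
                                   theta = 0, params = p, n_frames = 10,
                                   n = 20)
  expect_gt(diff(range(ts3$values)), 0)
})
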