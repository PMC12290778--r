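# Centreline merging, local orientation, tube voxelization, fBV maps and
# perivascular shells.

test_that("merging keeps the union and the largest diameter estimate", {
  a <- straight_vessel(c(8, 8, 8), axis = 3, voxel_size = 0.8,
                       diameter = 1.2, label = 1L)
  b <- straight_vessel(c(8, 8, 8), axis = 3, voxel_size = 0.8,
                       diameter = 2.0, label = 1L)
  cx <- straight_vessel(c(8, 8, 8), axis = 1, voxel_size = 0.8,
                        diameter = 1.0, label = 2L, at = c(2, 2))
  # single source: identity
  m1 <- merge_centerline_sources(list(a))
  expect_equal(m1$diameter, a$diameter)
  # overlapping: max diameter wins
  m <- merge_centerline_sources(list(a, b))
  expect_equal(unique(m$diameter[m$centreline]), 2.0)
  # disjoint: exact union with preserved diameters
  m2 <- merge_centerline_sources(list(a, cx))
  expect_equal(sum(m2$centreline), sum(a$centreline) + sum(cx$centreline))
  expect_equal(m2$diameter[4, 2, 2], 1.0)
  expect_equal(m2$diameter[4, 4, 4], 1.2)
  # commutative and idempotent
  m3 <- merge_centerline_sources(list(cx, a))
  expect_equal(m2$diameter, m3$diameter)
  expect_equal(merge_centerline_sources(list(a, a))$diameter, a$diameter)
  # grid mismatch
  expect_error(merge_centerline_sources(
    list(a, straight_vessel(c(6, 6, 6), voxel_size = 0.8))), "grid")
})

test_that("conflicting artery/vein labels resolve to vein with a warning", {
  a <- straight_vessel(c(8, 8, 8), diameter = 1, label = 1L,
                       voxel_size = 0.8)
  v <- straight_vessel(c(8, 8, 8), diameter = 0.9, label = 2L,
                       voxel_size = 0.8)
  expect_warning(m <- merge_centerline_sources(list(a, v)), "vein")
  expect_true(all(m$label[m$centreline] == 2L))
  expect_equal(unique(m$diameter[m$centreline]), 1)
})

test_that("local orientation recovers straight-vessel geometry", {
  vz <- straight_vessel(c(9, 9, 9), axis = 3, voxel_size = 0.8,
                        at = c(5, 5))
  oz <- local_orientation(vz)
  expect_equal(oz$zenith[5, 5, 5], 0)
  vx <- straight_vessel(c(9, 9, 9), axis = 1, voxel_size = 0.8,
                        at = c(5, 5))
  ox <- local_orientation(vx)
  expect_equal(ox$zenith[5, 5, 5], pi / 2)
  expect_equal(ox$azimuth[5, 5, 5], 0)
  # x = z diagonal: zenith pi/4
  cl <- array(FALSE, c(9, 9, 9))
  for (i in 1:9) cl[i, 5, i] <- TRUE
  di <- array(0, dim(cl)); di[cl] <- 1
  la <- array(0L, dim(cl)); la[cl] <- 2L
  vd <- vessel_volume(cl, di, la, 0.8)
  od <- local_orientation(vd)
  expect_equal(od$zenith[5, 5, 5], pi / 4, tolerance = 1e-10)
  # orientation is defined on every centreline voxel of a connected line
  expect_true(all(!is.na(oz$zenith[vz$centreline])))
  expect_true(all(is.na(oz$zenith[!vz$centreline])))
})

test_that("direction cosines rotate the zenith into the scanner frame", {
  # grid x axis maps to scanner z: a grid-x vessel is parallel to B0
  dc <- matrix(c(0, 0, 1,
                 0, 1, 0,
                 1, 0, 0), 3, 3, byrow = TRUE)
  v <- straight_vessel(c(9, 9, 9), axis = 1, voxel_size = 0.8,
                       at = c(5, 5))
  v$direction_cosines <- dc
  o <- local_orientation(v)
  expect_equal(o$zenith[5, 5, 5], 0)
})

test_that("isolated centreline voxels get undefined orientation", {
  cl <- array(FALSE, c(9, 9, 9)); cl[5, 5, 5] <- TRUE
  di <- array(0, dim(cl)); di[cl] <- 1
  la <- array(0L, dim(cl)); la[cl] <- 2L
  o <- local_orientation(vessel_volume(cl, di, la, 0.8))
  expect_true(is.na(o$zenith[5, 5, 5]))
})

test_that("voxelization reproduces the quantized tube footprint", {
  # 0.8 mm vessel centred on a 0.2 mm grid cell: 13-voxel cross-section
  v <- straight_vessel(c(32, 32, 32), axis = 3, voxel_size = 0.2,
                       diameter = 0.8)
  m <- voxelize_vessels(v, 0.2)
  expect_equal(sum(m[, , 16]), 13)
  # radius_scale 0: only the centreline path
  m0 <- voxelize_vessels(v, 0.2, radius_scale = 0)
  expect_equal(sum(m0[, , 16]), 1)
  expect_equal(which(m0[, , 16]), which(v$centreline[, , 16]))
  # empty centreline: empty mask
  cl <- array(FALSE, c(8, 8, 8))
  ve <- vessel_volume(cl, array(0, dim(cl)), array(0L, dim(cl)), 0.8)
  expect_equal(sum(voxelize_vessels(ve, 0.2)), 0)
})

test_that("voxelized fBV converges towards the analytic cross-section", {
  analytic <- pi * 0.4^2                       # mm^2 cross-section
  # 0.2 mm grid: 13 voxels, +3.5% (inclusive-disc lattice quantization)
  v2 <- straight_vessel(c(32, 32, 32), axis = 3, voxel_size = 0.2)
  a2 <- sum(voxelize_vessels(v2, 0.2)[, , 16]) * 0.2^2
  expect_lt(abs(a2 / analytic - 1), 0.05)
  # 0.1 mm grid: finer quantization, tighter error
  v1 <- straight_vessel(c(64, 64, 64), axis = 3, voxel_size = 0.1)
  a1 <- sum(voxelize_vessels(v1, 0.1)[, , 32]) * 0.1^2
  expect_lt(abs(a1 / analytic - 1), 0.03)
  expect_lt(abs(a1 / analytic - 1), abs(a2 / analytic - 1))
})

test_that("fBV maps count occupied sub-voxels per fMRI voxel", {
  m <- array(FALSE, c(8, 8, 8))
  attr(m, "voxel_size") <- 1
  m[1:4, 1:4, 1:4] <- TRUE                     # one fully occupied block
  fb <- fbv_map(m, fmri_voxel = 4)
  expect_equal(dim(fb$fbv), c(2, 2, 2))
  expect_equal(fb$fbv[1, 1, 1], 1)
  expect_equal(fb$fbv[2, 2, 2], 0)
  # partial occupancy: 400 of 20^3 sub-voxels
  m2 <- array(FALSE, c(20, 20, 20))
  attr(m2, "voxel_size") <- 0.2
  m2[seq_len(400)] <- TRUE
  expect_equal(fbv_map(m2, fmri_voxel = 4)$fbv[1, 1, 1], 0.05)
  expect_error(fbv_map(m2, fmri_voxel = 3), "divisible")
  expect_error(fbv_map(m2, fmri_voxel = 0.5), "integer multiple")
})

test_that("dominant orientation comes from the largest vessel inside", {
  pts <- data.frame(x = c(1, 2), y = c(1, 1), z = c(1, 1),
                    diameter = c(0.9, 2.5),
                    zenith = c(0.3, 1.2), azimuth = c(0, 2))
  m <- array(TRUE, c(20, 20, 20))
  attr(m, "voxel_size") <- 0.2
  fb <- fbv_map(m, fmri_voxel = 4, points = pts)
  expect_equal(fb$zenith[1, 1, 1], 1.2)
  expect_equal(fb$azimuth[1, 1, 1], 2)
})

test_that("perivascular shells are disjoint dilation differences", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  sh <- perivascular_shells(m, n_shells = 3)
  expect_equal(sum(sh[[1]]), 26)               # 3^3 - 1 neighbours
  expect_equal(sum(sh[[2]]), 5^3 - 3^3)
  # pairwise disjoint and disjoint from the mask
  expect_false(any(sh[[1]] & m))
  expect_false(any(sh[[1]] & sh[[2]]))
  expect_false(any(sh[[2]] & sh[[3]]))
  # telescoping: mask with shells 1..k equals the k-fold dilation
  dil <- m
  for (k in 1:3) dil <- vasobold:::dilate3d(dil, 26)
  expect_equal(m | sh[[1]] | sh[[2]] | sh[[3]], dil)
  # 6-connected variant
  sh6 <- perivascular_shells(m, n_shells = 1, connectivity = 6)
  expect_equal(sum(sh6[[1]]), 6)
})
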