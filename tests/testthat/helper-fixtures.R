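# Shared fixtures, built in code at test time.

# straight vessel along one grid axis through the volume centre
straight_vessel <- function(dims = c(16, 16, 16), axis = 3,
                            voxel_size = 0.2, diameter = 0.8,
                            label = 2L, at = NULL) {
  cl <- array(FALSE, dims)
  if (is.null(at)) at <- floor(dims[-axis] / 2)
  ii <- matrix(0L, dims[axis], 3)
  ii[, axis] <- seq_len(dims[axis])
  ii[, setdiff(1:3, axis)] <- rep(at, each = dims[axis])
  cl[ii] <- TRUE
  di <- array(0, dims); di[cl] <- diameter
  la <- array(0L, dims); la[cl] <- label
  vessel_volume(cl, di, la, voxel_size)
}

# vessel along an arbitrary direction, traced at half-voxel steps
traced_vessel <- function(dims = c(16, 16, 16), dir = c(0, 0, 1),
                          voxel_size = 0.2, diameter = 0.8, label = 2L) {
  dir <- dir / sqrt(sum(dir^2))
  fov <- dims * voxel_size
  ctr <- fov / 2
  cl <- array(FALSE, dims)
  for (s in seq(-2 * max(fov), 2 * max(fov), by = voxel_size / 2)) {
    p <- ctr + s * dir
    if (all(p > 0 & p < fov)) {
      i <- pmin(pmax(ceiling(p / voxel_size), 1), dims)
      cl[i[1], i[2], i[3]] <- TRUE
    }
  }
  di <- array(0, dims); di[cl] <- diameter
  la <- array(0L, dims); la[cl] <- label
  vessel_volume(cl, di, la, voxel_size)
}

# partial-volume (supersampled) sphere susceptibility grid; binary
# voxelization at this resolution would carry a percent-level volume
# error that is a fixture artifact, not a field-model error
sphere_chi <- function(n = 48, voxel = 0.5, radius = 2, chi0 = 1e-6,
                       ss = 4) {
  ic <- n / 2 + 1
  xs <- (seq_len(n) - ic) * voxel
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * voxel
  frac <- array(0, c(n, n, n))
  for (dx in off) for (dy in off) for (dz in off) {
    X <- array(xs + dx, c(n, n, n))
    Y <- array(rep(xs + dy, each = n), c(n, n, n))
    Z <- array(rep(xs + dz, each = n * n), c(n, n, n))
    frac <- frac + (X^2 + Y^2 + Z^2 <= radius^2)
  }
  list(chi = chi0 * frac / ss^3, centre = ic, voxel = voxel,
       radius = radius, chi0 = chi0)
}

# grid coordinates (voxel centres, mm, origin at volume centre) of an
# n^3 grid with voxel edge sub
centred_coords <- function(n, sub) (seq_len(n) - (n + 1) / 2) * sub
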