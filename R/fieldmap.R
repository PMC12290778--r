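# Susceptibility-to-field forward models: numerical (k-space dipole
# kernel) and analytic (infinite cylinder). The main field is fixed to the
# grid +z axis; oblique vessels are handled by rotating the geometry, not
# the kernel.

# FFT sample frequencies in cycles/mm for n samples at spacing d mm.
fft_freq <- function(n, d) {
  c(0:(ceiling(n / 2) - 1), -floor(n / 2):-1) / (n * d)
}

#' k-space dipole kernel
#'
#' The unit-response of a magnetic point dipole in k-space,
#' `1/3 - kz^2 / k^2`, sampled on the discrete frequency grid implied by
#' the array shape and voxel size. Multiplying the Fourier transform of a
#' susceptibility distribution by this kernel and transforming back yields
#' the relative field offset `dBz / B0`. The undefined `k = 0` value is
#' set to 0, i.e. the mean field offset is zero.
#'
#' @param dims Integer vector of grid dimensions (all >= 2).
#' @param voxel_size Voxel edge length(s) in mm; scalar or length 3.
#' @return A numeric array of shape `dims`.
#' @export
dipole_kernel <- function(dims, voxel_size) {
  stopifnot(length(dims) == 3, all(dims >= 2))
  vs <- rep_len(voxel_size, 3)
  kx2 <- fft_freq(dims[1], vs[1])^2
  ky2 <- fft_freq(dims[2], vs[2])^2
  kz2 <- fft_freq(dims[3], vs[3])^2
  k2 <- outer(outer(kx2, ky2, `+`), kz2, `+`)
  kz2a <- outer(outer(rep(0, dims[1]), rep(0, dims[2]), `+`), kz2, `+`)
  ker <- 1 / 3 - kz2a / k2
  ker[k2 == 0] <- 0
  ker
}

# kernel cache: building a 192^3 kernel costs more than the FFT it feeds
.kernel_cache <- new.env(parent = emptyenv())

cached_kernel <- function(dims, vs) {
  key <- paste(c(dims, signif(vs, 10)), collapse = "_")
  k <- .kernel_cache[[key]]
  if (is.null(k)) {
    if (length(ls(.kernel_cache)) > 4) rm(list = ls(.kernel_cache),
                                          envir = .kernel_cache)
    k <- dipole_kernel(dims, vs)
    .kernel_cache[[key]] <- k
  }
  k
}

# workhorse: susceptibility array -> relative field-offset array
field_offset_array <- function(chi, voxel_size, pad = dim(chi)) {
  d0 <- dim(chi)
  pad <- rep_len(as.integer(pad), 3)
  vs <- rep_len(voxel_size, 3)
  if (any(!is.finite(chi))) stop("susceptibility grid contains non-finite values")
  if (all(pad == 0L)) {
    ker <- cached_kernel(d0, vs)
    return(Re(stats::fft(ker * stats::fft(chi), inverse = TRUE)) / prod(d0))
  }
  dp <- d0 + 2L * pad
  chip <- array(0, dp)
  chip[pad[1] + seq_len(d0[1]), pad[2] + seq_len(d0[2]),
       pad[3] + seq_len(d0[3])] <- chi
  ker <- cached_kernel(dp, vs)
  f <- Re(stats::fft(ker * stats::fft(chip), inverse = TRUE)) / prod(dp)
  f[pad[1] + seq_len(d0[1]), pad[2] + seq_len(d0[2]),
    pad[3] + seq_len(d0[3])]
}

#' Field offset from a susceptibility distribution
#'
#' Computes the relative main-field offset `dBz / B0` induced by a
#' susceptibility distribution via cyclic convolution with the k-space
#' dipole kernel, zero-padding the input to suppress wraparound. The
#' default padding of one full field of view per side makes the circular
#' convolution effectively aperiodic; `pad = 0` performs a purely cyclic
#' convolution (useful for periodic constructions such as an infinite
#' cylinder threaded through the grid).
#'
#' @param chi 3D susceptibility array (dimensionless SI).
#' @param voxel_size Voxel size in mm (scalar or length 3).
#' @param pad Zero-padding in voxels per side (scalar or length 3);
#'   `NULL` (default) pads by the full grid extent.
#' @return A `field_volume` object: list with `data` (the `dBz/B0` array),
#'   `voxel_size` and `b0_axis` (fixed to `c(0, 0, 1)`).
#' @examples
#' chi <- array(0, c(8, 8, 8)); chi[4:5, 4:5, 4:5] <- 1e-6
#' f <- field_offset_volume(chi, voxel_size = 1)
#' range(f$data)
#' @export
field_offset_volume <- function(chi, voxel_size, pad = NULL) {
  if (is.null(pad)) pad <- dim(chi)
  data <- field_offset_array(chi, voxel_size, pad)
  structure(list(data = data, voxel_size = rep_len(voxel_size, 3),
                 b0_axis = c(0, 0, 1)),
            class = "field_volume")
}

#' @export
print.field_volume <- function(x, ...) {
  cat("field volume:", paste(dim(x$data), collapse = " x "),
      "voxels at", paste(signif(x$voxel_size, 3), collapse = " x "),
      "mm; dBz/B0 range",
      paste(signif(range(x$data), 3), collapse = " .. "), "\n")
  invisible(x)
}

#' Cylinder geometry
#'
#' @param radius_a Cylinder radius in mm (> 0).
#' @param zenith Angle between the cylinder axis and the main field, rad,
#'   in `[0, pi]`.
#' @param azimuth In-plane axis direction, rad (used by voxelized 3D
#'   constructions only; the analytic 2D field does not depend on it).
#' @return An object of class `cylinder_geometry`.
#' @export
cylinder_geometry <- function(radius_a, zenith, azimuth = 0) {
  stopifnot(radius_a > 0, zenith >= 0, zenith <= pi)
  structure(list(radius_a = radius_a, zenith = zenith, azimuth = azimuth),
            class = "cylinder_geometry")
}

#' Analytic field offset of an infinite cylinder
#'
#' Closed-form relative field offset `dBz / B0` of an infinite cylinder of
#' blood at oxygenation `y` embedded in tissue, in the plane perpendicular
#' to the cylinder axis. Outside the cylinder (`r >= a`):
#' `2*pi * (delta_chi/(4*pi)) * Hct * (Y_tissue - Y) * sin^2(theta) *
#' (a/r)^2 * cos(2*phi)`; inside (`r < a`):
#' `2*pi * (delta_chi/(4*pi)) * Hct * (Y_tissue - Y) *
#' (3*cos^2(theta) - 1) / 3`. The assembly is piecewise: the interior
#' value is constant and the exterior dipolar pattern attaches at
#' `r = a`, where its angular mean is zero.
#'
#' @param r Distance(s) from the cylinder axis in mm, >= 0.
#' @param phi Angle(s) in rad between the query vector and the projection
#'   of the main field onto the perpendicular plane.
#' @param geom A [cylinder_geometry()].
#' @param y Blood oxygenation fraction.
#' @param params A [sim_params()] object.
#' @return Relative field offset(s), dimensionless; recycled over
#'   `r`/`phi`.
#' @examples
#' g <- cylinder_geometry(radius_a = 0.5, zenith = pi / 2)
#' cylinder_field_offset(0.5, 0, g, y = 0.6)  # venous surface offset
#' @export
cylinder_field_offset <- function(r, phi, geom, y, params = sim_params()) {
  stopifnot(inherits(geom, "cylinder_geometry"), all(r >= 0))
  scale <- 2 * pi * (params$delta_chi / (4 * pi)) * params$hct *
    (params$y_tissue - y)
  a <- geom$radius_a
  out <- scale * sin(geom$zenith)^2 * (a / pmax(r, .Machine$double.eps))^2 *
    cos(2 * phi)
  inside <- r < a
  out[inside] <- scale * (3 * cos(geom$zenith)^2 - 1) / 3
  out
}
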