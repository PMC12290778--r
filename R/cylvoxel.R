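# Single-voxel simulators: an analytic 2D infinite-cylinder voxel and a
# voxelized 3D infinite-cylinder voxel, with complex-mean signal
# formation in the static dephasing regime and sinusoidally driven time
# series.

# Disc radius (mm) realizing a blood-volume fraction inside a square
# voxel of edge L. For fbv <= pi/4 the disc fits the voxel and
# a = L * sqrt(fbv / pi); beyond that the disc is clipped by the voxel
# edges and the radius is solved so the clipped area still equals
# fbv * L^2 (the whole voxel is blood at fbv = 1, when a = L / sqrt(2)).
disc_radius_for_fbv <- function(fbv, L) {
  if (fbv <= 0 || fbv >= 1) stop("fbv must lie strictly between 0 and 1")
  a0 <- L * sqrt(fbv / pi)
  if (a0 <= L / 2) return(a0)
  h <- L / 2
  clipped_area <- function(a) {
    pi * a^2 - 4 * (a^2 * acos(pmin(h / a, 1)) - h * sqrt(pmax(a^2 - h^2, 0)))
  }
  stats::uniroot(function(a) clipped_area(a) - fbv * L^2,
                 lower = h, upper = L / sqrt(2),
                 tol = 1e-12)$root
}

#' Analytic 2D cylinder voxel
#'
#' Builds the cross-section of a single fMRI voxel containing one
#' infinite cylinder at the voxel centre, with the relative field offset
#' evaluated analytically at every sub-voxel: the dipolar exterior
#' pattern outside the vessel and the constant interior offset inside.
#' The in-plane angle phi of each sub-voxel is measured from the
#' projection of the main field onto the cross-section plane (the grid x
#' axis).
#'
#' @param fbv Blood-volume fraction in `(0, 1)`; the disc radius is
#'   `L * sqrt(fbv / pi)` (clipped-disc construction above `fbv = pi/4`).
#' @param theta Zenith angle of the cylinder axis to the main field, rad.
#' @param y Blood oxygenation fraction.
#' @param params A [sim_params()] object.
#' @param n Sub-voxel side count (default 4000, i.e. 1-micron sub-voxels
#'   in a 4 mm voxel; results change by less than 0.5% down to 1000).
#' @param voxel_mm fMRI voxel edge in mm (default 4).
#' @return An object of class `subvoxel_grid_2d`: `field` (n x n relative
#'   offsets), `iv_mask`, `subvoxel` (mm), `radius_a`, `fbv`,
#'   `fbv_realized`, `theta`, `y`.
#' @examples
#' v <- build_2d_voxel(fbv = 0.05, theta = pi / 2, y = 0.6, n = 400)
#' v$radius_a  # about 0.5 mm
#' @export
build_2d_voxel <- function(fbv, theta, y, params = sim_params(),
                           n = 4000, voxel_mm = 4) {
  if (fbv <= 0 || fbv >= 1)
    stop("fbv must lie strictly between 0 and 1")
  stopifnot(n >= 10)
  L <- voxel_mm
  a <- disc_radius_for_fbv(fbv, L)
  xs <- ((seq_len(n)) - 0.5) / n * L - L / 2
  x <- matrix(xs, n, n)
  zc <- matrix(xs, n, n, byrow = TRUE)
  r2 <- x^2 + zc^2
  scale <- 2 * pi * (params$delta_chi / (4 * pi)) * params$hct *
    (params$y_tissue - y)
  cos2phi <- (x^2 - zc^2) / pmax(r2, .Machine$double.eps)
  iv <- r2 <= a^2
  field <- scale * sin(theta)^2 * (a^2 / pmax(r2, .Machine$double.eps)) *
    cos2phi
  field[iv] <- scale * (3 * cos(theta)^2 - 1) / 3
  structure(list(field = field, iv_mask = iv, subvoxel = L / n, n = n,
                 radius_a = a, fbv = fbv, fbv_realized = mean(iv),
                 theta = theta, y = y),
            class = "subvoxel_grid_2d")
}

# Voxelized oriented cylinder mask on an (ext*n)^3 grid; the axis passes
# through the grid centre with direction (sin t cos p, sin t sin p, cos t).
cylinder_mask_3d <- function(radius, theta, azimuth, n, voxel_mm, ext = 1) {
  m <- ext * n
  sub <- voxel_mm / n
  xs <- (seq_len(m) - (m + 1) / 2) * sub
  u <- c(sin(theta) * cos(azimuth), sin(theta) * sin(azimuth), cos(theta))
  X <- array(xs, c(m, m, m))
  Y <- array(rep(xs, each = m), c(m, m, m))
  Z <- array(rep(xs, each = m * m), c(m, m, m))
  dot <- X * u[1] + Y * u[2] + Z * u[3]
  d2 <- X^2 + Y^2 + Z^2 - dot^2
  d2 <= radius^2
}

#' Voxelized 3D cylinder voxel
#'
#' Builds one fMRI voxel crossed by an oriented infinite cylinder,
#' voxelized at `voxel_mm / n` resolution, with the field computed
#' numerically through the k-space dipole kernel. The infinite cylinder
#' is emulated by drawing it across an extended grid (`ext` times the
#' voxel per side) and convolving cyclically, so the periodic images are
#' far from the voxel of interest; the central voxel is then cropped.
#' Unlike the 2D model, the realized blood-volume fraction grows with
#' obliquity (the oblique cylinder runs a longer path through the voxel).
#'
#' @param radius Cylinder radius in mm (at least one sub-voxel).
#' @param theta,azimuth Axis orientation, rad.
#' @param y Blood oxygenation fraction.
#' @param params A [sim_params()] object.
#' @param n Sub-voxel side count of the voxel (default 100, i.e. 40-micron
#'   sub-voxels in a 4 mm voxel).
#' @param voxel_mm fMRI voxel edge in mm (default 4).
#' @param ext Extension factor of the cyclic grid (default 3).
#' @return An object of class `subvoxel_grid_3d`: `field` (n^3 relative
#'   offsets), `iv_mask`, `subvoxel`, `radius`, `fbv_realized`, `theta`,
#'   `azimuth`, `y`.
#' @export
build_3d_voxel <- function(radius, theta, azimuth = 0, y,
                           params = sim_params(), n = 100, voxel_mm = 4,
                           ext = 3) {
  sub <- voxel_mm / n
  if (radius < sub)
    stop("radius must be at least one sub-voxel (", signif(sub, 3), " mm)")
  mask_ext <- cylinder_mask_3d(radius, theta, azimuth, n, voxel_mm, ext)
  chi <- array(0, dim(mask_ext))
  chi[mask_ext] <- blood_tissue_susceptibility(y, params)
  f <- field_offset_array(chi, sub, pad = 0)
  ctr <- (ext - 1) * n / 2 + seq_len(n)
  field <- f[ctr, ctr, ctr]
  iv <- mask_ext[ctr, ctr, ctr]
  if (!any(iv)) stop("cylinder misses the voxel entirely")
  structure(list(field = field, iv_mask = iv, subvoxel = sub,
                 radius = radius, fbv_realized = mean(iv),
                 theta = theta, azimuth = azimuth, y = y),
            class = "subvoxel_grid_3d")
}

#' Complex-mean dephasing signal of a sub-voxel grid
#'
#' Forms the voxel signal as the magnitude of the weighted complex mean
#' of the sub-voxel magnetization phases accumulated at the echo time:
#' each sub-voxel contributes `w * exp(i * gamma * B0 * (dBz/B0) * TE)`,
#' where the weight `w` is the steady-state amplitude of its compartment
#' (blood T1/T2 at the given oxygenation inside the vessel, tissue T1/T2
#' outside). `s_t2prime` is the magnitude of that mean normalized by the
#' mean weight, so it equals 1 for any uniform-phase voxel and decays
#' towards 0 with intravoxel dephasing; `s` is the unnormalized weighted
#' amplitude.
#'
#' @param field Array of relative field offsets (`dBz / B0`).
#' @param iv_mask Logical array of the same shape marking blood
#'   sub-voxels.
#' @param y_blood Blood oxygenation fraction (sets the blood weight).
#' @param params A [sim_params()] object.
#' @return A list with `s_t2prime`, `s` and `mean_weight`.
#' @export
voxel_signal <- function(field, iv_mask, y_blood, params = sim_params()) {
  if (any(!is.finite(field))) stop("field contains non-finite values")
  wb <- compartment_weight("blood", y_blood, params)
  wt <- compartment_weight("tissue", NA_real_, params)
  w <- ifelse(iv_mask, wb, wt)
  ph <- params$gamma * params$b0 * params$te * field
  m <- mean(w * exp(1i * ph))
  mw <- mean(w)
  list(s_t2prime = Mod(m) / mw, s = Mod(m), mean_weight = mw)
}

#' Reversible dephasing rate R2'
#'
#' @param s_t2prime Dephasing attenuation in `(0, 1]`.
#' @param te Echo time in seconds.
#' @return `-log(s_t2prime) / te`, in 1/s (non-negative).
#' @export
r2prime <- function(s_t2prime, te) {
  if (any(s_t2prime <= 0)) stop("s_t2prime must be positive")
  -log(s_t2prime) / te
}

#' Simulate a single-voxel BOLD time series
#'
#' Drives one cylinder voxel with the sinusoidal resting-state input:
#' arterial voxels oscillate their blood-volume fraction (realized as a
#' continuous rescaling of the cylinder radius, `a` proportional to
#' `sqrt(fbv)`), venous voxels oscillate their blood oxygenation. Each
#' frame's signal is the complex-mean dephasing signal scaled by the
#' steady-state amplitude. The output is deterministic given the
#' oscillation spec.
#'
#' @param model `"cyl2d"` or `"cyl3d"`.
#' @param fbv Baseline blood-volume fraction (2D model) or the fraction
#'   implied by `radius` (3D model; pass `radius` instead).
#' @param theta,azimuth Vessel orientation, rad.
#' @param vessel `"artery"` or `"vein"`.
#' @param params A [sim_params()] object.
#' @param osc An [oscillation_spec()]; defaults to a 0.1 Hz, 10%
#'   peak-to-peak oscillation of the class-appropriate quantity.
#' @param n_frames Number of frames (default `params$n_frames`).
#' @param n Sub-voxel side count (defaults: 1000 for `"cyl2d"`, 60 for
#'   `"cyl3d"`; per-frame rebuilds make the full-resolution defaults of
#'   the static builders impractical for long runs).
#' @param radius Cylinder radius in mm for the 3D model.
#' @param voxel_mm fMRI voxel edge in mm.
#' @param ext Extension factor for the 3D model grid.
#' @return An object of class `voxel_timeseries`: `values` (length
#'   `n_frames`, positive), `tr`, and a `meta` list.
#' @export
simulate_voxel_timeseries <- function(model = c("cyl2d", "cyl3d"),
                                      fbv = NULL, theta = pi / 2,
                                      azimuth = 0,
                                      vessel = c("artery", "vein"),
                                      params = sim_params(), osc = NULL,
                                      n_frames = params$n_frames,
                                      n = NULL, radius = NULL,
                                      voxel_mm = 4, ext = 3) {
  model <- match.arg(model)
  vessel <- match.arg(vessel)
  if (is.null(n)) n <- if (model == "cyl2d") 1000 else 60
  y0 <- if (vessel == "artery") params$y_a else params$y_v
  if (model == "cyl3d") {
    if (is.null(radius)) {
      if (is.null(fbv)) stop("give fbv or radius")
      radius <- disc_radius_for_fbv(fbv, voxel_mm)
    }
    if (is.null(fbv)) fbv <- pi * radius^2 / voxel_mm^2
  }
  if (is.null(fbv)) stop("fbv is required")
  if (is.null(osc)) {
    osc <- if (vessel == "artery")
      oscillation_spec("arterial_fbv", baseline = fbv)
    else
      oscillation_spec("venous_y", baseline = y0)
  }
  tt <- (seq_len(n_frames) - 1) * params$tr
  drive <- oscillate(osc, tt)
  vals <- numeric(n_frames)

  if (model == "cyl2d") {
    L <- voxel_mm
    xs <- ((seq_len(n)) - 0.5) / n * L - L / 2
    x <- matrix(xs, n, n)
    zc <- matrix(xs, n, n, byrow = TRUE)
    r2 <- pmax(x^2 + zc^2, .Machine$double.eps)
    cos2phi_r2 <- (x^2 - zc^2) / r2^2
    for (k in seq_len(n_frames)) {
      if (vessel == "artery") {
        a <- disc_radius_for_fbv(drive[k], L)
        y <- y0
      } else {
        a <- disc_radius_for_fbv(fbv, L)
        y <- drive[k]
      }
      scale <- 2 * pi * (params$delta_chi / (4 * pi)) * params$hct *
        (params$y_tissue - y)
      iv <- r2 <= a^2
      field <- scale * sin(theta)^2 * a^2 * cos2phi_r2
      field[iv] <- scale * (3 * cos(theta)^2 - 1) / 3
      sig <- voxel_signal(field, iv, y, params)
      vals[k] <- sig$s
    }
  } else {
    if (vessel == "vein") {
      # field scales linearly in (y_tissue - y): one build serves all frames
      base <- build_3d_voxel(radius, theta, azimuth, y0, params,
                             n = n, voxel_mm = voxel_mm, ext = ext)
      unit_field <- base$field / (params$y_tissue - y0)
      for (k in seq_len(n_frames)) {
        y <- drive[k]
        sig <- voxel_signal(unit_field * (params$y_tissue - y),
                            base$iv_mask, y, params)
        vals[k] <- sig$s
      }
    } else {
      memo <- new.env(parent = emptyenv())
      r0 <- radius
      for (k in seq_len(n_frames)) {
        rs <- r0 * sqrt(drive[k] / fbv)
        key <- sprintf("%.12g", rs)
        sig <- memo[[key]]
        if (is.null(sig)) {
          vox <- build_3d_voxel(rs, theta, azimuth, y0, params,
                                n = n, voxel_mm = voxel_mm, ext = ext)
          sig <- voxel_signal(vox$field, vox$iv_mask, y0, params)
          memo[[key]] <- sig
        }
        vals[k] <- sig$s
      }
    }
  }
  structure(list(values = vals, tr = params$tr,
                 meta = list(model = model, vessel = vessel, fbv = fbv,
                             theta = theta, azimuth = azimuth,
                             osc = osc, radius = radius)),
            class = "voxel_timeseries")
}

#' @export
print.voxel_timeseries <- function(x, ...) {
  cat(sprintf("voxel time series: %s %s, %d frames at TR %.3g s, mean %.4g\n",
              x$meta$model, x$meta$vessel, length(x$values), x$tr,
              mean(x$values)))
  invisible(x)
}

#' @export
plot.voxel_timeseries <- function(x, ...) {
  tt <- (seq_along(x$values) - 1) * x$tr
  graphics::plot(tt, x$values, type = "l", xlab = "time (s)",
                 ylab = "signal", ...)
  invisible(x)
}

#' Sweep the 2D cylinder model across blood-volume fractions
#'
#' For each baseline fBV, computes the static dephasing signal, the R2'
#' rate, and the BOLD fluctuation amplitude dBOLD: the signal difference
#' between the two extremes of the oscillating input (fBV +/- 5% of
#' baseline for arteries, oxygenation +/- 5% for veins; the extremes of a
#' 10% peak-to-peak swing).
#'
#' @param fbvs Baseline fBV values (default `seq(0.1, 0.9, 0.1)`).
#' @param vessel `"artery"` or `"vein"`.
#' @param theta Zenith angle, rad (default `pi/2`).
#' @param params A [sim_params()] object.
#' @param n Sub-voxel side count per evaluation.
#' @param half_swing Half the peak-to-peak fractional swing (default
#'   0.05).
#' @return A data frame with columns `fbv`, `s_t2prime`, `r2prime`, `s`,
#'   `s_lo`, `s_hi`, `delta_bold`.
#' @examples
#' sw <- sweep_fbv_2d(c(0.2, 0.4, 0.6), vessel = "artery", n = 300)
#' sw$fbv[which.max(sw$r2prime)]
#' @export
sweep_fbv_2d <- function(fbvs = seq(0.1, 0.9, by = 0.1),
                         vessel = c("artery", "vein"), theta = pi / 2,
                         params = sim_params(), n = 1000,
                         half_swing = 0.05) {
  vessel <- match.arg(vessel)
  y0 <- if (vessel == "artery") params$y_a else params$y_v
  eval1 <- function(fbv, y) {
    v <- build_2d_voxel(fbv, theta, y, params, n = n)
    voxel_signal(v$field, v$iv_mask, y, params)
  }
  rows <- lapply(fbvs, function(f) {
    base <- eval1(f, y0)
    if (vessel == "artery") {
      lo <- eval1(f * (1 - half_swing), y0)
      hi <- eval1(f * (1 + half_swing), y0)
    } else {
      lo <- eval1(f, y0 * (1 - half_swing))
      hi <- eval1(f, y0 * (1 + half_swing))
    }
    data.frame(fbv = f, s_t2prime = base$s_t2prime,
               r2prime = r2prime(base$s_t2prime, params$te),
               s = base$s, s_lo = lo$s, s_hi = hi$s,
               delta_bold = hi$s - lo$s)
  })
  do.call(rbind, rows)
}

#' Realized fBV of an oblique cylinder through a voxel
#'
#' Purely geometric: voxelizes an oriented cylinder through the voxel
#' centre and returns the occupied fraction of the central voxel. A thin
#' vessel at 45 degrees obliquity runs a sqrt(2)-times longer path
#' through a cubic voxel than an axis-aligned one, so its fBV is about
#' 1.41 times larger.
#'
#' @inheritParams build_3d_voxel
#' @return The occupied fraction of the voxel.
#' @export
realized_fbv_3d <- function(radius, theta, azimuth = 0, n = 100,
                            voxel_mm = 4) {
  mean(cylinder_mask_3d(radius, theta, azimuth, n, voxel_mm, ext = 1))
}

#' Blood-volume fraction of an oblique cylinder, by exact line clipping
#'
#' Computes the volume of an oriented cylinder (axis through the voxel
#' centre) intersected with the cubic voxel, without lattice
#' quantization: the cross-section disc is sampled on a polar grid and
#' each axis-parallel chord is clipped exactly against the cube faces.
#' Useful as the converged reference for the voxelized construction and
#' for the obliquity dependence of fBV (a thin vessel at 45 degrees sees
#' about 1.41 times the fBV of an axis-aligned one; thick vessels less,
#' because the cube corners clip the tube).
#'
#' @param theta,azimuth Axis orientation, rad.
#' @param radius Cylinder radius in mm (default 0.05, thin-vessel
#'   regime).
#' @param voxel_mm Voxel edge in mm.
#' @param n_r,n_phi Radial and angular sample counts of the disc grid.
#' @return The occupied volume fraction of the voxel.
#' @examples
#' oblique_fbv_ratio <- oblique_cylinder_fbv(pi / 4) /
#'   oblique_cylinder_fbv(0)  # about sqrt(2)
#' @export
oblique_cylinder_fbv <- function(theta, azimuth = 0, radius = 0.05,
                                 voxel_mm = 4, n_r = 64, n_phi = 64) {
  L <- voxel_mm
  u <- c(sin(theta) * cos(azimuth), sin(theta) * sin(azimuth), cos(theta))
  # orthonormal frame perpendicular to the axis
  e1 <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0) -
    u * u[1]
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  # midpoint polar grid over the disc (area-weighted)
  rr <- (seq_len(n_r) - 0.5) / n_r
  ph <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  g <- expand.grid(r = rr, p = ph)
  w <- g$r  # polar Jacobian
  q <- outer(radius * g$r * cos(g$p), e1) + outer(radius * g$r * sin(g$p), e2)
  tmin <- rep(-Inf, nrow(q)); tmax <- rep(Inf, nrow(q))
  ok <- rep(TRUE, nrow(q))
  for (i in 1:3) {
    if (abs(u[i]) < 1e-12) {
      ok <- ok & abs(q[, i]) <= L / 2
    } else {
      t1 <- (-L / 2 - q[, i]) / u[i]
      t2 <- (L / 2 - q[, i]) / u[i]
      tmin <- pmax(tmin, pmin(t1, t2))
      tmax <- pmin(tmax, pmax(t1, t2))
    }
  }
  len <- ifelse(ok, pmax(tmax - tmin, 0), 0)
  chord <- sum(w * len) / sum(w)   # mean chord length over the disc
  chord * pi * radius^2 / L^3
}
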