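# Whole-volume macrovascular network simulator: per-frame susceptibility
# volumes under oscillating arterial blood volume and venous oxygenation,
# numerical field computation, and aggregation of sub-voxel complex
# magnetization to fMRI-resolution time series.

# weighted complex block reduction; colSums handles complex
block_sum <- function(x, b) {
  d <- dim(x)
  dim(x) <- c(b, d[1] / b, b, d[2] / b, b, d[3] / b)
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(b^3, prod(d) / b^3)
  array(colSums(x), d / b)
}

#' Aggregate a sub-voxel complex magnetization grid to the fMRI grid
#'
#' Each fMRI voxel's signal is the magnitude of the mean complex
#' magnetization over its block of sub-voxels, consistent with
#' [voxel_signal()] semantics (a uniform-phase block yields the mean
#' weight; equal-weight half-blocks at opposite phase cancel).
#'
#' @param cplx 3D complex array of weighted sub-voxel magnetization
#'   (`w * exp(i*phase)`).
#' @param block Integer block edge; all dimensions must be divisible by
#'   it.
#' @return 3D numeric array of per-fMRI-voxel signal magnitudes.
#' @export
aggregate_to_fmri_grid <- function(cplx, block) {
  if (any(dim(cplx) %% block != 0))
    stop("grid dimensions must be divisible by the block size")
  Mod(block_sum(cplx, block) / block^3)
}

#' Scene for a whole-volume vascular-network simulation
#'
#' Collects the vessel geometry, working and fMRI grids, and the
#' per-class oscillation settings. Arterial vessels oscillate their
#' blood-volume fraction (default 30% peak-to-peak, realized as a
#' continuous modulation of the vessel radius by `sqrt(fbv(t)/fbv0)`);
#' venous vessels oscillate their blood oxygenation (default 10%
#' peak-to-peak). Per-vessel phase offsets are taken from the volume's
#' `vessel_meta` (column `phase`) when present, so vessels can be
#' decorrelated.
#'
#' @param vessel A [vessel_volume()] (centreline + diameter + label, with
#'   optional `vessel_id`/`vessel_meta`).
#' @param params A [sim_params()] object.
#' @param working_voxel Working resolution in mm (default 0.2); should
#'   not exceed the smallest diameter / 4.
#' @param fmri_voxel fMRI voxel size in mm (default 4); must be an
#'   integer multiple of `working_voxel`, and the field of view an
#'   integer multiple of both.
#' @param arterial_ptp,venous_ptp Peak-to-peak fractions of the two
#'   drives.
#' @param frequency Oscillation frequency, Hz.
#' @param pad Zero-padding (working voxels per side) for the field
#'   computation; `NULL` pads by one full field of view.
#' @param mem_cap_gb Refuse to simulate if the padded complex grid would
#'   exceed this many GiB.
#' @return An object of class `macro_van_scene`.
#' @export
macro_van_scene <- function(vessel, params = sim_params(),
                            working_voxel = 0.2, fmri_voxel = 4,
                            arterial_ptp = 0.30, venous_ptp = 0.10,
                            frequency = 0.1, pad = NULL,
                            mem_cap_gb = 6) {
  stopifnot(inherits(vessel, "vessel_volume"))
  fov <- dim(vessel$centreline) * vessel$voxel_size
  dims <- round(fov / working_voxel)
  if (max(abs(dims - fov / working_voxel)) > 1e-6)
    stop("field of view is not an integer multiple of working_voxel")
  block <- fmri_voxel / working_voxel
  if (abs(block - round(block)) > 1e-8 || any(dims %% round(block) != 0))
    stop("fmri_voxel must be an integer multiple of working_voxel and ",
         "divide the field of view")
  pts <- as_centreline_points(vessel)
  if (nrow(pts) && working_voxel > min(pts$diameter) / 4)
    warning("working_voxel exceeds min(diameter)/4")
  meta <- vessel$vessel_meta
  if (is.null(pts$id)) pts$id <- pts$label  # one pseudo-vessel per class
  ids <- sort(unique(pts$id[pts$id > 0]))
  vessels <- lapply(ids, function(i) {
    sel <- pts$id == i
    up <- densify_centreline(pts[sel, , drop = FALSE], vessel$voxel_size,
                             working_voxel / 2)
    cls <- if (!is.null(meta) && "class" %in% names(meta))
      meta$class[match(i, meta$id)] else c("artery", "vein")[pts$label[sel][1]]
    phase <- if (!is.null(meta) && "phase" %in% names(meta))
      meta$phase[match(i, meta$id)] else 0
    list(id = i, class = cls, phase = phase,
         points = as.matrix(up[, c("x", "y", "z")]),
         diameter = up$diameter)
  })
  if (is.null(pad)) pad <- dims
  structure(list(vessels = vessels, params = params, dims = dims,
                 working_voxel = working_voxel, fmri_voxel = fmri_voxel,
                 block = as.integer(round(block)),
                 arterial_ptp = arterial_ptp, venous_ptp = venous_ptp,
                 frequency = frequency, pad = rep_len(pad, 3),
                 mem_cap_gb = mem_cap_gb,
                 cache = new.env(parent = emptyenv())),
            class = "macro_van_scene")
}

#' @export
print.macro_van_scene <- function(x, ...) {
  cat("macro-VAN scene:", paste(x$dims, collapse = " x "),
      "working voxels at", x$working_voxel, "mm;",
      length(x$vessels), "vessel(s);",
      "fMRI voxel", x$fmri_voxel, "mm\n")
  invisible(x)
}

# per-vessel drive value at time t: relative fbv for arteries,
# oxygenation for veins
vessel_drive <- function(scene, v, t) {
  p <- scene$params
  if (v$class == "artery") {
    1 + scene$arterial_ptp / 2 * sin(2 * pi * scene$frequency * t + v$phase)
  } else {
    p$y_v * (1 + scene$venous_ptp / 2 *
               sin(2 * pi * scene$frequency * t + v$phase))
  }
}

vessel_mask_cached <- function(scene, v, radius_scale = 1) {
  key <- sprintf("m_%d_%.6f", v$id, radius_scale)
  m <- scene$cache[[key]]
  if (is.null(m)) {
    m <- stamp_tube(v$points, radius_scale * v$diameter / 2,
                    scene$dims, scene$working_voxel)
    scene$cache[[key]] <- m
  }
  m
}

# full frame state: susceptibility, blood mask and steady-state weights
frame_state <- function(scene, frame_time) {
  p <- scene$params
  chi <- array(0, scene$dims)
  w <- array(compartment_weight("tissue", NA_real_, p), scene$dims)
  blood <- array(FALSE, scene$dims)
  for (v in scene$vessels) {
    d <- vessel_drive(scene, v, frame_time)
    if (v$class == "artery") {
      m <- vessel_mask_cached(scene, v, radius_scale = sqrt(d))
      y <- p$y_a
    } else {
      m <- vessel_mask_cached(scene, v, radius_scale = 1)
      y <- d
    }
    chi[m] <- blood_tissue_susceptibility(y, p)
    w[m] <- compartment_weight("blood", y, p)
    blood <- blood | m
  }
  list(chi = chi, weights = w, blood = blood)
}

#' Susceptibility volume of a scene at one time point
#'
#' Builds the working-resolution susceptibility grid: blood-minus-tissue
#' susceptibility inside vessels (venous oxygenation and arterial radius
#' at their instantaneous oscillating values), zero in tissue.
#'
#' @param scene A [macro_van_scene()].
#' @param frame_time Time in seconds.
#' @return 3D susceptibility array (dimensionless SI).
#' @export
build_susceptibility_volume <- function(scene, frame_time) {
  frame_state(scene, frame_time)$chi
}

#' Simulate a whole-volume vascular-network BOLD run
#'
#' For each frame: builds the susceptibility volume, computes the field
#' via the dipole kernel, accumulates the sub-voxel phase at the echo
#' time, and aggregates the weighted complex magnetization to the fMRI
#' grid. Frames whose oscillation state repeats (the 0.1 Hz drive sampled
#' at TR 2.2 s cycles every 50 frames) are memoized, so long runs cost
#' only as many field computations as there are distinct states.
#'
#' @param scene A [macro_van_scene()].
#' @param n_frames Number of frames (default `params$n_frames`).
#' @return An object of class `simulated_run`: `signals` (4D array, x-y-z
#'   by frame), `fbv` (baseline blood-volume-fraction map), `class_frac`
#'   (list of arterial and venous per-voxel fractions), `tr`, `params`.
#' @export
simulate_van_timeseries <- function(scene, n_frames = scene$params$n_frames) {
  p <- scene$params
  dims <- scene$dims
  padded <- dims + 2 * scene$pad
  need_gb <- prod(padded) * 16 / 1024^3  # complex doubles
  if (need_gb > scene$mem_cap_gb)
    stop(sprintf(paste0("padded grid %s needs %.1f GiB (complex), above the ",
                        "%.1f GiB cap; reduce the field of view or padding"),
                 paste(padded, collapse = "x"), need_gb, scene$mem_cap_gb))
  tt <- (seq_len(n_frames) - 1) * p$tr
  states <- vapply(tt, function(t)
    paste(sprintf("%.10g", vapply(scene$vessels, vessel_drive, 0,
                                  scene = scene, t = t)), collapse = "|"),
    "")
  uniq <- !duplicated(states)
  lut <- match(states, states[uniq])
  nb <- dims %/% scene$block
  sig_u <- vector("list", sum(uniq))
  ui <- 0
  for (k in which(uniq)) {
    ui <- ui + 1
    st <- frame_state(scene, tt[k])
    f <- field_offset_array(st$chi, scene$working_voxel, pad = scene$pad)
    ph <- p$gamma * p$b0 * p$te * f
    cplx <- st$weights * exp(1i * ph)
    sig_u[[ui]] <- aggregate_to_fmri_grid(cplx, scene$block)
  }
  signals <- array(0, c(nb, n_frames))
  for (k in seq_len(n_frames)) {
    signals[, , , k] <- sig_u[[lut[k]]]
  }
  base <- baseline_masks(scene)
  structure(list(signals = signals, fbv = base$fbv,
                 class_frac = base$class_frac, tr = p$tr, params = p,
                 fmri_voxel = scene$fmri_voxel),
            class = "simulated_run")
}

# baseline fBV and per-class occupancy at the fMRI grid
baseline_masks <- function(scene) {
  b <- scene$block
  art <- array(FALSE, scene$dims)
  ven <- array(FALSE, scene$dims)
  for (v in scene$vessels) {
    m <- vessel_mask_cached(scene, v, 1)
    if (v$class == "artery") art <- art | m else ven <- ven | m
  }
  list(fbv = block_sum((art | ven) + 0, b) / b^3,
       class_frac = list(artery = block_sum(art + 0, b) / b^3,
                         vein = block_sum(ven + 0, b) / b^3))
}

#' @export
print.simulated_run <- function(x, ...) {
  d <- dim(x$signals)
  cat("simulated run:", paste(d[1:3], collapse = " x "), "fMRI voxels x",
      d[4], "frames at TR", x$tr, "s\n")
  cat(sprintf("  %d voxels with fBV > 0 (max %.3f)\n",
              sum(x$fbv > 0), max(x$fbv)))
  invisible(x)
}

#' Per-voxel time-series matrix of a simulated run
#'
#' @param run A `simulated_run` (or any 4D array).
#' @param voxels Optional logical 3D array or integer vector selecting
#'   voxels.
#' @return A frames-by-voxels numeric matrix; column names are voxel
#'   linear indices.
#' @export
run_series_matrix <- function(run, voxels = NULL) {
  sig <- if (inherits(run, "simulated_run")) run$signals else run
  d <- dim(sig)
  m <- matrix(sig, prod(d[1:3]), d[4])
  idx <- if (is.null(voxels)) seq_len(nrow(m))
         else if (is.logical(voxels)) which(voxels) else voxels
  out <- t(m[idx, , drop = FALSE])
  colnames(out) <- as.character(idx)
  out
}
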