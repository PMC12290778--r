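# Vascular geometry processing: centreline volumes carrying diameter and
# artery/vein labels, local orientation estimation, tube voxelization,
# blood-volume-fraction maps and perivascular shells.
#
# Conventions: voxel indices are 1-based in R but the geometry uses the
# voxel-centre convention with the grid corner at the origin, so voxel i
# is centred at (i - 0.5) * voxel_size mm. Label codes: 0 = none,
# 1 = artery, 2 = vein.

#' Gridded vessel representation
#'
#' A centreline volume with per-voxel diameter and artery/vein labels, the
#' standard encoding of a macrovascular anatomical network derived from
#' time-of-flight angiography segmentation.
#'
#' @param centreline 3D logical array marking centreline voxels.
#' @param diameter 3D numeric array, vessel diameter in mm (non-zero only
#'   on the centreline).
#' @param label 3D integer array: 0 none, 1 artery, 2 vein; non-zero only
#'   on the centreline.
#' @param voxel_size Isotropic voxel size in mm.
#' @param direction_cosines 3x3 orientation of the grid axes in the
#'   scanner frame (rows map grid axes to scanner axes); the scanner z
#'   axis is the main-field direction.
#' @param vessel_id Optional 3D integer array tagging each centreline
#'   voxel with the vessel it belongs to.
#' @param vessel_meta Optional data frame with one row per vessel id
#'   (columns such as `id`, `class`, `phase`).
#' @return An object of class `vessel_volume`.
#' @export
vessel_volume <- function(centreline, diameter, label, voxel_size,
                          direction_cosines = diag(3),
                          vessel_id = NULL, vessel_meta = NULL) {
  stopifnot(length(dim(centreline)) == 3,
            identical(dim(centreline), dim(diameter)),
            identical(dim(centreline), dim(label)),
            voxel_size > 0)
  centreline <- centreline != 0
  if (any(diameter[centreline] <= 0))
    stop("diameter must be positive on every centreline voxel")
  if (any(diameter[!centreline] != 0))
    stop("diameter must be zero off the centreline")
  if (any(label[!centreline] != 0))
    stop("labels must be zero off the centreline")
  structure(list(centreline = centreline, diameter = diameter,
                 label = label, voxel_size = voxel_size,
                 direction_cosines = direction_cosines,
                 vessel_id = vessel_id, vessel_meta = vessel_meta),
            class = "vessel_volume")
}

#' @export
print.vessel_volume <- function(x, ...) {
  n <- sum(x$centreline)
  cat("vessel volume:", paste(dim(x$centreline), collapse = " x "),
      "voxels at", x$voxel_size, "mm;", n, "centreline voxels\n")
  if (n) {
    d <- x$diameter[x$centreline]
    cat(sprintf("  diameters %.2f-%.2f mm; %d arterial, %d venous voxels\n",
                min(d), max(d), sum(x$label == 1), sum(x$label == 2)))
  }
  invisible(x)
}

#' Merge centreline volumes from multiple sources
#'
#' Takes the union of the centrelines; where sources overlap, the highest
#' diameter estimate is kept. Conflicting artery/vein labels are resolved
#' in favour of the vein (warned), since venous susceptibility dominates
#' the BOLD effect where the two overlap.
#'
#' @param sources A list of [vessel_volume()] objects on a common grid.
#' @return A merged `vessel_volume`.
#' @export
merge_centerline_sources <- function(sources) {
  stopifnot(length(sources) >= 1)
  ref <- sources[[1]]
  for (s in sources[-1]) {
    if (!identical(dim(s$centreline), dim(ref$centreline)) ||
        !isTRUE(all.equal(s$voxel_size, ref$voxel_size)))
      stop("sources must share one grid (dimensions and voxel size)")
  }
  cl <- ref$centreline
  di <- ref$diameter
  la <- ref$label
  for (s in sources[-1]) {
    conflict <- cl & s$centreline & la > 0 & s$label > 0 & la != s$label
    if (any(conflict)) {
      warning(sum(conflict),
              " voxel(s) with conflicting artery/vein labels; vein kept")
      la[conflict] <- 2L
    }
    take <- s$centreline & (!cl | s$diameter > di)
    di[take] <- s$diameter[take]
    la[take & !conflict] <- s$label[take & !conflict]
    cl <- cl | s$centreline
  }
  vessel_volume(cl, di, la, ref$voxel_size, ref$direction_cosines)
}

# 26-connected neighbour offsets
.offsets26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
.offsets26 <- .offsets26[rowSums(abs(.offsets26)) > 0, ]

#' Local vessel orientation
#'
#' Estimates, at every centreline voxel, the direction of the vessel as
#' the line through the pair of centreline voxels that (a) lie in the
#' `window^3` neighbourhood, (b) are both connected to the central voxel
#' along the centreline (26-connectivity), and (c) are maximally separated
#' in Euclidean distance. If no connected pair exists but other centreline
#' voxels occupy the window, the principal axis of their second-moment
#' tensor is used instead. Isolated voxels get `NA` orientation and are
#' excluded downstream.
#'
#' The direction is mapped to the scanner frame through the volume's
#' direction cosines. Because a centreline has no preferred direction of
#' travel (and all field formulas depend on the orientation only through
#' `sin^2`, `cos^2` and `cos(2*phi)`), the zenith is folded to
#' `[0, pi/2]` and the azimuth to `[0, pi)`.
#'
#' @param v A [vessel_volume()].
#' @param window Odd window edge length in voxels (default 9).
#' @return A list of class `orientation_map` with 3D arrays `zenith` and
#'   `azimuth` (radians, `NA` off the centreline or where undefined).
#' @export
local_orientation <- function(v, window = 9) {
  stopifnot(inherits(v, "vessel_volume"), window %% 2 == 1, window >= 3)
  h <- (window - 1) / 2
  dims <- dim(v$centreline)
  zen <- array(NA_real_, dims)
  azi <- array(NA_real_, dims)
  idx <- which(v$centreline, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(structure(list(zenith = zen, azimuth = azi),
                     class = "orientation_map"))
  for (k in seq_len(nrow(idx))) {
    c0 <- idx[k, ]
    lo <- pmax(c0 - h, 1)
    hi <- pmin(c0 + h, dims)
    sub <- v$centreline[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    pts <- which(array(sub, hi - lo + 1), arr.ind = TRUE)
    pts <- sweep(pts, 2, lo - 1, `+`)  # back to global indices
    if (nrow(pts) < 2) next           # isolated voxel: undefined
    # connectivity to the centre along the centreline, within the window
    keyfun <- function(m) (m[, 1] - 1) + dims[1] * ((m[, 2] - 1) +
                                                      dims[2] * (m[, 3] - 1))
    keys <- keyfun(pts)
    reach <- keyfun(matrix(c0, 1)) == keys
    frontier <- which(reach)
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- sweep(.offsets26, 2, as.numeric(pts[f, ]), `+`)
        hit <- which(!reach & keys %in% keyfun(nb))
        reach[hit] <- TRUE
        nxt <- c(nxt, hit)
      }
      frontier <- nxt
    }
    cand <- pts[reach, , drop = FALSE]
    dir <- NULL
    if (nrow(cand) >= 2) {
      dm <- as.matrix(stats::dist(cand))
      best <- which(dm == max(dm), arr.ind = TRUE)[1, ]
      dir <- cand[best[1], ] - cand[best[2], ]
    } else {
      # centre cut off from its window companions: principal axis fallback
      ctr <- sweep(pts, 2, colMeans(pts))
      dir <- eigen(crossprod(ctr), symmetric = TRUE)$vectors[, 1]
    }
    dir <- as.numeric(dir %*% v$direction_cosines)
    dir <- dir / sqrt(sum(dir^2))
    zen[c0[1], c0[2], c0[3]] <- acos(min(abs(dir[3]), 1))
    azi[c0[1], c0[2], c0[3]] <- atan2(dir[2], dir[1]) %% pi
  }
  structure(list(zenith = zen, azimuth = azi), class = "orientation_map")
}

# Stamp tubes: mark every voxel of a target grid whose centre lies within
# radius of any of the given centreline points (mm coordinates). A
# centreline sampled at least once per voxel makes the union of spheres
# equivalent to a tube around the polyline.
stamp_tube <- function(points_mm, radius_mm, dims, voxel_size) {
  mask <- array(FALSE, dims)
  if (nrow(points_mm) == 0) return(mask)
  radius_mm <- rep_len(radius_mm, nrow(points_mm))
  for (rr in unique(radius_mm)) {
    sel <- radius_mm == rr
    rv <- rr / voxel_size
    w <- floor(rv + 0.5)
    off <- as.matrix(expand.grid(-w:w, -w:w, -w:w))
    off <- off[rowSums(off^2) > 0 | TRUE, , drop = FALSE]
    pts <- points_mm[sel, , drop = FALSE]
    ctr <- pts / voxel_size + 0.5  # fractional voxel index of the point
    base <- round(ctr)
    for (j in seq_len(nrow(off))) {
      cand <- sweep(base, 2, off[j, ], `+`)
      d2 <- rowSums((cand - 0.5 - pts / voxel_size)^2)
      ok <- d2 <= rv^2 + 1e-9
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      inb <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
        cand[, 1] <= dims[1] & cand[, 2] <= dims[2] & cand[, 3] <= dims[3]
      cand <- cand[inb, , drop = FALSE]
      if (nrow(cand)) mask[cand] <- TRUE
    }
  }
  mask
}

#' Centreline voxels as a point table
#'
#' @param v A [vessel_volume()].
#' @param orient Optional [local_orientation()] result to attach zenith
#'   and azimuth columns.
#' @return A data frame with columns `x`, `y`, `z` (mm, voxel-centre
#'   coordinates), `diameter`, `label`, optionally `id`, `zenith`,
#'   `azimuth`.
#' @export
as_centreline_points <- function(v, orient = NULL) {
  idx <- which(v$centreline, arr.ind = TRUE)
  out <- data.frame((idx - 0.5) * v$voxel_size)
  names(out) <- c("x", "y", "z")
  out$diameter <- v$diameter[idx]
  out$label <- v$label[idx]
  if (!is.null(v$vessel_id)) out$id <- v$vessel_id[idx]
  if (!is.null(orient)) {
    out$zenith <- orient$zenith[idx]
    out$azimuth <- orient$azimuth[idx]
  }
  out
}

#' Voxelize vessels into a binary mask
#'
#' Builds a tube mask at a (typically finer) target resolution: the
#' centreline path is resampled at the target resolution along the
#' piecewise-linear segments joining 26-adjacent centreline voxels
#' (diameters carried over nearest-neighbour style, the larger of the two
#' endpoint diameters), then a voxel becomes vessel if its centre lies
#' within `radius_scale * diameter / 2` of the resampled path. With
#' `radius_scale = 0` only the voxels traversed by the path are marked.
#'
#' @param v A [vessel_volume()].
#' @param target_voxel Target voxel size in mm; the source grid extent
#'   must be an integer multiple of it. Values above `min(diameter) / 4`
#'   trigger a warning (coarse sampling of the smallest vessels).
#' @param radius_scale Multiplier on the vessel radius (default 1).
#' @return A 3D logical array with attribute `voxel_size`.
#' @export
voxelize_vessels <- function(v, target_voxel, radius_scale = 1) {
  stopifnot(inherits(v, "vessel_volume"), target_voxel > 0,
            radius_scale >= 0)
  pts <- as_centreline_points(v)
  ratio <- v$voxel_size / target_voxel
  dims <- round(dim(v$centreline) * ratio)
  if (max(abs(dims - dim(v$centreline) * ratio)) > 1e-6)
    stop("grid extent is not an integer multiple of target_voxel")
  if (nrow(pts) == 0) {
    out <- array(FALSE, dims)
    attr(out, "voxel_size") <- target_voxel
    return(out)
  }
  if (target_voxel > min(pts$diameter) / 4)
    warning("target_voxel exceeds min(diameter)/4; tube cross-sections ",
            "will be coarsely sampled")
  up <- densify_centreline(pts, v$voxel_size, target_voxel / 2)
  mask <- if (radius_scale == 0) {
    m <- array(FALSE, dims)
    ii <- cbind(pmin(pmax(ceiling(up$x / target_voxel), 1), dims[1]),
                pmin(pmax(ceiling(up$y / target_voxel), 1), dims[2]),
                pmin(pmax(ceiling(up$z / target_voxel), 1), dims[3]))
    m[ii] <- TRUE
    m
  } else {
    stamp_tube(as.matrix(up[, c("x", "y", "z")]),
               radius_scale * up$diameter / 2, dims, target_voxel)
  }
  attr(mask, "voxel_size") <- target_voxel
  mask
}

# Resample a centreline point table along the piecewise-linear segments
# joining 26-adjacent centreline voxels, at the given arc-length step.
# Segment samples inherit the larger endpoint diameter (the merging
# convention for overlapping estimates). Isolated points are kept as-is.
densify_centreline <- function(pts, source_voxel, step) {
  co <- as.matrix(pts[, c("x", "y", "z")])
  gi <- round(sweep(co, 2, source_voxel, `/`) + 0.5)  # voxel indices
  key <- paste(gi[, 1], gi[, 2], gi[, 3])
  half <- .offsets26[seq_len(13), , drop = FALSE]  # one of each +/- pair
  out <- list(cbind(co, pts$diameter))
  for (j in seq_len(nrow(half))) {
    o <- half[j, ]
    nb_key <- paste(gi[, 1] + o[1], gi[, 2] + o[2], gi[, 3] + o[3])
    hit <- match(nb_key, key)
    has <- !is.na(hit)
    if (!any(has)) next
    a <- co[has, , drop = FALSE]
    b <- co[hit[has], , drop = FALSE]
    dmax <- pmax(pts$diameter[has], pts$diameter[hit[has]])
    len <- sqrt(sum((o * source_voxel)^2))
    nstep <- max(1L, ceiling(len / step))
    for (t in seq_len(nstep - 1) / nstep) {
      out[[length(out) + 1]] <- cbind(a + t * (b - a), dmax)
    }
  }
  m <- do.call(rbind, out)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], diameter = m[, 4])
}

# block-mean of a 3D array with integer block edge
block_mean <- function(x, block) {
  d <- dim(x)
  nb <- d %/% block
  dim(x) <- c(block, nb[1], block, nb[2], block, nb[3])
  out <- apply(x, c(2, 4, 6), mean)
  out
}

#' Blood-volume-fraction map at fMRI resolution
#'
#' Aggregates a high-resolution vessel mask to the fMRI grid by counting
#' occupied sub-voxels per fMRI voxel. If a centreline point table with
#' orientations is supplied, each fMRI voxel is also assigned the dominant
#' orientation: the zenith/azimuth at the largest-diameter centreline
#' point falling inside it.
#'
#' @param mask High-resolution logical array (attribute `voxel_size`, or
#'   pass `voxel_size`).
#' @param fmri_voxel fMRI voxel size in mm (default 4); must be an integer
#'   multiple of the mask's voxel size.
#' @param voxel_size Voxel size of `mask` in mm, if not carried as an
#'   attribute.
#' @param points Optional centreline point table from
#'   [as_centreline_points()] with `zenith`/`azimuth` columns.
#' @return A list of class `fbv_map`: `fbv` (3D array in `[0, 1]`),
#'   `zenith`, `azimuth` (3D arrays, `NA` where no centreline point
#'   falls), `voxel_size`.
#' @export
fbv_map <- function(mask, fmri_voxel = 4, voxel_size = attr(mask, "voxel_size"),
                    points = NULL) {
  if (is.null(voxel_size)) stop("mask carries no voxel_size")
  ratio <- fmri_voxel / voxel_size
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("fmri_voxel must be an integer multiple of the mask voxel size")
  ratio <- round(ratio)
  if (any(dim(mask) %% ratio != 0))
    stop("mask dimensions must be divisible by the resolution ratio")
  fbv <- block_mean(mask + 0, ratio)
  zen <- array(NA_real_, dim(fbv))
  azi <- array(NA_real_, dim(fbv))
  if (!is.null(points) && nrow(points)) {
    bi <- cbind(pmin(pmax(ceiling(points$x / fmri_voxel), 1), dim(fbv)[1]),
                pmin(pmax(ceiling(points$y / fmri_voxel), 1), dim(fbv)[2]),
                pmin(pmax(ceiling(points$z / fmri_voxel), 1), dim(fbv)[3]))
    ord <- order(points$diameter)  # later (larger) writes win
    for (k in ord) {
      zen[bi[k, 1], bi[k, 2], bi[k, 3]] <- points$zenith[k]
      azi[bi[k, 1], bi[k, 2], bi[k, 3]] <- points$azimuth[k]
    }
  }
  structure(list(fbv = fbv, zenith = zen, azimuth = azi,
                 voxel_size = fmri_voxel),
            class = "fbv_map")
}

# one-step binary dilation by shifting (26- or 6-connected)
dilate3d <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(mask)
  out <- mask
  offs <- if (connectivity == 26) .offsets26 else
    .offsets26[rowSums(abs(.offsets26)) == 1, ]
  for (j in seq_len(nrow(offs))) {
    o <- offs[j, ]
    src <- list(max(1, 1 - o[1]):min(d[1], d[1] - o[1]),
                max(1, 1 - o[2]):min(d[2], d[2] - o[2]),
                max(1, 1 - o[3]):min(d[3], d[3] - o[3]))
    dst <- list(src[[1]] + o[1], src[[2]] + o[2], src[[3]] + o[3])
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] |
      mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Perivascular shells
#'
#' Shell k is the set of voxels added by the k-th one-voxel dilation of
#' the vessel mask: `dilate^k(mask) - dilate^(k-1)(mask)`. Shells are
#' pairwise disjoint and disjoint from the mask, and their union with the
#' mask equals the k-fold dilation.
#'
#' @param mask 3D logical array (typically at fMRI resolution).
#' @param n_shells Number of shells (>= 1, default 3).
#' @param connectivity 26 (default; one voxel in every direction including
#'   diagonals) or 6 (faces only).
#' @return A list of `n_shells` logical arrays.
#' @export
perivascular_shells <- function(mask, n_shells = 3, connectivity = 26) {
  stopifnot(n_shells >= 1)
  shells <- vector("list", n_shells)
  prev <- mask
  for (k in seq_len(n_shells)) {
    cur <- dilate3d(prev, connectivity)
    shells[[k]] <- cur & !prev
    prev <- cur
  }
  shells
}
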