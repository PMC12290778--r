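# NIfTI-1 input/output for vessel volumes, masks and runs, plus a small
# provenance writer used by the command-line interface. Volumes are
# written as float32 with the voxel size in the header.

#' Read a vessel volume from a NIfTI triplet
#'
#' @param centreline,diameter,label Paths to NIfTI volumes on a common
#'   grid: a binary centreline mask, the diameter image in mm, and the
#'   label image (0 none, 1 artery, 2 vein).
#' @return A [vessel_volume()]; the voxel size is taken from the
#'   centreline header (must be isotropic).
#' @export
read_vessel_volume <- function(centreline, diameter, label) {
  cl <- RNifti::readNifti(centreline)
  vs <- RNifti::pixdim(cl)
  if (max(abs(vs - vs[1])) > 1e-6)
    stop("anisotropic voxels are not supported")
  di <- RNifti::readNifti(diameter)
  la <- RNifti::readNifti(label)
  xf <- structure(RNifti::xform(cl), class = NULL)
  dc <- xf[1:3, 1:3] / vs[1]
  vessel_volume(array(as.array(cl) != 0, dim(cl)),
                array(as.numeric(di), dim(di)),
                array(as.integer(la), dim(la)),
                voxel_size = vs[1], direction_cosines = dc)
}

#' Write a 3D or 4D array as a float32 NIfTI volume
#'
#' @param x Numeric or logical array (a `field_volume` or
#'   `simulated_run` is unwrapped).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel size in mm (scalar or length 3); taken from
#'   the object when it carries one.
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(x, path, voxel_size = NULL) {
  if (inherits(x, "field_volume")) {
    voxel_size <- x$voxel_size
    x <- x$data
  } else if (inherits(x, "simulated_run")) {
    if (is.null(voxel_size)) voxel_size <- x$fmri_voxel
    x <- x$signals
  }
  if (is.null(voxel_size)) voxel_size <- attr(x, "voxel_size")
  if (is.null(voxel_size)) stop("voxel_size required")
  vs <- rep_len(voxel_size, 3)
  img <- RNifti::asNifti(array(as.numeric(x), dim(x)),
                         reference = list(pixdim = c(-1, vs, rep(1, 4))),
                         datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Array with attribute `voxel_size` (mm).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1]
  out
}

#' Write a provenance record next to an output
#'
#' Records the invoking configuration, package version and seed so any
#' output directory documents how to reproduce it.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seed Seed used, if any.
#' @return The path, invisibly.
#' @export
write_provenance <- function(path, config = list(), seed = NULL) {
  rec <- list(
    package = "vasobold",
    version = as.character(utils::packageVersion("vasobold")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
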