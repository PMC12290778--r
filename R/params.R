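#' Simulation parameters
#'
#' Bundles the physical constants and sequence parameters used by every
#' simulator in the package. Defaults correspond to a gradient-echo EPI
#' resting-state acquisition at 3 T (TR 2.2 s, TE 27 ms, 90-degree flip,
#' 30-minute run) with standard literature values for blood and tissue
#' properties. All quantities are SI: seconds, Tesla, radians;
#' susceptibilities are dimensionless SI volume susceptibilities.
#'
#' @param delta_chi Volume susceptibility difference between fully
#'   deoxygenated and fully oxygenated blood (dimensionless SI). The default
#'   is 4*pi*0.27e-6, i.e. 0.27 ppm (cgs) converted to SI.
#' @param hct Hematocrit fraction in `[0, 1]`.
#' @param b0 Main magnetic field strength in Tesla.
#' @param te Echo time in seconds.
#' @param tr Repetition time in seconds; must exceed `te`.
#' @param alpha Flip angle in radians.
#' @param y_a,y_v,y_tissue Arterial, venous and tissue oxygenation
#'   fractions in `[0, 1]`.
#' @param t1_blood,t1_tissue Longitudinal relaxation times in seconds.
#' @param t2_tissue Transverse relaxation time of grey matter in seconds.
#' @param t2_blood_coef Named coefficients `c(A, B, C)` in 1/s of the
#'   quadratic blood relaxometry law `1/T2 = A + B*(1-Y) + C*(1-Y)^2`.
#' @param gamma Proton gyromagnetic ratio in rad/s/T.
#' @param n_frames Number of frames per run; the default 818 is
#'   `floor(30 min / 2.2 s)`.
#' @param signal_form Either `"as_printed"` (the steady-state expression with
#'   the `exp(-TE/T2)` factor inside the denominator) or `"spgr"` (the
#'   textbook spoiled-gradient-echo form with a multiplicative
#'   `exp(-TE/T2)` decay). See [steady_state_signal()].
#'
#' @return An object of class `sim_params`: a validated list of the above
#'   fields plus the derived Larmor angular frequency `omega0 = gamma * b0`.
#' @examples
#' p <- sim_params()
#' p$omega0 / (2 * pi) / 1e6  # Larmor frequency at 3 T, MHz
#' @export
sim_params <- function(delta_chi = 4 * pi * 0.27e-6,
                       hct = 0.4,
                       b0 = 3,
                       te = 0.027,
                       tr = 2.2,
                       alpha = pi / 2,
                       y_a = 0.98,
                       y_v = 0.6,
                       y_tissue = 0.85,
                       t1_blood = 1.649,
                       t1_tissue = 1.465,
                       t2_tissue = 0.066,
                       t2_blood_coef = c(A = 4.0, B = 35, C = 300),
                       gamma = 2 * pi * 42.58e6,
                       n_frames = 818L,
                       signal_form = c("as_printed", "spgr")) {
  signal_form <- match.arg(signal_form)
  p <- list(delta_chi = delta_chi, hct = hct, b0 = b0, te = te, tr = tr,
            alpha = alpha, y_a = y_a, y_v = y_v, y_tissue = y_tissue,
            t1_blood = t1_blood, t1_tissue = t1_tissue,
            t2_tissue = t2_tissue,
            t2_blood_coef = t2_blood_coef,
            gamma = gamma, n_frames = as.integer(n_frames),
            signal_form = signal_form)
  stopifnot(
    "hct must lie in [0, 1]" = hct >= 0 && hct <= 1,
    "oxygenation fractions must lie in [0, 1]" =
      all(c(y_a, y_v, y_tissue) >= 0 & c(y_a, y_v, y_tissue) <= 1),
    "te must be shorter than tr" = te < tr,
    "all times must be positive" =
      all(c(te, tr, t1_blood, t1_tissue, t2_tissue) > 0),
    "n_frames must be positive" = n_frames >= 1
  )
  if (length(t2_blood_coef) != 3)
    stop("t2_blood_coef must hold the three coefficients A, B, C")
  p$omega0 <- gamma * b0
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (", x$b0, "T, TE ", x$te * 1e3, " ms, TR ",
      x$tr, " s, alpha ", round(x$alpha * 180 / pi, 1), " deg)\n", sep = "")
  cat(sprintf("  Y_a %.2f  Y_v %.2f  Y_tissue %.2f  Hct %.2f\n",
              x$y_a, x$y_v, x$y_tissue, x$hct))
  cat(sprintf("  T1 blood/tissue %.0f/%.0f ms, T2 tissue %.0f ms, %d frames\n",
              x$t1_blood * 1e3, x$t1_tissue * 1e3, x$t2_tissue * 1e3,
              x$n_frames))
  cat("  steady-state form:", x$signal_form, "\n")
  invisible(x)
}

#' Update simulation parameters from a config file
#'
#' Reads a YAML or JSON file whose keys mirror the parameter names of
#' [sim_params()]. Times may alternatively be given in milliseconds via
#' `*_ms` keys (`te_ms`, `tr_ms`, `t1_blood_ms`, `t1_tissue_ms`,
#' `t2_tissue_ms`), and the flip angle in degrees via `alpha_deg`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param base Parameters to update; defaults to `sim_params()`.
#' @return A `sim_params` object.
#' @export
load_sim_params <- function(path, base = sim_params()) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ms <- c(te_ms = "te", tr_ms = "tr", t1_blood_ms = "t1_blood",
          t1_tissue_ms = "t1_tissue", t2_tissue_ms = "t2_tissue")
  for (k in names(ms)) {
    if (!is.null(cfg[[k]])) {
      cfg[[ms[[k]]]] <- cfg[[k]] / 1e3
      cfg[[k]] <- NULL
    }
  }
  if (!is.null(cfg$alpha_deg)) {
    cfg$alpha <- cfg$alpha_deg * pi / 180
    cfg$alpha_deg <- NULL
  }
  known <- setdiff(names(formals(sim_params)), "signal_form")
  bad <- setdiff(names(cfg), c(known, "signal_form"))
  if (length(bad))
    stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "))
  args <- unclass(base)
  args$omega0 <- NULL
  args[names(cfg)] <- cfg
  do.call(sim_params, args)
}

#' Sinusoidal oscillation of a physiological quantity
#'
#' Describes the low-frequency sinusoidal drive applied to a vascular
#' quantity: the arterial blood-volume fraction or the venous oxygenation.
#' The peak-to-peak excursion is expressed as a fraction of the baseline,
#' so `peak_to_peak_fraction = 0.10` means the value swings between 95%
#' and 105% of baseline ("+/-10% peak-to-peak").
#'
#' @param target Which quantity oscillates: `"arterial_fbv"` or
#'   `"venous_y"`.
#' @param baseline Baseline value (a fraction in `[0, 1]`).
#' @param peak_to_peak_fraction Total swing as a fraction of baseline.
#'   Defaults to 0.10; whole-volume vascular-network simulations use 0.30
#'   for arterial blood volume so the quantized vessel footprint can change
#'   by one voxel.
#' @param frequency Oscillation frequency in Hz (default 0.1).
#' @param phase Phase offset in radians.
#' @return An object of class `oscillation_spec`.
#' @examples
#' os <- oscillation_spec("venous_y", baseline = 0.6)
#' oscillate(os, seq(0, 10, by = 2.2))
#' @export
oscillation_spec <- function(target = c("arterial_fbv", "venous_y"),
                             baseline,
                             peak_to_peak_fraction = 0.10,
                             frequency = 0.1,
                             phase = 0) {
  target <- match.arg(target)
  stopifnot(
    "peak_to_peak_fraction must be non-negative" = peak_to_peak_fraction >= 0,
    "frequency must be positive" = frequency > 0,
    "baseline must lie in [0, 1]" = baseline >= 0 && baseline <= 1
  )
  hi <- baseline * (1 + peak_to_peak_fraction / 2)
  lo <- baseline * (1 - peak_to_peak_fraction / 2)
  if (lo < 0 || hi > 1)
    stop("oscillation would leave [0, 1]: range [",
         signif(lo, 4), ", ", signif(hi, 4), "]")
  structure(list(target = target, baseline = baseline,
                 peak_to_peak_fraction = peak_to_peak_fraction,
                 frequency = frequency, phase = phase),
            class = "oscillation_spec")
}

#' @export
print.oscillation_spec <- function(x, ...) {
  cat(sprintf("oscillation: %s, baseline %.3g, %.0f%% peak-to-peak, %.3g Hz, phase %.3g rad\n",
              x$target, x$baseline, 100 * x$peak_to_peak_fraction,
              x$frequency, x$phase))
  invisible(x)
}

#' Evaluate an oscillation at given times
#'
#' @param spec An [oscillation_spec()].
#' @param t Time(s) in seconds, non-negative.
#' @return `baseline * (1 + (ptp/2) * sin(2*pi*f*t + phase))`, vectorized
#'   over `t`. The time-average over an integer number of periods equals
#'   the baseline.
#' @export
oscillate <- function(spec, t) {
  stopifnot(inherits(spec, "oscillation_spec"), all(t >= 0))
  spec$baseline *
    (1 + spec$peak_to_peak_fraction / 2 *
       sin(2 * pi * spec$frequency * t + spec$phase))
}
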