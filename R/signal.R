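#' Blood-tissue susceptibility difference
#'
#' Volume susceptibility of blood at oxygenation `y`, either relative to
#' the surrounding tissue (the difference that drives extravascular field
#' offsets) or in absolute form relative to fully oxygenated blood.
#'
#' The tissue-referenced form is `delta_chi * hct * (y_tissue - y)`:
#' positive for veins (less oxygenated than tissue), negative for
#' arteries. The absolute form is `delta_chi * hct * (1 - y)`.
#'
#' @param y Oxygenation fraction(s) in `[0, 1]`.
#' @param params A [sim_params()] object.
#' @param reference `"tissue"` (default) or `"oxygenated"` for the
#'   absolute form.
#' @return Dimensionless SI susceptibility (difference), vectorized over
#'   `y`.
#' @examples
#' p <- sim_params()
#' blood_tissue_susceptibility(p$y_v, p)  # venous, positive
#' blood_tissue_susceptibility(p$y_a, p)  # arterial, negative
#' @export
blood_tissue_susceptibility <- function(y, params = sim_params(),
                                        reference = c("tissue", "oxygenated")) {
  reference <- match.arg(reference)
  if (any(y < 0 | y > 1)) stop("oxygenation y must lie in [0, 1]")
  ref <- if (reference == "tissue") params$y_tissue else 1
  params$delta_chi * params$hct * (ref - y)
}

#' Relaxation times of blood or tissue
#'
#' Tissue T1 and T2 are constants from the parameter set. Blood T1 is a
#' constant; blood T2 depends on oxygenation through the quadratic
#' relaxometry law `1/T2 = A + B*(1 - Y) + C*(1 - Y)^2` with coefficients
#' `params$t2_blood_coef` (defaults calibrated for 3 T). For positive B
#' and C the law makes T2 strictly decrease with deoxygenation.
#'
#' @param y Oxygenation fraction in `[0, 1]` (used for blood only).
#' @param compartment `"blood"` or `"tissue"`.
#' @param params A [sim_params()] object.
#' @return Named numeric vector `c(t1 = , t2 = )` in seconds.
#' @export
relaxation_times <- function(y, compartment = c("blood", "tissue"),
                             params = sim_params()) {
  compartment <- match.arg(compartment)
  if (compartment == "tissue")
    return(c(t1 = params$t1_tissue, t2 = params$t2_tissue))
  if (any(is.na(y)) || any(y < 0 | y > 1))
    stop("oxygenation y must lie in [0, 1]")
  cf <- params$t2_blood_coef
  r2 <- cf[[1]] + cf[[2]] * (1 - y) + cf[[3]] * (1 - y)^2
  if (any(r2 <= 0))
    stop("blood T2 law gives non-positive relaxation rate; check t2_blood_coef")
  c(t1 = params$t1_blood, t2 = 1 / r2)
}

#' Steady-state gradient-echo signal amplitude
#'
#' Scales a mesoscopic-dephasing attenuation factor by the steady-state
#' amplitude of a spoiled gradient-echo acquisition.
#'
#' With `signal_form = "as_printed"` (default) the expression is
#' `sin(a) * (1 - E1) / (1 - cos(a) * E1 * E2) * s_t2prime` with
#' `E1 = exp(-TR/T1)` and `E2 = exp(-TE/T2)`, the transverse-decay factor
#' sitting inside the steady-state denominator. With `"spgr"` the textbook
#' form `sin(a) * (1 - E1) / (1 - cos(a) * E1) * E2 * s_t2prime` is used
#' instead. At a 90-degree flip angle the two differ only by the
#' multiplicative `E2`, and the denominator reduces to 1 in both.
#'
#' @param s_t2prime Dephasing attenuation in `[0, 1]` (see
#'   [voxel_signal()]).
#' @param t1,t2 Relaxation times in seconds.
#' @param params A [sim_params()] object (supplies TR, TE, flip angle and
#'   the form switch).
#' @return Signal amplitude; monotone increasing in `s_t2prime` and
#'   bounded by `sin(alpha)`.
#' @export
steady_state_signal <- function(s_t2prime, t1, t2, params = sim_params()) {
  if (any(s_t2prime < 0 | s_t2prime > 1))
    stop("s_t2prime must lie in [0, 1]")
  e1 <- exp(-params$tr / t1)
  e2 <- exp(-params$te / t2)
  if (params$signal_form == "as_printed") {
    den <- 1 - cos(params$alpha) * e1 * e2
    if (any(den <= 0)) stop("non-positive steady-state denominator")
    sin(params$alpha) * (1 - e1) / den * s_t2prime
  } else {
    den <- 1 - cos(params$alpha) * e1
    if (any(den <= 0)) stop("non-positive steady-state denominator")
    sin(params$alpha) * (1 - e1) / den * e2 * s_t2prime
  }
}

# Steady-state amplitude prefactor for one compartment (the weight applied
# to each sub-voxel in complex signal formation).
compartment_weight <- function(compartment, y, params) {
  rt <- relaxation_times(y, compartment, params)
  steady_state_signal(1, rt[["t1"]], rt[["t2"]], params)
}
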