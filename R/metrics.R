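# Resting-state metrics (RSFA, extremum cross-correlation FC,
# sigma-weighting) and binned-regression evaluation of predicted against
# measured connectivity.

#' Resting-state fluctuation amplitude
#'
#' Normalizes a voxel time series by its mean, removes outlier frames
#' lying beyond the Tukey fences (1.5 interquartile ranges beyond the
#' first/third quartile of the normalized series), and returns the
#' standard deviation of the retained frames. `sigma` is the standard
#' deviation before outlier removal (the sigma used for SNR-surrogate
#' weighting of FC values).
#'
#' @param x Numeric vector of at least 8 frames (or a
#'   [simulate_voxel_timeseries()] result).
#' @param k Fence multiplier (default 1.5).
#' @return A list of class `ts_stats` with `mean`, `sigma`, `rsfa`,
#'   `n_used`.
#' @examples
#' tt <- seq(0, 1799, by = 2.2)
#' s <- 1 + 0.05 * sin(2 * pi * 0.1 * tt)
#' rsfa(s)$rsfa  # close to 0.05 / sqrt(2)
#' @export
rsfa <- function(x, k = 1.5) {
  if (inherits(x, "voxel_timeseries")) x <- x$values
  stopifnot(length(x) >= 8)
  mu <- mean(x)
  if (mu == 0) stop("zero-mean series cannot be mean-normalized")
  z <- x / mu
  q <- stats::quantile(z, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  keep <- z >= q[1] - k * iqr & z <= q[2] + k * iqr
  structure(list(mean = mu, sigma = stats::sd(z), rsfa = stats::sd(z[keep]),
                 n_used = sum(keep)),
            class = "ts_stats")
}

#' @export
print.ts_stats <- function(x, ...) {
  cat(sprintf("mean %.4g, sigma %.4g, RSFA %.4g (%d frames retained)\n",
              x$mean, x$sigma, x$rsfa, x$n_used))
  invisible(x)
}

# normalized cross-correlation of two equal-length series at lags
# -max_lag..max_lag (ccf convention: full-series means and variances,
# 1/n normalization); positive lag means b lags behind a.
cross_corr_lags <- function(a, b, max_lag) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  va <- sqrt(mean(a^2)); vb <- sqrt(mean(b^2))
  if (va == 0 || vb == 0) return(NULL)
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) sum(a[seq_len(n - l)] * b[seq_len(n - l) + l])
    else sum(a[seq_len(n + l) - l] * b[seq_len(n + l)])
  }, 0) / (n * va * vb)
  list(lags = lags, r = r)
}

#' Extremum cross-correlation functional connectivity
#'
#' Computes the normalized cross-correlation between two voxel time
#' series over lags up to `max_lag` frames and returns the signed
#' extremum: the maximum if the largest-magnitude extremum is positive,
#' the minimum if it is negative (ties prefer the positive extremum).
#' This lag-tolerant definition allows simulated correlation values to be
#' compared directly with measured ones without modelling transit lags.
#'
#' @param a,b Equal-length numeric vectors (or `voxel_timeseries`).
#' @param max_lag Maximum lag in frames (default 5, i.e. 11 s at TR
#'   2.2 s, covering a full 0.1 Hz period); must be below length/4.
#' @return A list of class `fc_record` with `r`, `lag`, and `defined`
#'   (`FALSE` for zero-variance input, with `r = NA`).
#' @export
cross_corr_fc <- function(a, b, max_lag = 5) {
  if (inherits(a, "voxel_timeseries")) a <- a$values
  if (inherits(b, "voxel_timeseries")) b <- b$values
  stopifnot(length(a) == length(b), max_lag >= 0,
            max_lag < length(a) / 4)
  cc <- cross_corr_lags(a, b, max_lag)
  if (is.null(cc))
    return(structure(list(r = NA_real_, lag = NA_integer_, defined = FALSE),
                     class = "fc_record"))
  i_max <- which.max(cc$r); i_min <- which.min(cc$r)
  i <- if (cc$r[i_max] >= -cc$r[i_min]) i_max else i_min
  structure(list(r = cc$r[i], lag = cc$lags[i], defined = TRUE),
            class = "fc_record")
}

#' @export
print.fc_record <- function(x, ...) {
  if (!x$defined) cat("FC undefined (zero-variance input)\n")
  else cat(sprintf("FC r = %.4f at lag %d\n", x$r, x$lag))
  invisible(x)
}

#' SNR-surrogate weighting of FC values
#'
#' Noiseless simulated time courses have effectively infinite SNR; to
#' compare them with noisy measurements, each cross-correlation value is
#' multiplied by the temporal standard deviation (sigma) of the simulated
#' target voxel, a surrogate for its SNR. The default uses the target
#' voxel's sigma; `method = "geometric"` uses `sqrt(sigma_i * sigma_j)`.
#'
#' @param r Cross-correlation value(s).
#' @param sigma_i,sigma_j Sigmas of the two voxels (from [rsfa()]).
#' @param method `"target"` (default) or `"geometric"`.
#' @return Weighted value(s); the sign of `r` is preserved.
#' @export
sigma_weight <- function(r, sigma_i, sigma_j, method = c("target", "geometric")) {
  method <- match.arg(method)
  if (method == "target") r * sigma_j else r * sqrt(sigma_i * sigma_j)
}

# vectorized all-pairs extremum cross-correlation on a frames-by-voxels
# matrix; returns r and lag matrices (upper triangle meaningful)
pairwise_xcorr <- function(m, max_lag) {
  n <- nrow(m)
  N <- ncol(m)
  mc <- sweep(m, 2, colMeans(m))
  sds <- sqrt(colMeans(mc^2))
  best_r <- matrix(-Inf, N, N)
  best_l <- matrix(0L, N, N)
  worst_r <- matrix(Inf, N, N)
  worst_l <- matrix(0L, N, N)
  for (l in 0:max_lag) {
    # r_ij at lag l: series j delayed by l relative to i
    cc <- crossprod(mc[seq_len(n - l), , drop = FALSE],
                    mc[seq_len(n - l) + l, , drop = FALSE]) /
      (n * outer(sds, sds))
    for (sgn in if (l == 0) 1 else c(1, -1)) {
      r <- if (sgn == 1) cc else t(cc)
      upd <- r > best_r
      best_r[upd] <- r[upd]; best_l[upd] <- sgn * l
      upd <- r < worst_r
      worst_r[upd] <- r[upd]; worst_l[upd] <- sgn * l
    }
  }
  pick_max <- best_r >= -worst_r
  r <- ifelse(pick_max, best_r, worst_r)
  lag <- ifelse(pick_max, best_l, worst_l)
  list(r = r, lag = lag, sigma = sds)
}

#' Pairwise FC table between voxel groups
#'
#' Computes the extremum cross-correlation for every unordered voxel pair
#' within and between the supplied masks, classed by the mask pair
#' (`AA`, `AV`, `VV` for artery/vein masks; otherwise `name1-name2`).
#' Sigma-weighted values use the target (second) voxel's sigma.
#'
#' @param run A `simulated_run`, a 4D array, or a frames-by-voxels
#'   matrix with voxel ids as column names.
#' @param masks Named list of voxel selections (logical 3D arrays or
#'   integer vectors); typically `list(artery = ..., vein = ...)` or
#'   vessel and perivascular-shell masks.
#' @param max_lag Maximum lag in frames.
#' @param between Optional 2-column matrix or list of mask-name pairs to
#'   restrict which combinations are tabulated; default all (within and
#'   between).
#' @return A data frame with columns `i`, `j` (voxel ids), `class`, `r`,
#'   `lag`, `sigma_i`, `sigma_j`, `weighted`.
#' @export
pairwise_fc_table <- function(run, masks, max_lag = 5, between = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1, !is.null(names(masks)))
  if (any(vapply(masks, function(m) sum(m != 0), 0) == 0))
    stop("all masks must be non-empty")
  sel <- lapply(masks, function(m) if (is.logical(m)) which(m) else
    if (is.array(m)) which(m != 0) else m)
  if (all(c("artery", "vein") %in% names(sel))) {
    ov <- intersect(sel$artery, sel$vein)
    if (length(ov)) {
      warning(length(ov), " voxel(s) carry both labels; classed as vein")
      sel$artery <- setdiff(sel$artery, ov)
      if (!length(sel$artery)) sel$artery <- NULL
    }
  }
  if (length(sel) > 1) {
    for (i in seq_along(sel)[-1]) {
      ov <- intersect(sel[[i]], unlist(sel[seq_len(i - 1)]))
      if (length(ov))
        warning("masks overlap in ", length(ov),
                " voxel(s); pairs are classed by each mask separately")
    }
  }
  all_idx <- sort(unique(unlist(sel)))
  m <- if (is.matrix(run)) run[, as.character(all_idx), drop = FALSE]
       else run_series_matrix(run, all_idx)
  px <- pairwise_xcorr(m, max_lag)
  col_of <- stats::setNames(seq_along(all_idx), as.character(all_idx))
  abbrev <- function(nm) {
    map <- c(artery = "A", vein = "V")
    if (all(nm %in% names(map))) paste0(map[nm[1]], map[nm[2]])
    else paste(nm, collapse = "-")
  }
  combos <- if (is.null(between)) {
    nm <- names(masks)
    cb <- expand.grid(a = seq_along(nm), b = seq_along(nm))
    cb <- cb[cb$a <= cb$b, , drop = FALSE]
    cbind(nm[cb$a], nm[cb$b])
  } else if (is.list(between)) do.call(rbind, between) else between
  rows <- list()
  for (k in seq_len(nrow(combos))) {
    na <- combos[k, 1]; nb <- combos[k, 2]
    ia <- sel[[na]]; ib <- sel[[nb]]
    pr <- if (identical(na, nb)) {
      if (length(ia) < 2) next
      t(utils::combn(ia, 2))
    } else as.matrix(expand.grid(i = ia, j = ib))
    pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
    if (!nrow(pr)) next
    ci <- col_of[as.character(pr[, 1])]
    cj <- col_of[as.character(pr[, 2])]
    lin <- cbind(ci, cj)
    r <- px$r[lin]; lag <- px$lag[lin]
    si <- px$sigma[ci]; sj <- px$sigma[cj]
    rows[[length(rows) + 1]] <- data.frame(
      i = pr[, 1], j = pr[, 2],
      class = abbrev(sort(c(na, nb))),
      r = r, lag = lag, sigma_i = si, sigma_j = sj,
      weighted = sigma_weight(r, si, sj), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned regression of measured against predicted values
#'
#' Sorts the pairs by the predicted (simulated) value, groups them into
#' consecutive fixed-count bins (the remainder after the last full bin is
#' dropped), averages predicted and measured values within each bin, and
#' fits an ordinary least-squares line through the bin means. The R
#' squared of that fit quantifies prediction quality. Bin sizes follow
#' the relative abundance of pairs (e.g. 100 for arterial-arterial, 1000
#' for arterial-venous, 10000 for venous-venous tables).
#'
#' @param sim Predicted values (the independent axis).
#' @param exp Measured values, same length.
#' @param bin_size Pairs per bin; at least two full bins are required.
#' @return An object of class `binned_fit` with `slope`, `intercept`,
#'   `r_squared`, `n_bins`, `bin_size`, `bins` (data frame of bin means)
#'   and the underlying `lm` fit. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @examples
#' x <- runif(500); fit <- binned_regression(x, 2 * x + 1, bin_size = 50)
#' coef(fit); fit$r_squared
#' @export
binned_regression <- function(sim, exp, bin_size) {
  stopifnot(length(sim) == length(exp), bin_size >= 1)
  n <- length(sim)
  n_bins <- n %/% bin_size
  if (n_bins < 2)
    stop("need at least ", 2 * bin_size, " pairs for bin_size ", bin_size,
         " (got ", n, ")")
  ord <- order(sim)
  keep <- ord[seq_len(n_bins * bin_size)]
  g <- rep(seq_len(n_bins), each = bin_size)
  bins <- data.frame(sim = tapply(sim[keep], g, mean),
                     exp = tapply(exp[keep], g, mean))
  fit <- stats::lm(exp ~ sim, data = bins)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((bins$exp - mean(bins$exp))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_bins = n_bins, bin_size = bin_size, bins = bins,
                 fit = fit),
            class = "binned_fit")
}

#' @export
print.binned_fit <- function(x, ...) {
  cat(sprintf("binned regression: %d bins of %d pairs\n", x$n_bins,
              x$bin_size))
  cat(sprintf("  slope %.4g, intercept %.4g, R^2 %.4f\n", x$slope,
              x$intercept, x$r_squared))
  invisible(x)
}

#' @export
summary.binned_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.binned_fit <- function(object, ...) stats::coef(object$fit)

#' @export
predict.binned_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit,
                      newdata = data.frame(sim = newdata), ...)
}

#' @export
residuals.binned_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.binned_fit <- function(x, ...) {
  graphics::plot(x$bins$sim, x$bins$exp, xlab = "predicted (bin mean)",
                 ylab = "measured (bin mean)", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}
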