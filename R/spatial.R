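#' Pairwise Pearson correlations of a binary raster
#'
#' Pearson correlation coefficient between the activity series of every
#' neuron pair. Constant columns have undefined correlations; their pairs
#' are excluded and counted.
#'
#' @param raster binary (or numeric) matrix, time x neuron; `T >= 3`.
#' @param positions optional positions table; when given, a `distance_um`
#'   column is added.
#' @return data.frame with columns `i`, `j` (0-based ids, i < j), `value`
#'   (Pearson r) and optionally `distance_um`; attribute `n_excluded` counts
#'   pairs dropped for zero variance.
#' @export
pairwise_pearson <- function(raster, positions = NULL) {
  raster <- as.matrix(raster)
  if (nrow(raster) < 3L) stop_invalid("need at least 3 timepoints")
  n <- ncol(raster)
  ids <- if (!is.null(positions)) positions$neuron_id else seq_len(n) - 1L
  cm <- suppressWarnings(cor(raster))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  val <- cm[pairs]
  out <- data.frame(i = ids[pairs[, 1L]], j = ids[pairs[, 2L]], value = val)
  if (!is.null(positions)) {
    if (nrow(positions) != n) stop_invalid("positions inconsistent with raster")
    D <- pair_distance_matrix(positions)
    out$distance_um <- D[pairs]
  }
  keep <- is.finite(out$value)
  n_excluded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Bin per-pair values by inter-neuron distance
#'
#' Logarithmically spaced distance bins between `d_min` and `d_max_bin`;
#' the unweighted mean of the per-pair values is computed for each bin.
#' Bins with fewer than `min_pairs_per_bin` pairs keep their count but have
#' an undefined mean. Pairs outside `[d_min, d_max_bin]` are dropped.
#'
#' @param values data.frame with columns `value` and `distance_um` (e.g.
#'   from [pairwise_pearson()]), or a numeric vector paired with `distances`.
#' @param distances numeric vector of distances when `values` is a vector.
#' @param n_bins number of bins (>= 2).
#' @param d_min lower edge, micrometres (> 0).
#' @param d_max_bin upper edge; defaults to the maximum distance present.
#' @param min_pairs_per_bin minimum pair count for a defined bin mean.
#' @return object of class `distance_curve`: data.frame with `bin_lo`,
#'   `bin_hi`, `bin_center` (geometric mean of the edges), `mean_value`,
#'   `pair_count`.
#' @export
bin_by_distance <- function(values, distances = NULL, n_bins = 20L,
                            d_min = 10, d_max_bin = NULL,
                            min_pairs_per_bin = 50L) {
  if (is.data.frame(values)) {
    stopifnot(all(c("value", "distance_um") %in% names(values)))
    distances <- values$distance_um
    values <- values$value
  }
  if (length(values) != length(distances)) {
    stop_invalid("values and distances must have equal length")
  }
  if (n_bins < 2L) stop_invalid("n_bins must be >= 2")
  if (d_min <= 0) stop_invalid("d_min must be positive (log-spaced bins)")
  ok <- is.finite(values) & is.finite(distances)
  values <- values[ok]; distances <- distances[ok]
  if (is.null(d_max_bin)) d_max_bin <- max(distances)
  if (d_max_bin <= d_min) stop_invalid("d_max_bin must exceed d_min")
  edges <- exp(seq(log(d_min), log(d_max_bin), length.out = n_bins + 1L))
  inb <- distances >= d_min & distances <= d_max_bin
  values <- values[inb]; distances <- distances[inb]
  bin <- findInterval(distances, edges, rightmost.closed = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  sums <- vapply(seq_len(n_bins),
                 function(b) sum(values[bin == b]), numeric(1))
  mean_value <- ifelse(cnt >= min_pairs_per_bin & cnt > 0L, sums / cnt,
                       NA_real_)
  out <- data.frame(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L],
                    bin_center = sqrt(edges[-(n_bins + 1L)] * edges[-1L]),
                    mean_value = mean_value, pair_count = cnt)
  class(out) <- c("distance_curve", "data.frame")
  out
}

#' Fit an exponential decay with offset to a distance-binned curve
#'
#' Nonlinear least squares fit of `C(d) = C_inf + (C0 - C_inf) exp(-d /
#' lambda)` to the occupied bin means, via bounded Levenberg-Marquardt.
#' Starting values: `C0` = first occupied mean, `C_inf` = last occupied
#' mean, `lambda` = one third of the occupied span; `lambda` is constrained
#' to `(1, 10 * span]` micrometres.
#'
#' @param curve a `distance_curve` from [bin_by_distance()].
#' @param weights optional per-bin weights (e.g. pair counts); default
#'   unweighted.
#' @return object of class `decay_fit`: list with `c0`, `c_inf`, `lam`
#'   (micrometres), `cov` (parameter covariance), `rss`, `converged`,
#'   `unidentifiable`, `n_bins_used`.
#' @export
fit_exponential_decay <- function(curve, weights = NULL) {
  occ <- is.finite(curve$mean_value)
  d <- curve$bin_center[occ]
  y <- curve$mean_value[occ]
  if (length(d) < 4L) {
    stop_invalid("need at least 4 occupied bins to fit the decay (have ",
                 length(d), ")")
  }
  if (sd(y) < 1e-12) {
    fit <- list(c0 = y[1L], c_inf = y[1L], lam = NA_real_, cov = NULL,
                rss = 0, converged = FALSE, unidentifiable = TRUE,
                n_bins_used = length(d))
    class(fit) <- "decay_fit"
    return(fit)
  }
  span <- max(d) - min(d)
  start <- list(c0 = y[1L], c_inf = y[length(y)], lam = span / 3)
  w <- if (is.null(weights)) rep(1, length(d)) else weights[occ]
  fit <- minpack.lm::nlsLM(
    y ~ c_inf + (c0 - c_inf) * exp(-d / lam),
    data = data.frame(d = d, y = y), start = start, weights = w,
    lower = c(c0 = -Inf, c_inf = -Inf, lam = 1),
    upper = c(c0 = Inf, c_inf = Inf, lam = 10 * span),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- stats::coef(fit)
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  out <- list(c0 = unname(est["c0"]), c_inf = unname(est["c_inf"]),
              lam = unname(est["lam"]), cov = cv,
              rss = sum(stats::residuals(fit)^2),
              converged = fit$convInfo$isConv, unidentifiable = FALSE,
              n_bins_used = length(d))
  if (out$c0 < out$c_inf) out$flagged_inverted <- TRUE
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$unidentifiable) {
    cat("Exponential decay fit: unidentifiable (flat curve)\n")
  } else {
    cat(sprintf(
      "Exponential decay fit: C0 = %.4g, Cinf = %.4g, lambda = %.4g um (%s)\n",
      x$c0, x$c_inf, x$lam,
      if (isTRUE(x$converged)) "converged" else "not converged"))
  }
  invisible(x)
}

#' Normalized decay curve
#'
#' Rescales the occupied bin means to `(C(d) - C_inf) / (C0 - C_inf)`, which
#' equals `exp(-d / lambda)` for the fitted model; puts curves from
#' different datasets and conditions on a common 0-1 scale.
#'
#' @param curve a `distance_curve`.
#' @param fit the `decay_fit` for that curve.
#' @return a `distance_curve` with `mean_value` replaced by the normalized
#'   values.
#' @export
normalized_curve <- function(curve, fit) {
  stopifnot(inherits(fit, "decay_fit"))
  if (isTRUE(fit$unidentifiable) || !isTRUE(fit$converged)) {
    stop_invalid("fit did not converge; cannot normalize")
  }
  denom <- fit$c0 - fit$c_inf
  if (abs(denom) < 1e-12) {
    stop_invalid("C0 = Cinf: normalization is unidentifiable")
  }
  curve$mean_value <- (curve$mean_value - fit$c_inf) / denom
  curve
}

#' Effective information length of a fitted decay
#'
#' Normalized area under the fitted decay between `d0` and `dmax`:
#' `lambda_eff = (1 / C0) * integral over [d0, dmax] of C(d) dd`. A robust
#' summary of spatial extent for slowly decaying quantities whose fitted
#' `lambda` may exceed the field of view. Computed by numeric quadrature and
#' verified against the closed form
#' `(1 / C0) * ( C_inf (dmax - d0) + (C0 - C_inf) lambda (e^{-d0/lambda} -
#' e^{-dmax/lambda}) )` to 1e-9.
#'
#' @param fit a converged `decay_fit` with `c0 > 0`.
#' @param d0 lower distance, micrometres (default 100).
#' @param dmax upper distance, micrometres (default 1500).
#' @return object of class `effective_length`: list with `lambda_eff`, `d0`,
#'   `dmax`.
#' @export
effective_length <- function(fit, d0 = 100, dmax = 1500) {
  stopifnot(inherits(fit, "decay_fit"))
  if (isTRUE(fit$unidentifiable)) stop_invalid("fit is unidentifiable")
  if (d0 >= dmax) stop_invalid("d0 must be smaller than dmax")
  if (!is.finite(fit$c0) || fit$c0 <= 0) {
    stop_invalid("lambda_eff undefined: fitted C0 must be positive")
  }
  cd <- function(d) fit$c_inf + (fit$c0 - fit$c_inf) * exp(-d / fit$lam)
  quad <- integrate(cd, d0, dmax, rel.tol = 1e-12, abs.tol = 1e-12)$value
  closed <- fit$c_inf * (dmax - d0) +
    (fit$c0 - fit$c_inf) * fit$lam * (exp(-d0 / fit$lam) - exp(-dmax / fit$lam))
  if (abs(quad - closed) > 1e-9 * max(1, abs(closed))) {
    stop_invalid("internal error: quadrature and closed form disagree")
  }
  structure(list(lambda_eff = quad / fit$c0, d0 = d0, dmax = dmax),
            class = "effective_length")
}

#' @export
print.effective_length <- function(x, ...) {
  cat(sprintf("Effective information length: %.4g um over [%g, %g] um\n",
              x$lambda_eff, x$d0, x$dmax))
  invisible(x)
}

#' Model-free effective length from binned values
#'
#' Trapezoidal integration of the occupied bin means over `[d0, dmax]`,
#' normalized by the first included bin mean, without fitting a decay
#' model. Bin means are extended as constants from the nearest occupied bin
#' to the window boundaries. Always defined whenever at least two occupied
#' bins fall in the window and the first bin mean is positive — the robust
#' fallback when a noisy curve cannot support the exponential fit.
#'
#' @param curve a `distance_curve` from [bin_by_distance()].
#' @param d0,dmax integration window, micrometres.
#' @return object of class `effective_length` with `lambda_eff`, `d0`,
#'   `dmax` and `method = "trapezoid"`.
#' @export
effective_length_raw <- function(curve, d0 = 100, dmax = 1500) {
  if (d0 >= dmax) stop_invalid("d0 must be smaller than dmax")
  occ <- is.finite(curve$mean_value)
  d <- curve$bin_center[occ]
  y <- curve$mean_value[occ]
  keep <- d >= d0 & d <= dmax
  d <- d[keep]; y <- y[keep]
  if (length(d) < 2L) {
    stop_invalid("need at least 2 occupied bins inside [d0, dmax]")
  }
  if (y[1L] <= 0) {
    stop_invalid("lambda_eff undefined: first bin mean must be positive")
  }
  dd <- c(d0, d, dmax)
  yy <- c(y[1L], y, y[length(y)])
  area <- sum(diff(dd) * (head(yy, -1L) + yy[-1L]) / 2)
  structure(list(lambda_eff = area / y[1L], d0 = d0, dmax = dmax,
                 method = "trapezoid"),
            class = "effective_length")
}

#' Distance curve, fit and lengths for one per-pair metric
#'
#' Convenience wrapper running [bin_by_distance()],
#' [fit_exponential_decay()] and [effective_length()] on one per-pair scalar
#' (Pearson r, Z-scored synergy, Z-scored redundancy, ...). The same path
#' applies unchanged to any per-pair value with distances.
#'
#' @param pair_values data.frame with `value` and `distance_um` columns.
#' @param n_bins,d_min,d_max_bin,min_pairs_per_bin passed to
#'   [bin_by_distance()].
#' @param d0,dmax passed to [effective_length()].
#' @return list with `curve`, `fit`, `normalized`, `lambda`, `lambda_eff`.
#' @export
spatial_profile <- function(pair_values, n_bins = 20L, d_min = 10,
                            d_max_bin = NULL, min_pairs_per_bin = 50L,
                            d0 = 100, dmax = 1500) {
  curve <- bin_by_distance(pair_values, n_bins = n_bins, d_min = d_min,
                           d_max_bin = d_max_bin,
                           min_pairs_per_bin = min_pairs_per_bin)
  fit <- fit_exponential_decay(curve)
  # undefined lambda_eff (c0 <= 0, unconverged fit) is flagged, not fatal:
  # Z-scored curves from short recordings can be too noisy to normalize
  eff <- tryCatch(effective_length(fit, d0 = d0, dmax = dmax),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    list(lambda_eff = NA_real_)
                  })
  norm <- tryCatch(normalized_curve(curve, fit), error = function(e) NULL)
  list(curve = curve, fit = fit, normalized = norm,
       lambda = fit$lam, lambda_eff = eff$lambda_eff)
}
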