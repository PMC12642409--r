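# Pair-state coding used throughout: a joint state (x, y) of two binary
# neurons is coded as s = x + 2*y in {0, 1, 2, 3}; a lagged 4-tuple
# (x_t, y_t, x_{t+tau}, y_{t+tau}) as u + 4*v with u = past, v = future.

#' Empirical joint distribution of a neuron pair at lag tau
#'
#' Relative frequencies of the `T - tau` aligned 4-tuples
#' `(x_t, y_t, x_{t+tau}, y_{t+tau})` over the 16 joint binary outcomes.
#'
#' @param x,y binary vectors of equal length `T`.
#' @param tau time lag in frames (>= 1, < T).
#' @return object of class `pair_joint`: list with `probs` (4x4 matrix,
#'   rows = past pair state `x + 2y`, columns = future pair state),
#'   `sample_count` (= T - tau) and `tau`.
#' @export
estimate_pair_joint <- function(x, y, tau = 1L) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  tt <- length(x)
  if (tau < 1L) stop_invalid("tau must be >= 1")
  if (tt - tau < 1L) stop_invalid("tau must be smaller than the series length")
  if (!all(x %in% c(0L, 1L)) || !all(y %in% c(0L, 1L))) {
    stop_invalid("x and y must be binary (0/1)")
  }
  idx <- seq_len(tt - tau)
  u <- x[idx] + 2L * y[idx]
  v <- x[idx + tau] + 2L * y[idx + tau]
  counts <- tabulate(u + 4L * v + 1L, nbins = 16L)
  pair_joint(matrix(counts / (tt - tau), 4L, 4L), sample_count = tt - tau,
             tau = tau)
}

#' Construct a pair joint distribution from a 4x4 probability table
#'
#' @param probs 4x4 matrix, rows = past pair state (coded `x + 2y`),
#'   columns = future pair state; must be nonnegative and sum to 1.
#' @param sample_count number of samples behind the table (NA for analytic
#'   tables).
#' @param tau lag in frames.
#' @return a `pair_joint` object.
#' @export
pair_joint <- function(probs, sample_count = NA_integer_, tau = 1L) {
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(4L, 4L))) stop_invalid("probs must be 4x4")
  if (any(probs < -1e-12)) stop_invalid("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-6) {
    stop_invalid("probabilities must sum to 1 (got ", sum(probs), ")")
  }
  dimnames(probs) <- list(past = c("00", "10", "01", "11"),
                          future = c("00", "10", "01", "11"))
  structure(list(probs = probs, sample_count = sample_count, tau = tau),
            class = "pair_joint")
}

# Mutual information (bits) of a joint probability matrix, 0*log0 = 0.
# Lean internal kernel; reused heavily by the null-model calibration.
.mi_bits <- function(p) {
  pu <- rowSums(p)
  pv <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / outer(pu, pv)[pos]))
}

#' Mutual information of a discrete joint distribution
#'
#' `I(U; V) = sum_u sum_v p(u, v) log2( p(u, v) / (p(u) p(v)) )` with the
#' convention `0 log 0 = 0`; marginals are computed from the table.
#'
#' @param joint numeric matrix, `p[u, v]`; must sum to 1 within 1e-6.
#' @return mutual information in bits.
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < -1e-12)) stop_invalid("joint has negative entries")
  if (abs(sum(joint) - 1) > 1e-6) {
    stop_invalid("joint is not normalized (sums to ", sum(joint), ")")
  }
  .mi_bits(joint)
}

#' Time-delayed mutual information of a neuron pair
#'
#' `TDMI = I(X_t, Y_t ; X_{t+tau}, Y_{t+tau})`, the total information the
#' pair's present carries about its joint future; between 0 and 2 bits for
#' binary pairs.
#'
#' @param joint a `pair_joint` object.
#' @return TDMI in bits.
#' @export
tdmi <- function(joint) {
  stopifnot(inherits(joint, "pair_joint"))
  mutual_information(joint$probs)
}

# PID of a 4x4 past/future pair table; lean internal kernel.
# Rows of p are past states coded x + 2y, so x = 0 for rows 1, 3.
.pid_bits <- function(p, tol = 1e-12) {
  td <- .mi_bits(p)
  px <- rbind(p[1L, ] + p[3L, ], p[2L, ] + p[4L, ])  # I(X_t ; future)
  py <- rbind(p[1L, ] + p[2L, ], p[3L, ] + p[4L, ])  # I(Y_t ; future)
  ix <- .mi_bits(px)
  iy <- .mi_bits(py)
  ri <- min(ix, iy)
  comp <- c(tdmi = td, ui_x = ix - ri, ui_y = iy - ri, ri = ri,
            si = td - max(ix, iy))
  comp[comp < 0 & comp > -tol] <- 0
  comp
}

#' Partial information decomposition with MMI redundancy
#'
#' Decomposes the TDMI of a binary neuron pair into unique, redundant and
#' synergistic components using the minimum-mutual-information redundancy
#' measure: `RI = min( I(X_t; future), I(Y_t; future) )`, where "future" is
#' the joint state `(X_{t+tau}, Y_{t+tau})`. The unique components are the
#' single-source informations minus RI (so at least one of them is exactly
#' zero) and synergy is TDMI minus the larger single-source information. All
#' four components are nonnegative and sum to the TDMI.
#'
#' Pairs with a constant series (zero-entropy margin) yield TDMI = 0 and all
#' components 0, with the `degenerate` flag set.
#'
#' @param joint a `pair_joint` object.
#' @return object of class `pid_components`: list with `tdmi`, `ui_x`,
#'   `ui_y`, `ri`, `si` (bits) and `degenerate`.
#' @export
pid_mmi <- function(joint) {
  stopifnot(inherits(joint, "pair_joint"))
  comp <- .pid_bits(joint$probs)
  if (any(comp < 0)) {
    stop_invalid("internal error: negative PID component beyond tolerance")
  }
  structure(list(tdmi = unname(comp["tdmi"]), ui_x = unname(comp["ui_x"]),
                 ui_y = unname(comp["ui_y"]), ri = unname(comp["ri"]),
                 si = unname(comp["si"]),
                 degenerate = comp["tdmi"] < 1e-12),
            class = "pid_components")
}

#' @export
print.pid_components <- function(x, ...) {
  cat(sprintf(
    "PID (MMI): TDMI = %.6g bits | UI(X) %.6g, UI(Y) %.6g, RI %.6g, SI %.6g\n",
    x$tdmi, x$ui_x, x$ui_y, x$ri, x$si))
  invisible(x)
}

#' Pairwise time-delayed PID table for a raster
#'
#' Computes the MMI partial information decomposition at lag `tau` for
#' neuron pairs of a binary raster, together with the inter-neuron distance.
#' Pairs whose series are constant are flagged (`degenerate = TRUE`, all
#' components zero). Pair enumeration can be capped (`max_pairs`, uniform
#' random subsample under `seed`) and pairs closer than
#' `min_pair_distance_um` can be excluded.
#'
#' @param raster binary matrix, time x neuron.
#' @param positions positions table matching the raster columns.
#' @param tau lag in frames (default 1).
#' @param max_pairs cap on the number of pairs analysed.
#' @param min_pair_distance_um exclude pairs closer than this.
#' @param seed seed for the pair subsample.
#' @return data.frame with columns `i`, `j` (0-based neuron ids, i < j),
#'   `distance_um`, `tdmi`, `ui_x`, `ui_y`, `ri`, `si`, `degenerate`.
#' @export
pid_pair_table <- function(raster, positions, tau = 1L, max_pairs = 500000L,
                           min_pair_distance_um = 0, seed = 1L) {
  if (!is_binary_matrix(raster)) stop_invalid("raster must be binary")
  n <- ncol(raster)
  if (nrow(positions) != n) {
    stop_invalid("positions inconsistent with raster columns")
  }
  D <- pair_distance_matrix(positions)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[pairs]
  keep <- d >= min_pair_distance_um
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(pairs) > max_pairs) {
    sel <- with_seed(seed, sample.int(nrow(pairs), max_pairs))
    pairs <- pairs[sel, , drop = FALSE]
    d <- d[sel]
  }
  m <- nrow(pairs)
  out <- data.frame(i = positions$neuron_id[pairs[, 1L]],
                    j = positions$neuron_id[pairs[, 2L]],
                    distance_um = d, tdmi = NA_real_, ui_x = NA_real_,
                    ui_y = NA_real_, ri = NA_real_, si = NA_real_,
                    degenerate = FALSE)
  tt <- nrow(raster)
  idx <- seq_len(tt - tau)
  for (k in seq_len(m)) {
    x <- raster[, pairs[k, 1L]]
    y <- raster[, pairs[k, 2L]]
    u <- x[idx] + 2L * y[idx]
    v <- x[idx + tau] + 2L * y[idx + tau]
    p <- matrix(tabulate(u + 4L * v + 1L, nbins = 16L) / (tt - tau), 4L, 4L)
    comp <- .pid_bits(p)
    out$tdmi[k] <- comp["tdmi"]; out$ui_x[k] <- comp["ui_x"]
    out$ui_y[k] <- comp["ui_y"]; out$ri[k] <- comp["ri"]
    out$si[k] <- comp["si"]
    out$degenerate[k] <- comp["tdmi"] < 1e-12
  }
  out
}
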