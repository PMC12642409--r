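#' Generator parameters for synthetic rasters
#'
#' Bundles the parameters of the dichotomized-Gaussian raster generator. The
#' defaults mirror the scale of mesoscale two-photon recordings: a 3 mm
#' square field of view, sparse activity (5% of frames active per neuron),
#' and an exponential spatial correlation kernel with a nonzero asymptote.
#'
#' @param n_neurons number of neurons.
#' @param n_timepoints number of frames.
#' @param field_size side of the square field of view, in micrometres.
#' @param lambda_true planted spatial correlation length (micrometres).
#' @param c0_true latent pairwise correlation at zero distance (dimensionless).
#' @param c_inf_true latent asymptotic correlation at large distance.
#' @param persistence lag-1 autoregressive coefficient of the latent
#'   dynamics, in `[0, 1)`.
#' @param firing_prob per-frame marginal activation probability, in (0, 1).
#' @param xor_triplets list of integer triples `c(source_a, source_b, target)`
#'   (0-based neuron ids); each target neuron's state at time `t + 1` is set
#'   to the XOR of the two sources at time `t`, a purely synergistic motif.
#' @param xor_flip_prob probability of flipping each XOR target symbol, so
#'   plug-in estimators see all joint states.
#' @param frame_rate_hz acquisition frame rate; metadata only.
#' @param seed integer seed for the generator.
#' @return an object of class `generator_params` (a validated list).
#' @export
generator_params <- function(n_neurons = 200L, n_timepoints = 20000L,
                             field_size = 3000, lambda_true = 600,
                             c0_true = 0.1, c_inf_true = 0.01,
                             persistence = 0.3, firing_prob = 0.05,
                             xor_triplets = list(), xor_flip_prob = 0.05,
                             frame_rate_hz = 7.5, seed = 1L) {
  p <- list(n_neurons = as.integer(n_neurons),
            n_timepoints = as.integer(n_timepoints),
            field_size = field_size, lambda_true = lambda_true,
            c0_true = c0_true, c_inf_true = c_inf_true,
            persistence = persistence, firing_prob = firing_prob,
            xor_triplets = xor_triplets, xor_flip_prob = xor_flip_prob,
            frame_rate_hz = frame_rate_hz, seed = as.integer(seed))
  if (p$n_neurons < 0L) stop_invalid("n_neurons must be non-negative")
  if (p$n_timepoints < 2L) stop_invalid("n_timepoints must be at least 2")
  if (p$field_size <= 0) stop_invalid("field_size must be positive")
  if (p$lambda_true <= 0) stop_invalid("lambda_true must be positive")
  if (p$c0_true >= 1 || p$c0_true < 0) {
    stop_invalid("infeasible correlation target: c0_true = ", p$c0_true,
                 " must lie in [0, 1) for a binary-attainable kernel")
  }
  if (p$c_inf_true < 0 || p$c_inf_true > p$c0_true) {
    stop_invalid("infeasible correlation targets: need 0 <= c_inf_true (",
                 p$c_inf_true, ") <= c0_true (", p$c0_true, ")")
  }
  if (p$persistence < 0 || p$persistence >= 1) {
    stop_invalid("persistence must be in [0, 1)")
  }
  if (p$firing_prob <= 0 || p$firing_prob >= 1) {
    stop_invalid("firing_prob must be in (0, 1)")
  }
  for (tr in p$xor_triplets) {
    if (length(tr) != 3L || anyDuplicated(tr) ||
        any(tr < 0L) || any(tr >= p$n_neurons)) {
      stop_invalid("each xor triplet must be three distinct neuron ids in [0, n_neurons)")
    }
  }
  class(p) <- "generator_params"
  p
}

#' Place neurons uniformly in a square field of view
#'
#' @param n_neurons number of neurons (may be 0).
#' @param field_size side of the square, micrometres.
#' @param seed integer seed.
#' @return data.frame with columns `neuron_id` (0-based, contiguous),
#'   `x_um`, `y_um`.
#' @export
generate_positions <- function(n_neurons, field_size = 3000, seed = 1L) {
  if (n_neurons < 0) stop_invalid("n_neurons must be non-negative")
  if (field_size <= 0) stop_invalid("field_size must be positive")
  with_seed(seed, {
    data.frame(neuron_id = seq_len(n_neurons) - 1L,
               x_um = runif(n_neurons, 0, field_size),
               y_um = runif(n_neurons, 0, field_size))
  })
}

#' Euclidean inter-neuron distance matrix (micrometres)
#' @param positions positions table from [generate_positions()].
#' @return symmetric matrix of distances, ordered by neuron id.
#' @export
pair_distance_matrix <- function(positions) {
  stopifnot(all(c("x_um", "y_um") %in% names(positions)))
  as.matrix(dist(cbind(positions$x_um, positions$y_um)))
}

#' Simulate a spatially correlated binary activity raster
#'
#' Dichotomized-Gaussian construction: a latent zero-mean Gaussian field with
#' unit variances and spatial correlation kernel
#' `c(d) = c_inf_true + (c0_true - c_inf_true) * exp(-d / lambda_true)`
#' evolves under lag-1 autoregressive dynamics with coefficient
#' `persistence`, and is thresholded at the quantile giving marginal
#' activation probability `firing_prob`. The kernel matrix is projected to
#' the nearest positive-semidefinite matrix (eigenvalue clipping at zero,
#' then rescaling to unit diagonal) before sampling, since exponential
#' kernels with an additive offset on arbitrary point sets can be
#' indefinite. Binary correlations are a monotone (approximately linear at
#' these magnitudes) transform of the latent correlations, so the planted
#' exponential decay shape and its length scale carry over to the raster.
#'
#' XOR triplets overwrite the thresholded value of each target neuron:
#' `target[t + 1] = xor(source_a[t], source_b[t])`, each symbol then flipped
#' with probability `xor_flip_prob`.
#'
#' @param positions positions table consistent with `params$n_neurons`.
#' @param params a [generator_params()] object.
#' @return integer matrix `n_timepoints x n_neurons` with entries in {0, 1};
#'   column names are the neuron ids.
#' @export
simulate_raster <- function(positions, params) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_neurons
  if (nrow(positions) != n) {
    stop_invalid("positions (", nrow(positions),
                 " rows) inconsistent with params$n_neurons (", n, ")")
  }
  tt <- params$n_timepoints
  with_seed(params$seed, {
    D <- pair_distance_matrix(positions)
    C <- params$c_inf_true +
      (params$c0_true - params$c_inf_true) * exp(-D / params$lambda_true)
    diag(C) <- 1
    ee <- eigen(C, symmetric = TRUE)
    vals <- pmax(ee$values, 0)
    A <- ee$vectors %*% (sqrt(vals) * t(ee$vectors))
    # restore unit marginal variance after clipping
    v <- rowSums(A^2)
    A <- A / sqrt(v)

    phi <- params$persistence
    innov <- matrix(rnorm(tt * n), tt, n) %*% t(A)
    Z <- matrix(0, tt, n)
    Z[1L, ] <- innov[1L, ]
    if (tt > 1L) {
      s <- sqrt(1 - phi^2)
      for (t in 2:tt) Z[t, ] <- phi * Z[t - 1L, ] + s * innov[t, ]
    }
    R <- matrix(0L, tt, n)
    R[Z > qnorm(1 - params$firing_prob)] <- 1L

    for (tr in params$xor_triplets) {
      a <- tr[1L] + 1L; b <- tr[2L] + 1L; g <- tr[3L] + 1L
      xorv <- as.integer(xor(R[1:(tt - 1L), a] == 1L, R[1:(tt - 1L), b] == 1L))
      if (params$xor_flip_prob > 0) {
        flips <- rbinom(tt - 1L, 1L, params$xor_flip_prob)
        xorv <- as.integer(xor(xorv == 1L, flips == 1L))
      }
      R[2:tt, g] <- xorv
    }
    colnames(R) <- positions$neuron_id
    R
  })
}

#' Synthetic deconvolved traces from a known binary raster
#'
#' Active frames get value `amplitude` plus Gaussian noise, quiet frames
#' noise only; values are clipped at zero (deconvolved rates are
#' nonnegative). A round-trip fixture for the HMM binarization stage.
#'
#' @param raster binary matrix (time x neuron).
#' @param amplitude mean trace value in the active state (must be > 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return numeric matrix, same shape and column names as `raster`.
#' @export
traces_from_raster <- function(raster, amplitude = 5, noise_sd = 0.5,
                               seed = 1L) {
  if (amplitude <= 0) stop_invalid("amplitude must be positive")
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  if (!is_binary_matrix(raster)) stop_invalid("raster must be binary")
  with_seed(seed, {
    tr <- amplitude * raster
    if (noise_sd > 0) {
      tr <- tr + matrix(rnorm(length(raster), 0, noise_sd),
                        nrow(raster), ncol(raster))
    }
    tr[tr < 0] <- 0
    dimnames(tr) <- dimnames(raster)
    tr
  })
}
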