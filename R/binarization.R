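#' Fit a two-state Gaussian hidden Markov model to a deconvolved trace
#'
#' Expectation-maximization fit of a 2-state HMM with Gaussian emissions to a
#' single continuous nonnegative trace, used to discretize each neuron into
#' Active (1) / Quiet (0) frames without an arbitrary per-neuron threshold.
#' States are relabelled so that state 1 is the state with the larger
#' emission mean. Initialization is deterministic and scale-adaptive:
#' emission means at the 20th and 95th percentiles of the trace, self-
#' transition probability 0.95.
#'
#' @param trace numeric vector (length >= 10, finite values).
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood improvement (nats).
#' @param seed accepted for interface symmetry; the fit is deterministic.
#' @return an object of class `hmm_model`: list with `means`, `sds` (quiet
#'   state first), `transition` (2x2 row-stochastic), `initial`,
#'   `log_likelihood` (nats), `converged`, `degenerate`, `n_iter`.
#' @export
fit_hmm <- function(trace, max_iter = 200L, tol = 1e-4, seed = NULL) {
  trace <- as.numeric(trace)
  if (length(trace) < 10L) stop_invalid("trace must have length >= 10")
  if (any(!is.finite(trace))) stop_invalid("trace contains non-finite values")

  if (sd(trace) < 1e-12) {
    model <- list(means = c(trace[1L], trace[1L]), sds = c(1, 1),
                  transition = matrix(0.5, 2, 2), initial = c(0.5, 0.5),
                  log_likelihood = NA_real_, converged = FALSE,
                  degenerate = TRUE, n_iter = 0L)
    class(model) <- "hmm_model"
    return(model)
  }

  mu <- unname(quantile(trace, c(0.20, 0.99)))
  if (diff(mu) < 1e-8) mu[2L] <- mu[1L] + sd(trace)
  sig <- rep(max(sd(trace) / 2, 1e-6), 2L)
  # emission sds are floored at a fraction of the overall spread: deconvolved
  # traces have a point mass at zero (clipped noise), and an unfloored
  # Gaussian EM collapses a state onto it (unbounded likelihood)
  sd_floor <- max(1e-6, 0.1 * sd(trace))
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)

  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fb <- forward_backward(trace, mu, sig, P, pi0)
    ll <- fb$log_likelihood
    if (is.finite(ll) && ll - ll_prev < tol && iter > 1L) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
    g <- fb$gamma             # T x 2 posterior marginals
    xi <- fb$xi_sum           # 2 x 2 expected transition counts
    pi0 <- g[1L, ] / sum(g[1L, ])
    P <- xi / rowSums(xi)
    w <- colSums(g)
    mu <- colSums(g * trace) / w
    sig <- sqrt(colSums(g * (outer(trace, mu, "-")^2)) / w)
    sig <- pmax(sig, sd_floor)
    if (iter >= max_iter) break
  }

  # state 2 = Active = larger emission mean
  if (mu[1L] > mu[2L]) {
    ord <- c(2L, 1L)
    mu <- mu[ord]; sig <- sig[ord]
    P <- P[ord, ord]; pi0 <- pi0[ord]
  }
  model <- list(means = mu, sds = sig, transition = P, initial = pi0,
                log_likelihood = ll_prev, converged = converged,
                degenerate = FALSE, n_iter = iter)
  class(model) <- "hmm_model"
  model
}

# Scaled forward-backward for a 2-state Gaussian HMM.
# Returns per-timepoint posterior marginals (gamma), expected transition
# counts (xi_sum) and the log-likelihood in nats.
forward_backward <- function(trace, mu, sig, P, pi0) {
  tt <- length(trace)
  B <- cbind(dnorm(trace, mu[1L], sig[1L]), dnorm(trace, mu[2L], sig[2L]))
  B[B < 1e-300] <- 1e-300
  alpha <- matrix(0, tt, 2L)
  cvec <- numeric(tt)
  a <- pi0 * B[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  for (t in 2:tt) {
    a <- (alpha[t - 1L, ] %*% P) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, tt, 2L)
  beta[tt, ] <- 1
  for (t in (tt - 1L):1L) {
    b <- P %*% (B[t + 1L, ] * beta[t + 1L, ])
    beta[t, ] <- b / cvec[t + 1L]
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  xi_sum <- matrix(0, 2L, 2L)
  for (t in 1:(tt - 1L)) {
    x <- (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * P / cvec[t + 1L]
    xi_sum <- xi_sum + x
  }
  list(gamma = g, xi_sum = xi_sum, log_likelihood = sum(log(cvec)))
}

#' Decode per-timepoint most-probable states
#'
#' Computes the forward-backward posterior marginal of the Active state at
#' each timepoint and returns its argmax — the most probable state at each
#' time point individually (not the single best path).
#'
#' @param trace numeric vector on the scale the model was fitted on.
#' @param model an `hmm_model` from [fit_hmm()].
#' @return integer vector of {0, 1}, 1 = Active.
#' @export
decode_states <- function(trace, model) {
  stopifnot(inherits(model, "hmm_model"))
  trace <- as.numeric(trace)
  if (length(trace) < 1L) stop_invalid("empty trace")
  if (any(!is.finite(trace))) stop_invalid("trace contains non-finite values")
  if (isTRUE(model$degenerate)) return(rep(0L, length(trace)))
  fb <- forward_backward(trace, model$means, model$sds,
                         model$transition, model$initial)
  as.integer(fb$gamma[, 2L] > 0.5)
}

#' Posterior marginals of the Active state
#'
#' @inheritParams decode_states
#' @return matrix `T x 2` of posterior state probabilities (rows sum to 1).
#' @export
posterior_marginals <- function(trace, model) {
  stopifnot(inherits(model, "hmm_model"))
  if (isTRUE(model$degenerate)) {
    return(matrix(c(1, 0), length(trace), 2L, byrow = TRUE))
  }
  forward_backward(as.numeric(trace), model$means, model$sds,
                   model$transition, model$initial)$gamma
}

#' Binarize a full dataset of deconvolved traces
#'
#' Applies [fit_hmm()] + [decode_states()] column-wise. Already-binary input
#' is detected and returned unchanged. Degenerate (zero-variance) neurons
#' decode to all-quiet and are reported as a warning, never an error.
#'
#' @param traces numeric matrix, time x neuron, nonnegative.
#' @param max_iter,tol passed to [fit_hmm()].
#' @return integer binary matrix of the same shape, with attribute
#'   `diagnostics`: data.frame of per-neuron convergence / degeneracy flags
#'   and log-likelihoods.
#' @export
binarize_dataset <- function(traces, max_iter = 200L, tol = 1e-4) {
  traces <- as.matrix(traces)
  if (ncol(traces) < 1L) stop_invalid("need at least one neuron")
  if (is_binary_matrix(traces)) {
    out <- matrix(as.integer(traces), nrow(traces), ncol(traces))
    dimnames(out) <- dimnames(traces)
    attr(out, "diagnostics") <- data.frame(
      neuron = seq_len(ncol(traces)) - 1L, converged = NA,
      degenerate = FALSE, log_likelihood = NA_real_)
    return(out)
  }
  out <- matrix(0L, nrow(traces), ncol(traces))
  diag_df <- data.frame(neuron = seq_len(ncol(traces)) - 1L,
                        converged = FALSE, degenerate = FALSE,
                        log_likelihood = NA_real_)
  for (j in seq_len(ncol(traces))) {
    m <- fit_hmm(traces[, j], max_iter = max_iter, tol = tol)
    out[, j] <- decode_states(traces[, j], m)
    diag_df$converged[j] <- m$converged
    diag_df$degenerate[j] <- m$degenerate
    diag_df$log_likelihood[j] <- m$log_likelihood
  }
  if (any(diag_df$degenerate)) {
    warning(sum(diag_df$degenerate),
            " neuron(s) had zero-variance traces; decoded as all-quiet",
            call. = FALSE)
  }
  dimnames(out) <- dimnames(traces)
  attr(out, "diagnostics") <- diag_df
  out
}

#' @export
print.hmm_model <- function(x, ...) {
  if (x$degenerate) {
    cat("2-state Gaussian HMM: degenerate (zero-variance trace)\n")
  } else {
    cat("2-state Gaussian HMM\n")
    cat(sprintf("  means (quiet, active): %.4g, %.4g\n",
                x$means[1L], x$means[2L]))
    cat(sprintf("  sds: %.4g, %.4g\n", x$sds[1L], x$sds[2L]))
    cat(sprintf("  self-transitions: %.3f, %.3f\n",
                x$transition[1L, 1L], x$transition[2L, 2L]))
    cat(sprintf("  logLik %.2f nats, %s after %d iterations\n",
                x$log_likelihood,
                if (x$converged) "converged" else "not converged", x$n_iter))
  }
  invisible(x)
}
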