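# Null models for information-theoretic measures: random stationary binary
# pair processes with calibrated independent flip noise, matched on TDMI.
#
# A null process is a 4-state Markov chain over joint pair states
# s = x + 2y with a random row-stochastic transition kernel M, observed
# through an independent per-symbol bit-flip channel with rate eta (each
# neuron's bit flips independently). All information quantities of the
# observed process are available in closed form from the stationary
# distribution, so eta can be calibrated by bisection until the analytic
# stationary TDMI matches a requested target.

# 4x4 observation channel: P(observed pair state | true pair state) for
# independent per-bit flips at rate eta. Depends only on the number of
# disagreeing bits between the two pair states (precomputed), so the matrix
# is symmetric.
.PAIR_BIT_DISAGREE <- local({
  xb <- c(0L, 1L, 0L, 1L)
  yb <- c(0L, 0L, 1L, 1L)
  outer(xb, xb, "!=") + outer(yb, yb, "!=")
})

.flip_channel <- function(eta) {
  matrix((1 - eta)^(2L - .PAIR_BIT_DISAGREE) * eta^.PAIR_BIT_DISAGREE, 4L, 4L)
}

# Stationary distribution of an ergodic 4-state kernel (rows sum to 1).
.stationary <- function(M) {
  A <- t(M) - diag(4L)
  A[4L, ] <- 1
  solve(A, c(0, 0, 0, 1))
}

# Analytic joint table p(observed s_t, observed s_{t+1}) of the noisy chain.
.null_joint <- function(M, pi0, eta) {
  B <- .flip_channel(eta)   # symmetric
  B %*% (pi0 * M) %*% B
}

#' Draw one TDMI-matched null PID sample
#'
#' Draws a random stationary binary-pair process (a random joint transition
#' kernel over the four pair states), corrupts it with independent
#' per-symbol flip noise at rate `eta`, and calibrates `eta` by bisection so
#' that the analytic stationary TDMI of the observed process matches
#' `target_tdmi` within 1% relative tolerance. Returns the PID of the
#' calibrated null process, computed analytically from its stationary joint
#' table by default, or from a simulated finite series of length
#' `series_length` when `finite_sample = TRUE` (restoring plug-in
#' estimation bias in the null).
#'
#' Kernels are drawn with Dirichlet rows; when a drawn kernel cannot reach
#' the target even noiselessly, it is redrawn with a progressively sharper
#' (more deterministic) concentration, up to `max_retries`, so that targets
#' near the 2-bit ceiling remain reachable.
#'
#' @param target_tdmi target TDMI in bits, in (0, 2].
#' @param series_length series length for finite-sample nulls (>= 100).
#' @param seed integer seed.
#' @param finite_sample use plug-in PID of a simulated series instead of the
#'   analytic infinite-sample PID.
#' @param max_retries kernel redraws allowed before giving up.
#' @return list with `components` (a `pid_components`), `achieved_tdmi`,
#'   `eta`, `kernel`, `stationary`.
#' @export
sample_null_pair <- function(target_tdmi, series_length = 10000L, seed = 1L,
                             finite_sample = FALSE, max_retries = 200L) {
  if (target_tdmi <= 0 || target_tdmi > 2) {
    stop_invalid("target_tdmi must be in (0, 2] bits")
  }
  if (finite_sample && series_length < 100L) {
    stop_invalid("series_length must be >= 100")
  }
  with_seed(seed, {
    rel_tol <- 0.01
    for (attempt in seq_len(max_retries)) {
      # sharpen rows as attempts accumulate so high targets stay reachable
      alpha <- max(1 * 0.7^(attempt - 1L), 0.02)
      M <- matrix(rgamma(16L, shape = alpha, rate = 1), 4L, 4L)
      M <- M + 1e-9            # keep the chain ergodic
      M <- M / rowSums(M)
      pi0 <- .stationary(M)
      if (any(pi0 < 1e-9)) next
      f <- function(eta) .mi_bits(.null_joint(M, pi0, eta))
      t0 <- f(0)
      if (t0 < target_tdmi) next
      if (abs(t0 - target_tdmi) / target_tdmi <= rel_tol) {
        eta <- 0
      } else {
        lo <- 0; hi <- 0.5
        eta <- 0.25
        for (it in seq_len(60L)) {
          eta <- (lo + hi) / 2
          val <- f(eta)
          if (abs(val - target_tdmi) / target_tdmi < 1e-6) break
          if (val > target_tdmi) lo <- eta else hi <- eta
        }
      }
      joint <- .null_joint(M, pi0, eta)
      achieved <- .mi_bits(joint)
      if (abs(achieved - target_tdmi) / target_tdmi > rel_tol) next
      comp <- if (finite_sample) {
        xy <- .simulate_noisy_chain(M, pi0, eta, series_length)
        pid_mmi(estimate_pair_joint(xy$x, xy$y, tau = 1L))
      } else {
        pid_mmi(pair_joint(joint / sum(joint), tau = 1L))
      }
      return(list(components = comp, achieved_tdmi = achieved, eta = eta,
                  kernel = M, stationary = pi0))
    }
    stop_invalid("could not reach target TDMI ", target_tdmi,
                 " bits after ", max_retries, " kernel draws")
  })
}

# Simulate the noisy chain; returns observed binary series for both neurons.
.simulate_noisy_chain <- function(M, pi0, eta, len) {
  s <- integer(len)
  s[1L] <- sample.int(4L, 1L, prob = pi0)
  cums <- t(apply(M, 1L, cumsum))
  u <- runif(len)
  for (t in 2:len) {
    s[t] <- findInterval(u[t], cums[s[t - 1L], ]) + 1L
  }
  s <- s - 1L
  x <- s %% 2L
  y <- s %/% 2L
  if (eta > 0) {
    x <- as.integer(xor(x == 1L, runif(len) < eta))
    y <- as.integer(xor(y == 1L, runif(len) < eta))
  }
  list(x = x, y = y)
}

#' Null-model Z-scores of PID components (NuMIT)
#'
#' Normalizes empirical PID components against an ensemble of `n_null` null
#' processes matched on the empirical TDMI (see [sample_null_pair()]):
#' `Z_c = (c_emp - mean_null(c)) / sd_null(c)` for each of SI, RI, UI(X),
#' UI(Y). This expresses each component relative to what pairs carrying the
#' same total time-delayed information would show by chance, absorbing
#' biases from finite data, firing rates and the redundancy measure.
#'
#' Pairs with TDMI below 1e-6 bits are flagged `undefined` (no meaningful
#' null ensemble exists), as are components whose null sd is zero.
#'
#' @param pid a `pid_components` object.
#' @param n_null ensemble size (>= 2).
#' @param seed integer seed.
#' @param series_length,finite_sample passed to [sample_null_pair()].
#' @return object of class `zscored_pid`: list with `z_si`, `z_ri`, `z_ui_x`,
#'   `z_ui_y`, `null_mean`, `null_sd`, `achieved_tdmi`, `undefined`.
#' @export
numit_normalize <- function(pid, n_null = 100L, seed = 1L,
                            series_length = 10000L, finite_sample = FALSE) {
  stopifnot(inherits(pid, "pid_components"))
  if (n_null < 2L) stop_invalid("n_null must be >= 2")
  if (!is.finite(pid$tdmi) || pid$tdmi < 1e-6) {
    out <- list(z_si = NA_real_, z_ri = NA_real_, z_ui_x = NA_real_,
                z_ui_y = NA_real_, null_mean = NULL, null_sd = NULL,
                achieved_tdmi = numeric(0), undefined = TRUE)
    class(out) <- "zscored_pid"
    return(out)
  }
  ens <- null_ensemble(pid$tdmi, n_null = n_null, seed = seed,
                       series_length = series_length,
                       finite_sample = finite_sample)
  mu <- ens$mean
  sdv <- ens$sd
  z <- (c(si = pid$si, ri = pid$ri, ui_x = pid$ui_x, ui_y = pid$ui_y) - mu) / sdv
  z[sdv == 0] <- NA_real_
  out <- list(z_si = unname(z["si"]), z_ri = unname(z["ri"]),
              z_ui_x = unname(z["ui_x"]), z_ui_y = unname(z["ui_y"]),
              null_mean = mu, null_sd = sdv,
              achieved_tdmi = ens$achieved_tdmi,
              undefined = any(sdv == 0))
  class(out) <- "zscored_pid"
  out
}

#' Draw a TDMI-matched null ensemble
#'
#' @param target_tdmi target TDMI in bits.
#' @param n_null ensemble size.
#' @param seed integer seed (each member uses a sub-seed derived from it).
#' @param series_length,finite_sample passed to [sample_null_pair()].
#' @return list with `samples` (matrix n_null x 4: si, ri, ui_x, ui_y),
#'   `mean`, `sd`, `achieved_tdmi`, `target_tdmi`.
#' @export
null_ensemble <- function(target_tdmi, n_null = 100L, seed = 1L,
                          series_length = 10000L, finite_sample = FALSE) {
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_null))
  samples <- matrix(NA_real_, n_null, 4L,
                    dimnames = list(NULL, c("si", "ri", "ui_x", "ui_y")))
  achieved <- numeric(n_null)
  for (b in seq_len(n_null)) {
    nd <- sample_null_pair(target_tdmi, series_length = series_length,
                           seed = sub_seeds[b], finite_sample = finite_sample)
    samples[b, ] <- c(nd$components$si, nd$components$ri,
                      nd$components$ui_x, nd$components$ui_y)
    achieved[b] <- nd$achieved_tdmi
  }
  # label-symmetrized ensemble statistics: each null draw enters with both
  # neuron labellings, so Z-scores are exactly invariant under relabelling
  # (up to swapping the two unique components)
  sym <- rbind(samples, samples[, c("si", "ri", "ui_y", "ui_x"),
                                drop = FALSE])
  colnames(sym) <- colnames(samples)
  list(samples = samples, mean = colMeans(sym),
       sd = apply(sym, 2L, sd), achieved_tdmi = achieved,
       target_tdmi = target_tdmi)
}

#' Append NuMIT Z-score columns to a pair PID table
#'
#' Applies [numit_normalize()] to each row of a [pid_pair_table()] result.
#' Degenerate pairs (TDMI below 1e-6 bits) get NA Z-scores and are excluded
#' from downstream spatial and network analyses.
#'
#' @param pid_table data.frame from [pid_pair_table()].
#' @param n_null ensemble size per pair.
#' @param seed integer seed.
#' @param series_length,finite_sample passed to [sample_null_pair()].
#' @return the input table with columns `z_si`, `z_ri`, `z_ui_x`, `z_ui_y`
#'   appended.
#' @export
numit_table <- function(pid_table, n_null = 100L, seed = 1L,
                        series_length = 10000L, finite_sample = FALSE) {
  need <- c("tdmi", "ui_x", "ui_y", "ri", "si")
  if (!all(need %in% names(pid_table))) {
    stop_invalid("pid_table must come from pid_pair_table()")
  }
  m <- nrow(pid_table)
  row_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, m))
  zs <- matrix(NA_real_, m, 4L)
  for (k in seq_len(m)) {
    pid <- structure(list(tdmi = pid_table$tdmi[k], ui_x = pid_table$ui_x[k],
                          ui_y = pid_table$ui_y[k], ri = pid_table$ri[k],
                          si = pid_table$si[k],
                          degenerate = pid_table$tdmi[k] < 1e-12),
                     class = "pid_components")
    z <- numit_normalize(pid, n_null = n_null, seed = row_seeds[k],
                         series_length = series_length,
                         finite_sample = finite_sample)
    zs[k, ] <- c(z$z_si, z$z_ri, z$z_ui_x, z$z_ui_y)
  }
  pid_table$z_si <- zs[, 1L]
  pid_table$z_ri <- zs[, 2L]
  pid_table$z_ui_x <- zs[, 3L]
  pid_table$z_ui_y <- zs[, 4L]
  pid_table
}
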