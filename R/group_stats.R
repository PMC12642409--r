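#' Two-sided permutation test for a difference of group means
#'
#' Tests `|mean(a) - mean(b)|` against the label-permutation null. All
#' distinct label partitions are enumerated exhaustively when their number
#' `choose(n_a + n_b, n_a)` is at most `exhaustive_cap`; the p-value is then
#' the exact proportion of partitions whose statistic is at least the
#' observed one (no add-one correction, so its floor is
#' `2 / n_partitions` for a complete separation). Otherwise `n_perm`
#' Monte-Carlo label shuffles are drawn with the add-one correction
#' `p = (1 + #{|stat_perm| >= |stat_obs|}) / (1 + n_perm)`.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param n_perm Monte-Carlo permutations when exhaustive enumeration is not
#'   feasible.
#' @param seed integer seed for Monte-Carlo draws.
#' @param exhaustive_cap maximum number of partitions enumerated exactly.
#' @param statistic `"mean_diff"` (default) or `"welch_t"`.
#' @return list with `p_value`, `observed`, `method` ("exhaustive" or
#'   "monte_carlo"), `n_permutations`.
#' @export
permutation_test <- function(a, b, n_perm = 10000L, seed = 1L,
                             exhaustive_cap = 20000L,
                             statistic = c("mean_diff", "welch_t")) {
  statistic <- match.arg(statistic)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("both groups need at least 2 values")
  }
  stat_fun <- if (statistic == "mean_diff") {
    function(x, y) mean(x) - mean(y)
  } else {
    function(x, y) {
      se <- sqrt(var(x) / length(x) + var(y) / length(y))
      if (se == 0) 0 else (mean(x) - mean(y)) / se
    }
  }
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  obs <- abs(stat_fun(a, b))
  tol <- 1e-12 * max(1, obs)
  n_part <- choose(n, na)
  if (n_part <= exhaustive_cap) {
    idx <- combn(n, na)
    stats_perm <- apply(idx, 2L, function(ii)
      abs(stat_fun(pooled[ii], pooled[-ii])))
    p <- sum(stats_perm >= obs - tol) / n_part
    list(p_value = p, observed = stat_fun(a, b), method = "exhaustive",
         n_permutations = n_part)
  } else {
    stats_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        ii <- sample.int(n, na)
        abs(stat_fun(pooled[ii], pooled[-ii]))
      }, numeric(1))
    })
    p <- (1 + sum(stats_perm >= obs - tol)) / (1 + n_perm)
    list(p_value = p, observed = stat_fun(a, b), method = "monte_carlo",
         n_permutations = n_perm)
  }
}

#' Hedge's g effect size
#'
#' Bias-corrected standardized mean difference:
#' `g = (mean(a) - mean(b)) / s_pooled * J` with the pooled standard
#' deviation on `n_a + n_b - 2` degrees of freedom and small-sample
#' correction `J = 1 - 3 / (4 (n_a + n_b) - 9)`.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return Hedge's g (dimensionless); NA with a warning when the pooled
#'   variance is zero.
#' @export
hedges_g <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop_invalid("both groups need at least 2 values")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) {
    if (mean(a) == mean(b)) return(0)
    warning("zero pooled variance: Hedge's g undefined", call. = FALSE)
    return(NA_real_)
  }
  j <- 1 - 3 / (4 * (na + nb) - 9)
  (mean(a) - mean(b)) / sqrt(sp2) * j
}

#' Compare two condition groups on a scalar summary
#'
#' Bundles the mean difference, permutation p-value and Hedge's g for two
#' groups of per-recording summaries (fitted correlation lengths, effective
#' information lengths, long-path proportions, ...).
#'
#' @param summaries_a,summaries_b numeric vectors of per-recording summaries.
#' @param n_perm,seed,exhaustive_cap,statistic passed to
#'   [permutation_test()].
#' @return object of class `group_comparison`: list with `mean_difference`,
#'   `p_value`, `hedges_g`, `n_a`, `n_b`, `method`, `p_floor` (smallest
#'   achievable p under the method used).
#' @export
compare_conditions <- function(summaries_a, summaries_b, n_perm = 10000L,
                               seed = 1L, exhaustive_cap = 20000L,
                               statistic = "mean_diff") {
  pt <- permutation_test(summaries_a, summaries_b, n_perm = n_perm,
                         seed = seed, exhaustive_cap = exhaustive_cap,
                         statistic = statistic)
  floor_p <- if (pt$method == "exhaustive") {
    2 / pt$n_permutations
  } else {
    1 / (1 + pt$n_permutations)
  }
  structure(list(mean_difference = mean(summaries_a) - mean(summaries_b),
                 p_value = pt$p_value, hedges_g = hedges_g(summaries_a,
                                                           summaries_b),
                 n_a = length(summaries_a), n_b = length(summaries_b),
                 method = pt$method, p_floor = floor_p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Group comparison (n = %d vs %d): mean difference %.4g, p = %.4g (%s, floor %.2g), Hedge's g = %.3g\n",
    x$n_a, x$n_b, x$mean_difference, x$p_value, x$method, x$p_floor,
    x$hedges_g))
  invisible(x)
}
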