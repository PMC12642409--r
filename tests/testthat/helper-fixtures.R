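# Shared fixtures: exact joint tables for analytic PID endpoints, random
# joint tables, and independent brute-force oracles.

# Exact pair joint table where X's future is the XOR of both presents and Y
# is an independent fair coin at every time: purely synergistic.
xor_joint <- function() {
  p <- matrix(0, 4L, 4L)
  for (xt in 0:1) for (yt in 0:1) for (y1 in 0:1) {
    x1 <- as.integer(xor(xt == 1L, yt == 1L))
    p[xt + 2L * yt + 1L, x1 + 2L * y1 + 1L] <-
      p[xt + 2L * yt + 1L, x1 + 2L * y1 + 1L] + 0.25 * 0.5
  }
  pair_joint(p)
}

# Exact joint table of a persistent binary Markov chain duplicated into two
# identical neurons (y == x at all times).
duplicated_joint <- function(stay = 0.8) {
  trans <- matrix(c(stay, 1 - stay, 1 - stay, stay), 2L, 2L, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  p <- matrix(0, 4L, 4L)
  for (xt in 0:1) for (x1 in 0:1) {
    p[xt + 2L * xt + 1L, x1 + 2L * x1 + 1L] <-
      pi0[xt + 1L] * trans[xt + 1L, x1 + 1L]
  }
  pair_joint(p)
}

# Exact joint table: X a persistent 2-state chain, Y i.i.d. fair and
# independent of X.
persistent_independent_joint <- function(stay = 0.9) {
  trans <- matrix(c(stay, 1 - stay, 1 - stay, stay), 2L, 2L, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  p <- matrix(0, 4L, 4L)
  for (xt in 0:1) for (yt in 0:1) for (x1 in 0:1) for (y1 in 0:1) {
    p[xt + 2L * yt + 1L, x1 + 2L * y1 + 1L] <-
      p[xt + 2L * yt + 1L, x1 + 2L * y1 + 1L] +
      pi0[xt + 1L] * trans[xt + 1L, x1 + 1L] * 0.25
  }
  pair_joint(p)
}

# Random joint table over the 16 lagged pair states (Dirichlet).
random_pair_joint <- function() {
  w <- rgamma(16L, shape = 0.7, rate = 1)
  pair_joint(matrix(w / sum(w), 4L, 4L))
}

# Brute-force mutual information oracle: explicit double sum over the table.
mi_oracle <- function(p) {
  pu <- rowSums(p)
  pv <- colSums(p)
  total <- 0
  for (u in seq_len(nrow(p))) {
    for (v in seq_len(ncol(p))) {
      if (p[u, v] > 0) {
        total <- total + p[u, v] * log2(p[u, v] / (pu[u] * pv[v]))
      }
    }
  }
  total
}

# Brute-force posterior state marginals of a 2-state Gaussian HMM by
# enumerating every state path (feasible up to ~12 timepoints).
hmm_posterior_oracle <- function(trace, model) {
  tt <- length(trace)
  paths <- as.matrix(expand.grid(rep(list(0:1), tt)))
  logp <- apply(paths, 1L, function(s) {
    s1 <- s + 1L
    log(model$initial[s1[1L]]) +
      sum(log(model$transition[cbind(s1[-tt], s1[-1L])])) +
      sum(dnorm(trace, model$means[s1], model$sds[s1], log = TRUE))
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  vapply(seq_len(tt), function(t) sum(w[paths[, t] == 1L]), numeric(1))
}

# Brute-force unweighted shortest-path hop counts by boolean matrix powers.
bfs_oracle <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  if (nrow(edges) > 0L) {
    ii <- match(edges[, 1L], nodes)
    jj <- match(edges[, 2L], nodes)
    adj[cbind(ii, jj)] <- TRUE
    adj[cbind(jj, ii)] <- TRUE
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) == 1
  cur <- reach
  for (h in seq_len(n)) {
    cur <- (cur %*% adj) > 0
    newly <- cur & !reach
    d[newly] <- h
    reach <- reach | newly
    if (all(reach) || !any(newly)) break
  }
  dimnames(d) <- list(as.character(nodes), as.character(nodes))
  d
}

# Random two-layer network over n nodes with given edge probabilities.
random_two_layers <- function(n, p_a = 0.06, p_b = 0.06) {
  pairs <- t(combn(n, 2L)) - 1L
  pick <- function(p) pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  mk <- function(e, metric) {
    colnames(e) <- c("i", "j")
    structure(list(nodes = 0:(n - 1L), edges = e, k = NA_integer_,
                   metric = metric, n_short_of_k = NA_integer_),
              class = "interaction_layer")
  }
  combined_network(mk(pick(p_a), "a"), mk(pick(p_b), "b"))
}

# Small spatially structured raster used by several module tests.
small_fixture <- function(n = 30L, tt = 3000L, seed = 42L, ...) {
  pos <- generate_positions(n, 3000, seed = seed)
  params <- generator_params(n_neurons = n, n_timepoints = tt,
                             seed = seed + 1L, ...)
  list(positions = pos, raster = simulate_raster(pos, params),
       params = params)
}
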