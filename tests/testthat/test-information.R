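test_that("pair joint distribution matches direct tuple enumeration", {
  x <- c(0L, 1L, 0L, 1L, 0L, 1L)
  j <- estimate_pair_joint(x, x, tau = 1L)
  # aligned 4-tuples: (0,0,1,1) x3 and (1,1,0,0) x2
  expect_equal(sum(j$probs), 1)
  expect_equal(j$sample_count, 5L)
  expect_equal(j$probs["00", "11"], 3 / 5)
  expect_equal(j$probs["11", "00"], 2 / 5)
  expect_equal(sum(j$probs > 0), 2L)

  z <- rep(0L, 10L)
  jz <- estimate_pair_joint(z, z, tau = 1L)
  expect_equal(jz$probs["00", "00"], 1)

  expect_error(estimate_pair_joint(0:1, 0L), "equal length")
  expect_error(estimate_pair_joint(c(0L, 1L), c(0L, 1L), tau = 2L), "tau")
  expect_error(estimate_pair_joint(c(0L, 2L), c(0L, 1L)), "binary")
})

test_that("mutual information: independence, identity channel, oracle", {
  pu <- c(0.3, 0.7)
  pv <- c(0.6, 0.4)
  expect_equal(mutual_information(outer(pu, pv)), 0)
  expect_equal(mutual_information(diag(2) / 2), 1)
  set.seed(404)
  for (rep in 1:50) {
    p <- matrix(rgamma(16, 0.6), 4, 4)
    p <- p / sum(p)
    expect_equal(mutual_information(p), mi_oracle(p), tolerance = 1e-12)
  }
  expect_error(mutual_information(diag(2)), "normalized")
  expect_error(mutual_information(matrix(c(1.5, -0.5, 0, 0), 2, 2)),
               "negative")
})

test_that("TDMI endpoints: independent product and two identity channels", {
  # product of identical past/future marginals, independent in time
  m <- rep(0.25, 4)
  expect_equal(tdmi(pair_joint(outer(m, m))), 0)
  # x and y fair, independent of each other, both copied to t+1
  p <- diag(4) / 4
  expect_equal(tdmi(pair_joint(p)), 2)
})

test_that("empirical TDMI converges to the analytic chain value", {
  # 2-state persistent chain duplicated into a pair via the analytic table
  stay <- 0.85
  j_exact <- duplicated_joint(stay = stay)
  analytic <- tdmi(j_exact)
  set.seed(77)
  tt <- 100000L
  x <- integer(tt)
  x[1] <- 0L
  u <- runif(tt)
  for (t in 2:tt) {
    x[t] <- if (u[t] < stay) x[t - 1L] else 1L - x[t - 1L]
  }
  emp <- tdmi(estimate_pair_joint(x, x, tau = 1L))
  expect_lt(abs(emp - analytic), 0.01)
})

test_that("PID analytic endpoints: XOR, duplicated neuron, persistent-X", {
  px <- pid_mmi(xor_joint())
  expect_equal(px$ri, 0, tolerance = 1e-9)
  expect_equal(px$ui_x, 0, tolerance = 1e-9)
  expect_equal(px$ui_y, 0, tolerance = 1e-9)
  expect_equal(px$si, px$tdmi, tolerance = 1e-9)
  expect_equal(px$tdmi, 1, tolerance = 1e-9)

  pd <- pid_mmi(duplicated_joint())
  expect_equal(pd$si, 0, tolerance = 1e-9)
  expect_equal(pd$ui_x, 0, tolerance = 1e-9)
  expect_equal(pd$ui_y, 0, tolerance = 1e-9)
  expect_equal(pd$ri, pd$tdmi, tolerance = 1e-9)

  pp <- pid_mmi(persistent_independent_joint())
  expect_equal(pp$ri, 0, tolerance = 1e-9)
  expect_equal(pp$si, 0, tolerance = 1e-9)
  expect_equal(pp$ui_y, 0, tolerance = 1e-9)
  expect_equal(pp$ui_x, pp$tdmi, tolerance = 1e-9)
  expect_gt(pp$tdmi, 0)
})

test_that("PID identity, nonnegativity and MMI structure on random tables", {
  set.seed(808)
  for (rep in 1:200) {
    j <- random_pair_joint()
    p <- pid_mmi(j)
    expect_equal(p$ui_x + p$ui_y + p$ri + p$si, p$tdmi, tolerance = 1e-9)
    expect_true(all(c(p$tdmi, p$ui_x, p$ui_y, p$ri, p$si) >= 0))
    expect_lt(min(p$ui_x, p$ui_y), 1e-12)
  }
})

test_that("plug-in PID converges to the analytic decomposition of a chain", {
  # simulate a known pair kernel and compare with PID of its exact joint
  set.seed(99)
  M <- matrix(rgamma(16, 2), 4, 4)
  M <- M / rowSums(M)
  pi0 <- synpid:::.stationary(M)
  exact <- synpid:::.pid_bits(synpid:::.null_joint(M, pi0, 0))
  xy <- synpid:::.simulate_noisy_chain(M, pi0, 0, 100000L)
  est <- pid_mmi(estimate_pair_joint(xy$x, xy$y, tau = 1L))
  expect_lt(abs(est$tdmi - exact["tdmi"]), 0.01)
  expect_lt(abs(est$si - exact["si"]), 0.01)
  expect_lt(abs(est$ri - exact["ri"]), 0.01)
})

test_that("pid_pair_table computes distances and flags degenerate pairs", {
  fx <- small_fixture(n = 10L, tt = 800L, seed = 6L)
  r <- fx$raster
  r[, 4] <- 0L   # two constant neurons
  r[, 6] <- 0L
  tab <- pid_pair_table(r, fx$positions, tau = 1L, seed = 1L)
  expect_equal(nrow(tab), choose(10, 2))
  D <- pair_distance_matrix(fx$positions)
  expect_equal(tab$distance_um,
               D[cbind(tab$i + 1L, tab$j + 1L)])
  # a pair of two constant neurons carries no time-delayed information
  deg <- tab$i == 3L & tab$j == 5L
  expect_true(all(tab$degenerate[deg]))
  expect_true(all(tab$tdmi[deg] == 0))
  # a constant neuron paired with an active one reduces to the active
  # neuron's self-information, which is generally nonzero
  mixed <- tab$i == 3L & !tab$degenerate
  expect_true(any(tab$tdmi[mixed] > 0))
  expect_equal(tab$ui_x + tab$ui_y + tab$ri + tab$si, tab$tdmi,
               tolerance = 1e-9)
  # max_pairs subsample is honoured and deterministic
  t2 <- pid_pair_table(r, fx$positions, max_pairs = 10L, seed = 2L)
  expect_equal(nrow(t2), 10L)
  expect_identical(t2, pid_pair_table(r, fx$positions, max_pairs = 10L,
                                      seed = 2L))
})
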