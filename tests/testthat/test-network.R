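test_that("top-k selection builds the expected union of directed choices", {
  # node 0's top-1 is node 1, node 1's top-1 is node 2, etc.
  pv <- data.frame(i = c(0, 0, 0, 1, 1, 2), j = c(1, 2, 3, 2, 3, 3),
                   value = c(10, 1, 2, 9, 3, 8))
  la <- build_knn_layer(pv, 0:3, k = 1)
  expect_equal(unname(la$edges), cbind(c(0, 1, 2), c(1, 2, 3)))
  # symmetric by construction: every edge stored once with i < j
  expect_true(all(la$edges[, 1] < la$edges[, 2]))

  # k >= n - 1 gives the complete graph
  lc <- build_knn_layer(pv, 0:3, k = 3)
  expect_equal(nrow(lc$edges), choose(4, 2))

  # deterministic tie-break by smaller partner id
  tie <- data.frame(i = c(0, 0), j = c(1, 2), value = c(5, 5))
  lt <- build_knn_layer(tie, 0:2, k = 1)
  expect_true(any(lt$edges[, 1] == 0 & lt$edges[, 2] == 1))
})

test_that("shortest paths: path graph, disconnection, and BFS oracle", {
  d <- layer_shortest_paths(1:3, cbind(i = c(1, 2), j = c(2, 3)))
  expect_equal(d["1", "3"], 2)
  d2 <- layer_shortest_paths(1:4, cbind(i = 1, j = 2))
  expect_equal(d2["1", "2"], 1)
  expect_equal(d2["1", "3"], Inf)
  set.seed(22)
  for (rep in 1:5) {
    net <- random_two_layers(30)
    d_pkg <- layer_shortest_paths(net$nodes, net$union_edges)
    d_or <- bfs_oracle(net$nodes, net$union_edges)
    expect_equal(d_pkg, d_or)
  }
})

test_that("path classification follows the min/max rules", {
  # layer A path 1-2-3-4, layer B single edge 2-4
  mk <- function(e, metric) {
    colnames(e) <- c("i", "j")
    structure(list(nodes = 1:4, edges = e, k = 1L, metric = metric,
                   n_short_of_k = 0L), class = "interaction_layer")
  }
  net <- combined_network(mk(cbind(c(1, 2, 3), c(2, 3, 4)), "a"),
                          mk(cbind(2, 4), "b"))
  counts <- classify_paths(net)
  cls <- attr(counts, "classification")
  g <- function(i, j) cls$category[cls$i == i & cls$j == j]
  expect_equal(g(1, 4), "complementary")   # dA=3, dB=Inf, dU=2
  expect_equal(g(2, 4), "unique_b")        # dA=2, dB=1, dU=1
  expect_equal(g(1, 2), "unique_a")        # reachable only in A
  # identical layers: every reachable pair shared
  net2 <- combined_network(mk(cbind(c(1, 2), c(2, 3)), "a"),
                           mk(cbind(c(1, 2), c(2, 3)), "b"))
  c2 <- classify_paths(net2)
  expect_equal(sum(c2$shared), sum(c2$complementary, c2$shared,
                                   c2$unique_a, c2$unique_b))
  pp2 <- path_proportions(c2, long_threshold = 1)
  expect_true(all(pp2$by_length$shared == 1))
})

test_that("classification is exhaustive, exclusive and respects the union bound", {
  set.seed(33)
  for (rep in 1:10) {
    net <- random_two_layers(25)
    counts <- classify_paths(net)
    cls <- attr(counts, "classification")
    # d_union never exceeds either layer distance
    expect_true(all(cls$d_union <= pmin(cls$d_a, cls$d_b)))
    # every classified pair has exactly one category
    expect_equal(nrow(cls) + attr(counts, "n_excluded"), choose(25, 2))
    # per-length counts match the per-pair table
    for (L in counts$path_length) {
      at <- cls[cls$path_length == L, ]
      expect_equal(counts$complementary[counts$path_length == L],
                   sum(at$category == "complementary"))
    }
  }
})

test_that("swapping layer labels swaps unique counts only", {
  set.seed(44)
  net <- random_two_layers(20)
  swapped <- combined_network(net$layer_b, net$layer_a)
  c1 <- classify_paths(net)
  c2 <- classify_paths(swapped)
  expect_equal(c1$complementary, c2$complementary)
  expect_equal(c1$shared, c2$shared)
  expect_equal(c1$unique_a, c2$unique_b)
  expect_equal(c1$unique_b, c2$unique_a)
})

test_that("proportions sum to one per length and aggregate long paths", {
  set.seed(55)
  net <- random_two_layers(30, p_a = 0.04, p_b = 0.04)
  counts <- classify_paths(net)
  pp <- path_proportions(counts, long_threshold = 2)
  sums <- rowSums(pp$by_length[, c("complementary", "shared", "unique_a",
                                   "unique_b")])
  expect_equal(sums, rep(1, nrow(pp$by_length)))
  long_rows <- counts$path_length >= 2
  expect_equal(unname(pp$long["complementary"]),
               sum(counts$complementary[long_rows]) /
                 sum(counts[long_rows, c("complementary", "shared",
                                         "unique_a", "unique_b")]))
})
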