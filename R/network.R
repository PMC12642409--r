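#' Build an unweighted k-nearest-neighbour interaction layer
#'
#' For each neuron, select its `k` largest-valued partners by the given
#' per-pair scalar (e.g. Z-scored synergy or redundancy); the layer's edge
#' set is the symmetric union of these directed selections (an edge is
#' present if either endpoint selected the other). Ties are broken by the
#' smaller partner id, deterministically. Nodes with fewer than `k` finite
#' partners keep all they have (counted in attribute `n_short_of_k`). Pairs
#' with non-finite values are ignored.
#'
#' @param pair_values data.frame with columns `i`, `j`, `value`.
#' @param node_ids integer vector of all node ids (0-based).
#' @param k neighbours retained per node (>= 1).
#' @param metric label stored on the layer (e.g. "z_si").
#' @param mutual if TRUE keep only mutual selections (both endpoints chose
#'   each other) instead of the union.
#' @return object of class `interaction_layer`: list with `nodes`, `edges`
#'   (two-column matrix of ids, i < j), `k`, `metric`.
#' @export
build_knn_layer <- function(pair_values, node_ids, k, metric = "value",
                            mutual = FALSE) {
  stopifnot(all(c("i", "j", "value") %in% names(pair_values)))
  if (k < 1L) stop_invalid("k must be >= 1")
  pv <- pair_values[is.finite(pair_values$value), , drop = FALSE]
  # directed view: each row twice, once per endpoint
  from <- c(pv$i, pv$j)
  to <- c(pv$j, pv$i)
  val <- c(pv$value, pv$value)
  sel_from <- integer(0)
  sel_to <- integer(0)
  n_short <- 0L
  for (nd in node_ids) {
    m <- from == nd
    if (!any(m)) { n_short <- n_short + 1L; next }
    partners <- to[m]
    vals <- val[m]
    ord <- order(-vals, partners)
    take <- head(ord, k)
    if (length(partners) < k) n_short <- n_short + 1L
    sel_from <- c(sel_from, rep(nd, length(take)))
    sel_to <- c(sel_to, partners[take])
  }
  a <- pmin(sel_from, sel_to)
  b <- pmax(sel_from, sel_to)
  key <- paste(a, b)
  if (mutual) {
    keep <- key %in% names(which(table(key) == 2L))
    a <- a[keep]; b <- b[keep]; key <- key[keep]
  }
  dup <- duplicated(key)
  edges <- cbind(i = a[!dup], j = b[!dup])
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(list(nodes = sort(node_ids), edges = edges, k = as.integer(k),
                 metric = metric, n_short_of_k = n_short),
            class = "interaction_layer")
}

#' @export
print.interaction_layer <- function(x, ...) {
  cat(sprintf("Interaction layer (%s): %d nodes, %d edges, k = %d\n",
              x$metric, length(x$nodes), nrow(x$edges), x$k))
  invisible(x)
}

#' Combine two interaction layers and their edge union
#'
#' @param layer_a,layer_b `interaction_layer` objects over the same node set
#'   (conventionally a = synergy, b = redundancy).
#' @return object of class `combined_network`: list with `layer_a`,
#'   `layer_b`, `union_edges`.
#' @export
combined_network <- function(layer_a, layer_b) {
  stopifnot(inherits(layer_a, "interaction_layer"),
            inherits(layer_b, "interaction_layer"))
  if (!identical(layer_a$nodes, layer_b$nodes)) {
    stop_invalid("layers must share the same node set")
  }
  all_e <- rbind(layer_a$edges, layer_b$edges)
  key <- paste(all_e[, 1L], all_e[, 2L])
  un <- all_e[!duplicated(key), , drop = FALSE]
  un <- un[order(un[, 1L], un[, 2L]), , drop = FALSE]
  structure(list(layer_a = layer_a, layer_b = layer_b, union_edges = un,
                 nodes = layer_a$nodes),
            class = "combined_network")
}

# igraph over a fixed node set; vertex names are the 0-based neuron ids.
.layer_graph <- function(nodes, edges) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(nodes))
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(cbind(match(edges[, 1L], nodes),
                                      match(edges[, 2L], nodes))))
  }
  g
}

#' All-pairs shortest-path hop counts of an edge set
#'
#' Breadth-first hop counts between every node pair of an unweighted
#' undirected edge set; unreachable pairs are `Inf`.
#'
#' @param nodes integer vector of node ids.
#' @param edges two-column matrix of edges (ids).
#' @return numeric matrix of hop counts with node ids as dimnames.
#' @export
layer_shortest_paths <- function(nodes, edges) {
  g <- .layer_graph(nodes, edges)
  d <- igraph::distances(g)
  dimnames(d) <- list(as.character(nodes), as.character(nodes))
  d
}

#' Classify node pairs into complementary, shared and unique paths
#'
#' For each unordered node pair reachable in the union network, compare the
#' union shortest-path length `d_union` with the per-layer lengths `dA`,
#' `dB`:
#' * complementary: `d_union < min(dA, dB)` — the two layers together give a
#'   shorter route than either alone;
#' * shared: `d_union = max(dA, dB)` — neither layer improves on the other;
#' * unique to a layer: `d_union = min(dA, dB) < max(dA, dB)` — one layer
#'   alone provides the best route.
#' Infinite per-layer distances participate through the min/max rules; pairs
#' unreachable even in the union are excluded and counted.
#'
#' @param net a `combined_network`.
#' @param length_axis which distance indexes the per-length table:
#'   `"union"` (hop count in the union graph) or `"min_layer"`
#'   (`min(dA, dB)`).
#' @return object of class `path_class_counts`: data.frame with columns
#'   `path_length`, `complementary`, `shared`, `unique_a`, `unique_b`;
#'   attributes `n_excluded` (pairs disconnected in the union) and
#'   `classification` (per-pair table).
#' @export
classify_paths <- function(net, length_axis = c("union", "min_layer")) {
  stopifnot(inherits(net, "combined_network"))
  length_axis <- match.arg(length_axis)
  nodes <- net$nodes
  dA <- layer_shortest_paths(nodes, net$layer_a$edges)
  dB <- layer_shortest_paths(nodes, net$layer_b$edges)
  dU <- layer_shortest_paths(nodes, net$union_edges)
  ut <- upper.tri(dU)
  da <- dA[ut]; db <- dB[ut]; du <- dU[ut]
  if (any(du > pmin(da, db))) {
    stop("internal invariant violated: union distance exceeds a layer distance")
  }
  reach <- is.finite(du)
  n_excluded <- sum(!reach)
  da <- da[reach]; db <- db[reach]; du <- du[reach]
  lo <- pmin(da, db); hi <- pmax(da, db)
  category <- ifelse(du < lo, "complementary",
              ifelse(du == hi, "shared",
              ifelse(da < db, "unique_a", "unique_b")))
  len <- if (length_axis == "union") du else lo
  pairs_idx <- which(ut, arr.ind = TRUE)[reach, , drop = FALSE]
  cls <- data.frame(i = nodes[pairs_idx[, 1L]], j = nodes[pairs_idx[, 2L]],
                    d_a = da, d_b = db, d_union = du, path_length = len,
                    category = category)
  lengths <- sort(unique(len))
  counts <- data.frame(
    path_length = lengths,
    complementary = vapply(lengths, function(L)
      sum(len == L & category == "complementary"), integer(1)),
    shared = vapply(lengths, function(L)
      sum(len == L & category == "shared"), integer(1)),
    unique_a = vapply(lengths, function(L)
      sum(len == L & category == "unique_a"), integer(1)),
    unique_b = vapply(lengths, function(L)
      sum(len == L & category == "unique_b"), integer(1)))
  attr(counts, "n_excluded") <- n_excluded
  attr(counts, "classification") <- cls
  attr(counts, "length_axis") <- length_axis
  class(counts) <- c("path_class_counts", "data.frame")
  counts
}

#' Per-length path-category proportions and long-path summary
#'
#' @param counts a `path_class_counts` from [classify_paths()].
#' @param long_threshold paths of length `>= long_threshold` count as long
#'   (default 4).
#' @return list with `by_length` (data.frame of per-length proportions;
#'   lengths with no classified pairs yield NaN) and `long` (named vector of
#'   aggregate proportions over long paths, plus `n_long_pairs`).
#' @export
path_proportions <- function(counts, long_threshold = 4L) {
  stopifnot(inherits(counts, "path_class_counts"))
  cats <- c("complementary", "shared", "unique_a", "unique_b")
  tot <- rowSums(counts[cats])
  by_length <- data.frame(path_length = counts$path_length,
                          n_pairs = tot,
                          sweep(as.matrix(counts[cats]), 1L, tot, "/"))
  long_rows <- counts$path_length >= long_threshold
  long_tot <- sum(tot[long_rows])
  long <- if (long_tot > 0) {
    colSums(counts[long_rows, cats, drop = FALSE]) / long_tot
  } else {
    setNames(rep(NA_real_, 4L), cats)
  }
  list(by_length = by_length,
       long = c(long, n_long_pairs = long_tot),
       long_threshold = long_threshold)
}
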