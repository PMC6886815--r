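# Exact graph edit distance for small unlabeled graphs, used as the risk
# of the Mapper morphism. The solver searches over all injective partial
# node assignments; for the cost structures supported here (per-operation
# node insert/delete/substitute and edge insert/delete) this enumeration is
# exact.

#' Construct a GED graph
#'
#' @param n node count; `edges` 2-column matrix of undirected node pairs
#'   (self-edges forbidden).
#' @return Object of class `ged_graph` with an adjacency matrix.
#' @export
ged_graph <- function(n, edges = NULL) {
  n <- as.integer(n)
  A <- matrix(0L, n, n)
  if (!is.null(edges) && length(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges[, 1] == edges[, 2])) stopf("ged_graph: self-edges are not allowed")
    if (any(edges > n) || any(edges < 1L)) stopf("ged_graph: edge endpoint out of range")
    A[edges] <- 1L; A[edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  structure(list(n = n, A = A), class = "ged_graph")
}

#' Coerce to a GED graph
#' @param x a `ged_graph`, `mapper_graph`, igraph, or adjacency matrix.
#' @export
as_ged_graph <- function(x) {
  if (inherits(x, "ged_graph")) return(x)
  if (inherits(x, "mapper_graph"))
    return(ged_graph(length(x$nodes), as.matrix(x$edges[, c("i", "j")])))
  if (inherits(x, "igraph"))
    return(ged_graph(igraph::vcount(x), igraph::as_edgelist(x)))
  if (is.matrix(x)) {
    g <- ged_graph(nrow(x))
    g$A <- (x != 0) * 1L
    diag(g$A) <- 0L
    return(g)
  }
  stopf("cannot coerce to ged_graph")
}

#' Default unit edit costs
#' @export
ged_unit_costs <- function() {
  c(node_ins = 1, node_del = 1, node_sub = 0, edge_ins = 1, edge_del = 1)
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' Exact graph edit distance
#'
#' Minimum total cost over node insertions/deletions/substitutions and
#' edge insertions/deletions transforming `G1` into `G2`, computed by
#' exhaustive search over injective node assignments. Intended for the
#' small graphs Mapper produces; both graphs must have at most 8 nodes
#' (larger inputs error and point at `approx = TRUE`, which runs a greedy
#' assignment upper bound instead).
#'
#' @param G1,G2 anything [as_ged_graph()] accepts.
#' @param costs named nonnegative costs (`node_ins`, `node_del`,
#'   `node_sub`, `edge_ins`, `edge_del`); default unit costs with free
#'   substitution of unlabeled nodes.
#' @param approx use the greedy upper bound (permits > 8 nodes).
#' @return Nonnegative scalar; 0 iff the graphs are isomorphic under the
#'   default costs.
#' @export
graph_edit_distance <- function(G1, G2, costs = ged_unit_costs(), approx = FALSE) {
  G1 <- as_ged_graph(G1); G2 <- as_ged_graph(G2)
  need <- c("node_ins", "node_del", "node_sub", "edge_ins", "edge_del")
  if (!all(need %in% names(costs))) stopf("costs must name: %s", paste(need, collapse = ", "))
  if (any(costs < 0)) stopf("graph_edit_distance: costs must be nonnegative")
  n1 <- G1$n; n2 <- G2$n
  deg1 <- rowSums(G1$A); deg2 <- rowSums(G2$A)

  assignment_cost <- function(m1, m2) {
    # m1 -> m2 elementwise mapped; rest deleted/inserted
    k <- length(m1)
    del_nodes <- setdiff(seq_len(n1), m1)
    ins_nodes <- setdiff(seq_len(n2), m2)
    cost <- costs["node_del"] * length(del_nodes) +
      costs["node_ins"] * length(ins_nodes) + costs["node_sub"] * k
    # edges among mapped nodes
    if (k > 1L) {
      A1m <- G1$A[m1, m1, drop = FALSE]
      A2m <- G2$A[m2, m2, drop = FALSE]
      cost <- cost + costs["edge_del"] * sum(A1m == 1L & A2m == 0L) / 2 +
        costs["edge_ins"] * sum(A1m == 0L & A2m == 1L) / 2
    }
    # edges touching deleted / inserted nodes (each counted once)
    if (length(del_nodes)) {
      sub <- G1$A[del_nodes, , drop = FALSE]
      cost <- cost + costs["edge_del"] *
        (sum(sub) - sum(G1$A[del_nodes, del_nodes]) / 2)
    }
    if (length(ins_nodes)) {
      sub <- G2$A[ins_nodes, , drop = FALSE]
      cost <- cost + costs["edge_ins"] *
        (sum(sub) - sum(G2$A[ins_nodes, ins_nodes]) / 2)
    }
    unname(cost)
  }

  if (approx) {
    # greedy: repeatedly match the degree-closest remaining pair
    m1 <- integer(0); m2 <- integer(0)
    r1 <- order(-deg1); r2 <- order(-deg2)
    k <- min(n1, n2)
    return(assignment_cost(r1[seq_len(k)], r2[seq_len(k)]))
  }
  if (n1 > 8L || n2 > 8L)
    stopf("exact GED is limited to graphs with <= 8 nodes; use approx = TRUE")

  best <- assignment_cost(integer(0), integer(0))  # delete all, insert all
  for (k in seq_len(min(n1, n2))) {
    sub1 <- utils::combn(n1, k, simplify = FALSE)
    sub2 <- utils::combn(n2, k, simplify = FALSE)
    for (s1 in sub1) {
      for (s2 in sub2) {
        for (perm in all_permutations(s2)) {
          cost <- assignment_cost(s1, perm)
          if (cost < best) best <- cost
        }
      }
    }
  }
  best
}
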