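# From-scratch Mapper: a real-valued filtration over the data, an
# overlapping interval cover of its range, per-preimage clustering
# (deterministic k-medoids under Gower by default), pruning of small
# clusters, nerve edges between retained clusters sharing samples, and
# assignment of unseen points to nodes.

#' Mapper parameters
#'
#' @param k number of cover intervals (>= 1).
#' @param o overlap fraction in `[0, 1)`: adjacent intervals intersect in
#'   `o` times the (uniform) interval length.
#' @param b clusters per interval preimage.
#' @param min_node_size clusters with fewer members are dropped before edge
#'   construction (default 40).
#' @param filtration `"pca"` (first principal component of the standardized
#'   encoded matrix, the default), `"coordinate:<j>"` for the j-th encoded
#'   coordinate, or a list/function spec.
#' @param distance `"gower"` (on the raw mixed table, default) or
#'   `"euclidean"` (on the encoded matrix).
#' @param cluster_method `"kmedoids"` (deterministic farthest-point
#'   seeding; works with any metric) or `"kmeans"` (Euclidean on the
#'   encoded matrix, for literal conformance with the textbook recipe).
#' @return Object of class `mapper_params`.
#' @export
mapper_params <- function(k = 10L, o = 0.5, b = 20L, min_node_size = 40L,
                          filtration = "pca", distance = "gower",
                          cluster_method = c("kmedoids", "kmeans")) {
  if (k < 1L || b < 1L) stopf("mapper_params: k and b must be >= 1")
  if (o < 0 || o >= 1) stopf("mapper_params: o must lie in [0, 1)")
  structure(list(k = as.integer(k), o = o, b = as.integer(b),
                 min_node_size = as.integer(min_node_size),
                 filtration = filtration, distance = distance,
                 cluster_method = match.arg(cluster_method)),
            class = "mapper_params")
}

# ---- filtration ------------------------------------------------------------

#' Fit the first-principal-component filtration
#'
#' Standardizes the encoded matrix and projects onto the leading principal
#' axis; the sign is fixed so the largest-magnitude loading is positive,
#' making filter values reproducible. The fitted map applies to unseen
#' points.
#'
#' @param X_encoded numeric matrix (>= 2 rows, non-constant).
#' @return Object of class `mapper_filtration`.
#' @export
pca_filtration_fit <- function(X_encoded) {
  X <- as_matrix(X_encoded)
  if (nrow(X) < 2L) stopf("pca_filtration_fit needs at least 2 rows")
  if (all(apply(X, 2L, function(col) diff(range(col)) == 0)))
    stopf("pca_filtration_fit: constant data has no principal direction")
  pca <- suppressWarnings(fit_pca(X, c = 1L))
  structure(list(kind = "pca", pca = pca), class = "mapper_filtration")
}

fit_filtration <- function(spec, X_encoded) {
  if (inherits(spec, "mapper_filtration")) return(spec)
  if (is.function(spec))
    return(structure(list(kind = "function", fn = spec), class = "mapper_filtration"))
  if (is.character(spec) && spec == "pca") return(pca_filtration_fit(X_encoded))
  if (is.character(spec) && startsWith(spec, "coordinate:")) {
    j <- as.integer(sub("coordinate:", "", spec))
    return(structure(list(kind = "coordinate", index = j),
                     class = "mapper_filtration"))
  }
  stopf("unknown filtration spec")
}

#' Evaluate a fitted filtration at points
#' @param filt a fitted filtration; `x` encoded vector or matrix.
#' @export
filtration_apply <- function(filt, x) {
  x <- as_matrix(x)
  switch(filt$kind,
         pca = as.numeric(pca_project(filt$pca, x)),
         coordinate = as.numeric(x[, filt$index]),
         `function` = as.numeric(filt$fn(x)))
}

# ---- cover -----------------------------------------------------------------

#' Build a uniform overlapping interval cover
#'
#' `k` closed intervals of equal length `a_I = range / (k - (k-1) o)`, with
#' interval `j` starting at `min + (j-1)(1-o) a_I`, so each adjacent pair
#' intersects in a segment of length `o * a_I`. All filter values equal
#' yields a single degenerate interval.
#'
#' @param filter_values numeric filtration values.
#' @param k interval count; `o` overlap fraction in `[0, 1)`.
#' @return Object of class `mapper_cover` with fields `lo`, `hi`, `a_I`.
#' @export
build_cover <- function(filter_values, k, o) {
  if (k < 1L) stopf("build_cover: k must be >= 1")
  if (o < 0 || o >= 1) stopf("build_cover: o must lie in [0, 1)")
  lo_all <- min(filter_values); hi_all <- max(filter_values)
  rng <- hi_all - lo_all
  if (rng == 0) {
    return(structure(list(lo = lo_all, hi = hi_all, a_I = 0, k = 1L, o = o),
                     class = "mapper_cover"))
  }
  a_I <- rng / (k - (k - 1) * o)
  starts <- lo_all + (seq_len(k) - 1) * (1 - o) * a_I
  his <- starts + a_I
  # pin the extreme endpoints so the union covers every sample exactly
  starts[1L] <- lo_all
  his[k] <- hi_all
  structure(list(lo = starts, hi = his, a_I = a_I, k = as.integer(k),
                 o = o), class = "mapper_cover")
}

# interval indices containing each value (closed-interval membership)
cover_membership <- function(cover, values) {
  lapply(values, function(v)
    which(cover$lo <= v & v <= cover$hi))
}

# ---- deterministic k-medoids ----------------------------------------------

# Farthest-point seeding from the lowest-index point, then alternate
# nearest-medoid assignment and within-cluster medoid updates. Fully
# deterministic: all ties break toward the lowest index.
kmedoids_fit <- function(D, b) {
  n <- nrow(D)
  b <- min(b, n)
  medoids <- 1L
  while (length(medoids) < b) {
    dmin <- apply(D[, medoids, drop = FALSE], 1L, min)
    dmin[medoids] <- -Inf
    medoids <- c(medoids, which.max(dmin))
  }
  assignment <- integer(n)
  for (iter in seq_len(100L)) {
    assignment <- apply(D[, medoids, drop = FALSE], 1L, which.min)
    new_medoids <- vapply(seq_along(medoids), function(ci) {
      members <- which(assignment == ci)
      if (length(members) == 0L) return(medoids[ci])
      members[which.min(rowSums(D[members, members, drop = FALSE]))]
    }, integer(1))
    if (identical(new_medoids, medoids)) break
    medoids <- new_medoids
  }
  assignment <- apply(D[, medoids, drop = FALSE], 1L, which.min)
  list(assignment = assignment, medoids = medoids)
}

# Merge k-medoid clusters that are not separated by a density gap: two
# clusters are joined when their minimum cross-distance is within the
# preimage's within-cluster nearest-neighbor resolution (the largest
# distance from any point to its nearest same-cluster neighbor). This
# implements the "at most b clusters" contract: b is an upper bound and
# the solver keeps connected point clouds whole, so that e.g. the apex
# preimage of a circle stays one node instead of being cut in half.
merge_gapless_clusters <- function(D, assignment) {
  ids <- sort(unique(assignment))
  if (length(ids) <= 1L) return(assignment)
  res <- 0
  for (ci in ids) {
    members <- which(assignment == ci)
    if (length(members) < 2L) next
    Dm <- D[members, members, drop = FALSE]
    diag(Dm) <- Inf
    res <- max(res, max(apply(Dm, 1L, min)))
  }
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      cross <- min(D[assignment == ids[a], assignment == ids[b]])
      if (cross <= res + 1e-12) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  match(roots, sort(unique(roots)))[match(assignment, ids)]
}

# ---- graph construction ----------------------------------------------------

#' Build a Mapper graph
#'
#' Computes the filtration, covers its range with `k` overlapping
#' intervals, clusters every interval preimage into at most `b` clusters
#' (deterministic k-medoids under Gower by default, with clusters that are
#' not separated by a density gap merged back together, so `b` acts as an
#' upper bound; or Euclidean k-means on the encoded matrix), drops
#' clusters with fewer than `min_node_size` members, and adds an edge
#' between every retained pair of nodes sharing at least one sample.
#'
#' @param X_table raw mixed-type data frame (used by the Gower metric).
#' @param X_encoded numeric encoded matrix (used by the filtration and by
#'   Euclidean clustering); defaults to `data.matrix(X_table)`.
#' @param params a [mapper_params()].
#' @return Object of class `mapper_graph`: `nodes` (list of
#'   `id`/`interval`/`members`/`representative`), `edges` data frame
#'   (`i`, `j`, `shared`), plus the fitted filtration, cover and distance
#'   context needed to place unseen points.
#' @export
build_mapper_graph <- function(X_table, X_encoded = NULL, params = mapper_params()) {
  stopifnot(inherits(params, "mapper_params"))
  if (!is.data.frame(X_table)) X_table <- as.data.frame(X_table)
  if (is.null(X_encoded)) X_encoded <- data.matrix(X_table)
  X_encoded <- as_matrix(X_encoded)
  n <- nrow(X_table)
  if (n < params$min_node_size)
    stopf("build_mapper_graph: %d samples < min_node_size %d", n, params$min_node_size)
  filt <- fit_filtration(params$filtration, X_encoded)
  values <- filtration_apply(filt, X_encoded)
  cover <- build_cover(values, params$k, params$o)
  ctx <- if (params$distance == "gower") suppressWarnings(gower_context(X_table)) else NULL

  nodes <- list()
  for (j in seq_len(cover$k)) {
    members <- which(cover$lo[j] <= values & values <= cover$hi[j])
    if (length(members) == 0L) next
    b_eff <- min(params$b, length(members))
    if (params$cluster_method == "kmedoids") {
      D <- if (params$distance == "gower")
        gower_matrix(X_table[members, , drop = FALSE],
                     X_table[members, , drop = FALSE], ctx)
      else as.matrix(stats::dist(X_encoded[members, , drop = FALSE]))
      km <- kmedoids_fit(D, b_eff)
      assignment <- merge_gapless_clusters(D, km$assignment)
      for (ci in sort(unique(assignment))) {
        sel <- which(assignment == ci)
        mem <- members[sel]
        med <- sel[which.min(rowSums(D[sel, sel, drop = FALSE]))]
        nodes[[length(nodes) + 1L]] <- list(
          interval = j, members = mem,
          medoid = members[med],
          representative = NULL)
      }
    } else {
      cl <- with_seed(1L, stats::kmeans(X_encoded[members, , drop = FALSE],
                                        centers = b_eff, nstart = 5L))
      for (ci in sort(unique(cl$cluster))) {
        mem <- members[cl$cluster == ci]
        nodes[[length(nodes) + 1L]] <- list(
          interval = j, members = mem, medoid = NA_integer_,
          representative = cl$centers[ci, ])
      }
    }
  }
  # prune before edges so edges never reference removed nodes
  keep <- vapply(nodes, function(nd) length(nd$members) >= params$min_node_size,
                 logical(1))
  nodes <- nodes[keep]
  if (length(nodes) == 0L)
    stopf("no retained nodes; lower min_node_size")
  for (i in seq_along(nodes)) {
    nodes[[i]]$id <- i
    if (params$cluster_method == "kmedoids")
      nodes[[i]]$representative <- if (params$distance == "gower")
        X_table[nodes[[i]]$medoid, , drop = FALSE]
      else X_encoded[nodes[[i]]$medoid, ]
  }
  edges <- list()
  if (length(nodes) > 1L) {
    for (i in seq_len(length(nodes) - 1L)) {
      for (j in (i + 1L):length(nodes)) {
        shared <- length(intersect(nodes[[i]]$members, nodes[[j]]$members))
        if (shared > 0L)
          edges[[length(edges) + 1L]] <- c(i = i, j = j, shared = shared)
      }
    }
  }
  edges <- if (length(edges)) as.data.frame(do.call(rbind, edges))
           else data.frame(i = integer(0), j = integer(0), shared = integer(0))
  structure(list(nodes = nodes, edges = edges, params = params, cover = cover,
                 filtration = filt, gower_ctx = ctx, n_samples = n),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("<mapper_graph> %d nodes, %d edges (k=%d, o=%.2f, b=%d, min_node_size=%d)\n",
              length(x$nodes), nrow(x$edges), x$params$k, x$params$o,
              x$params$b, x$params$min_node_size))
  invisible(x)
}

#' Assign unseen points to Mapper nodes
#'
#' Computes each point's filtration value, collects the cover intervals
#' containing it (values outside the training range are clamped to the
#' nearest interval), picks within each such interval the retained node
#' whose representative is closest under the graph's distance, and returns
#' up to `max_nodes` nodes ordered by distance. If none of the containing
#' intervals has a retained node, the globally nearest node is used (with
#' a message).
#'
#' @param graph a [build_mapper_graph()] result.
#' @param X_new_table raw data frame of new points.
#' @param X_new_encoded encoded matrix of new points (defaults to
#'   `data.matrix(X_new_table)`).
#' @param max_nodes 1 or 2.
#' @return List (one element per point) of data frames with columns
#'   `node_id`, `distance`.
#' @export
assign_new_points <- function(graph, X_new_table, X_new_encoded = NULL,
                              max_nodes = 2L) {
  stopifnot(inherits(graph, "mapper_graph"), max_nodes %in% c(1L, 2L))
  if (!is.data.frame(X_new_table)) X_new_table <- as.data.frame(X_new_table)
  if (is.null(X_new_encoded)) X_new_encoded <- data.matrix(X_new_table)
  X_new_encoded <- as_matrix(X_new_encoded)
  values <- filtration_apply(graph$filtration, X_new_encoded)
  cover <- graph$cover
  node_intervals <- vapply(graph$nodes, `[[`, integer(1), "interval")
  gower <- graph$params$distance == "gower" &&
    graph$params$cluster_method == "kmedoids"

  dist_to_nodes <- function(i, node_ids) {
    if (gower) {
      reps <- do.call(rbind, lapply(graph$nodes[node_ids], `[[`, "representative"))
      as.numeric(gower_matrix(X_new_table[i, , drop = FALSE], reps, graph$gower_ctx))
    } else {
      reps <- do.call(rbind, lapply(graph$nodes[node_ids], `[[`, "representative"))
      sqrt(colSums((t(reps) - X_new_encoded[i, ])^2))
    }
  }

  lapply(seq_len(nrow(X_new_encoded)), function(i) {
    v <- values[i]
    containing <- which(cover$lo <= v & v <= cover$hi)
    if (length(containing) == 0L)  # clamp out-of-range values
      containing <- if (v < cover$lo[1]) 1L else length(cover$lo)
    cand_ids <- integer(0); cand_d <- numeric(0)
    for (j in containing) {
      in_int <- which(node_intervals == j)
      if (length(in_int) == 0L) next
      d <- dist_to_nodes(i, in_int)
      best <- which.min(d)
      cand_ids <- c(cand_ids, in_int[best]); cand_d <- c(cand_d, d[best])
    }
    if (length(cand_ids) == 0L) {
      message("assign_new_points: no retained node in containing interval(s); using globally nearest node")
      d <- dist_to_nodes(i, seq_along(graph$nodes))
      best <- which.min(d)
      cand_ids <- best; cand_d <- d[best]
    }
    ord <- order(cand_d)[seq_len(min(max_nodes, length(cand_ids)))]
    data.frame(node_id = cand_ids[ord], distance = cand_d[ord])
  })
}

# ---- exports ---------------------------------------------------------------

#' Export a Mapper graph as an edge-list TSV
#'
#' Columns: `node_i`, `node_j`, `shared` (shared-sample count). Isolated
#' nodes are listed in a trailing comment line.
#' @param graph a `mapper_graph`; `path` output file.
#' @export
mapper_edges_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a Mapper graph in DOT format
#'
#' Node size encodes member count; node fill color encodes outcome
#' prevalence when `y` is supplied (white = 0, red = 1).
#' @param graph a `mapper_graph`.
#' @param y optional binary outcome vector aligned with the training rows.
#' @param path output file.
#' @export
mapper_to_dot <- function(graph, y = NULL, path) {
  lines <- c("graph mapper {", "  node [style=filled];")
  for (nd in graph$nodes) {
    prev <- if (is.null(y)) 0 else mean(y[nd$members])
    col <- grDevices::rgb(1, 1 - prev, 1 - prev)
    size <- 0.3 + sqrt(length(nd$members)) / 10
    lines <- c(lines, sprintf(
      "  n%d [label=\"%d (n=%d)\", fillcolor=\"%s\", width=%.2f];",
      nd$id, nd$id, length(nd$members), col, size))
  }
  if (nrow(graph$edges))
    lines <- c(lines, sprintf("  n%d -- n%d [label=\"%d\"];",
                              graph$edges$i, graph$edges$j, graph$edges$shared))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a Mapper graph to an igraph object
#' @param graph a `mapper_graph`.
#' @export
mapper_to_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = length(graph$nodes), directed = FALSE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
  igraph::set_vertex_attr(g, "size",
                          value = vapply(graph$nodes, function(nd)
                            length(nd$members), integer(1)))
}
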