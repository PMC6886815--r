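# Gower metric, covers, filtration, Mapper graph construction, new-point
# assignment, and graph edit distance.

test_that("gower distance follows the range-normalized mixed formula", {
  df <- data.frame(n1 = c(0, 10), c1 = c("a", "b"), stringsAsFactors = FALSE)
  ctx <- gower_context(df)
  expect_equal(gower_distance(df[1, ], df[1, ], ctx), 0)
  # one numeric (range 10, diff 5) + one mismatched categorical -> 0.75
  p <- data.frame(n1 = 5, c1 = "b", stringsAsFactors = FALSE)
  expect_equal(gower_distance(df[1, ], p, ctx), (0.5 + 1) / 2)

  dfc <- data.frame(a = c("x", "y"), b = c("u", "v"), stringsAsFactors = FALSE)
  ctxc <- gower_context(dfc)
  expect_equal(gower_distance(dfc[1, ], dfc[2, ], ctxc), 1)

  expect_warning(gower_context(data.frame(z = c(1, 1))), "zero range")
})

test_that("gower matrix matches cluster::daisy on random mixed data", {
  skip_if_not_installed("cluster")
  tab <- make_mixed_table(35, seed = 17)
  tabf <- tab
  tabf$cat1 <- factor(tabf$cat1)
  tabf$cat2 <- factor(tabf$cat2)
  ours <- gower_matrix(tab, tab, gower_context(tab))
  ref <- as.matrix(cluster::daisy(tabf, metric = "gower"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("covers solve the uniform overlap equation", {
  cv <- build_cover(c(0, 1), k = 2, o = 0.5)
  expect_equal(cv$lo, c(0, 1 / 3), tolerance = 1e-12)
  expect_equal(cv$hi, c(2 / 3, 1), tolerance = 1e-12)
  expect_equal(cv$hi[1] - cv$lo[2], 0.5 * cv$a_I, tolerance = 1e-12)

  cv1 <- build_cover(c(-2, 5), k = 1, o = 0)
  expect_equal(c(cv1$lo, cv1$hi), c(-2, 5))

  cv0 <- build_cover(seq(0, 1, 0.1), k = 4, o = 0)
  expect_equal(cv0$lo[-1], cv0$hi[-4], tolerance = 1e-12)  # shared endpoints only

  # degenerate: constant filter values
  cvd <- build_cover(rep(3, 5), k = 6, o = 0.3)
  expect_equal(cvd$k, 1L)

  # union of memberships covers every sample for random inputs
  withr::with_seed(19, v <- rnorm(200))
  for (k in c(3, 7)) for (o in c(0, 0.25, 0.6)) {
    cvk <- build_cover(v, k, o)
    covered <- rep(FALSE, length(v))
    for (j in seq_len(cvk$k))
      covered <- covered | (cvk$lo[j] <= v & v <= cvk$hi[j])
    expect_true(all(covered))
  }
})

test_that("PCA filtration projects onto the dominant axis deterministically", {
  withr::with_seed(23, {
    t <- runif(100, -2, 2)
    X <- cbind(3 * t, -t) + matrix(rnorm(200, 0, 1e-3), 100, 2)
  })
  f <- pca_filtration_fit(X)
  v <- filtration_apply(f, X)
  expect_gt(abs(cor(v, t)), 0.9999)  # affine in arclength position

  # training filter variance equals the top covariance eigenvalue
  Z <- apply_standardize(f$pca$std, X)
  ev <- eigen(cov(Z), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(var(v), ev[1], tolerance = 1e-8)

  # sign rule: the largest-magnitude loading is positive
  expect_gt(max(f$pca$A), 0)
  f2 <- pca_filtration_fit(-X)
  expect_gt(max(f2$pca$A), 0)

  expect_error(pca_filtration_fit(matrix(1, 5, 2)), "constant")
})

test_that("mapper graphs recover blob, path and ladder structure", {
  withr::with_seed(31, {
    blob <- rbind(matrix(rnorm(120, 0, 0.2), 60, 2),
                  matrix(rnorm(120, 6, 0.2), 60, 2))
  })
  g <- build_mapper_graph(as.data.frame(blob), blob,
                          mapper_params(k = 2, o = 0, b = 1, min_node_size = 1))
  expect_equal(length(g$nodes), 2L)
  expect_equal(nrow(g$edges), 0L)

  u <- data.frame(x = seq(0, 1, length.out = 90))
  gp <- build_mapper_graph(u, as.matrix(u),
                           mapper_params(k = 3, o = 0.5, b = 1, min_node_size = 1,
                                         filtration = "coordinate:1"))
  expect_equal(length(gp$nodes), 3L)
  expect_equal(nrow(gp$edges), 2L)    # path graph

  # every edge shares >= 1 sample; no self-edges; members lie in interval
  for (r in seq_len(nrow(gp$edges))) {
    e <- gp$edges[r, ]
    expect_true(e$i != e$j)
    expect_gte(e$shared, 1)
  }
  vals <- filtration_apply(gp$filtration, as.matrix(u))
  for (nd in gp$nodes) {
    expect_true(all(vals[nd$members] >= gp$cover$lo[nd$interval] - 1e-12))
    expect_true(all(vals[nd$members] <= gp$cover$hi[nd$interval] + 1e-12))
    expect_gte(length(nd$members), gp$params$min_node_size)
  }

  # pruning: raising min_node_size drops nodes, erroring when all gone
  expect_error(build_mapper_graph(u, as.matrix(u),
                                  mapper_params(k = 3, o = 0.5, b = 1,
                                                min_node_size = 91)),
               "min_node_size")
})

test_that("increasing overlap never loses edges (b = 1, fixed data)", {
  withr::with_seed(37, X <- data.frame(x = rnorm(150), y = rnorm(150)))
  edge_counts <- vapply(c(0, 0.2, 0.4, 0.6), function(o) {
    g <- build_mapper_graph(X, as.matrix(X),
                            mapper_params(k = 5, o = o, b = 1, min_node_size = 1))
    nrow(g$edges)
  }, numeric(1))
  expect_true(all(diff(edge_counts) >= 0))
})

test_that("new points are assigned to nearest nodes within their intervals", {
  withr::with_seed(41, X <- data.frame(x = c(rnorm(80, 0), rnorm(80, 10))))
  g <- build_mapper_graph(X, as.matrix(X),
                          mapper_params(k = 2, o = 0.3, b = 1, min_node_size = 1,
                                        filtration = "coordinate:1"))
  # a medoid point maps to its own node at distance 0
  med <- g$nodes[[1]]$medoid
  a <- assign_new_points(g, X[med, , drop = FALSE], max_nodes = 1)
  expect_equal(a[[1]]$node_id, 1L)
  expect_equal(a[[1]]$distance, 0)

  # a point in the overlap region can get two nodes
  ov_lo <- g$cover$lo[2]; ov_hi <- g$cover$hi[1]
  mid <- data.frame(x = (ov_lo + ov_hi) / 2)
  a2 <- assign_new_points(g, mid, max_nodes = 2)
  expect_lte(nrow(a2[[1]]), 2)
  expect_gte(nrow(a2[[1]]), 1)

  # far beyond the training range: clamped into the last interval
  a3 <- assign_new_points(g, data.frame(x = 1e3), max_nodes = 1)
  expect_equal(g$nodes[[a3[[1]]$node_id]]$interval, 2L)
  a4 <- assign_new_points(g, data.frame(x = -1e3), max_nodes = 1)
  expect_equal(g$nodes[[a4[[1]]$node_id]]$interval, 1L)
})

test_that("graph exports write edge lists, DOT and igraph objects", {
  withr::with_seed(43, X <- data.frame(x = rnorm(60), y = rnorm(60)))
  g <- build_mapper_graph(X, as.matrix(X),
                          mapper_params(k = 3, o = 0.4, b = 1, min_node_size = 1))
  tsv <- tempfile(fileext = ".tsv")
  dot <- tempfile(fileext = ".dot")
  mapper_edges_tsv(g, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), nrow(g$edges))
  mapper_to_dot(g, y = rbinom(60, 1, 0.3), path = dot)
  expect_true(any(grepl("graph mapper", readLines(dot))))
  ig <- mapper_to_igraph(g)
  expect_equal(igraph::vcount(ig), length(g$nodes))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
})

test_that("graph edit distance satisfies metric-style basics", {
  tri <- ged_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  path3 <- ged_graph(3, rbind(c(1, 2), c(2, 3)))
  # isomorphic graphs at distance 0 (relabeled path)
  path3b <- ged_graph(3, rbind(c(2, 1), c(1, 3)))
  expect_equal(graph_edit_distance(tri, tri), 0)
  expect_equal(graph_edit_distance(path3, path3b), 0)
  # one extra edge costs 1; triangle vs path costs 1
  expect_equal(graph_edit_distance(tri, path3), 1)
  expect_equal(graph_edit_distance(path3, tri), 1)   # symmetric costs
  # node count difference
  single <- ged_graph(1)
  expect_equal(graph_edit_distance(single, path3), 4)  # 2 nodes + 2 edges

  expect_error(graph_edit_distance(tri, path3,
                                   costs = c(node_ins = -1, node_del = 1,
                                             node_sub = 0, edge_ins = 1,
                                             edge_del = 1)),
               "nonnegative")
  big <- ged_graph(9)
  expect_error(graph_edit_distance(big, tri), "approx")
  expect_gte(graph_edit_distance(big, tri, approx = TRUE), 0)
})
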