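# The morphism contract: fit-by-risk-minimization, application,
# composition, decomposable direct sums, collections, serialization.

test_that("fit and apply satisfy the basic morphism contract", {
  lr <- fit(mlm_linear_regression(), matrix(c(1, 2, 3), 3, 1), c(2, 4, 6))
  expect_equal(unname(lr$params), 2, tolerance = 1e-12)
  expect_equal(mlm_apply(lr, 3), 6)
  expect_equal(predict(lr, matrix(c(1, 10), 2, 1)), c(2, 20))

  expect_error(mlm_apply(mlm_linear_regression(), 3), "fitted")
  expect_error(fit(mlm_linear_regression(), matrix(1, 2, 1), c(1, 2, 3)),
               "length")
  expect_error(fit(mlm_linear_regression(), matrix(1, 2, 1)), "supervised")
  expect_error(fit(mlm_linear_regression(m = 2L), matrix(1, 2, 1), c(1, 2)),
               "dimension")

  # standardization: optimum is column means / sds, fitted unsupervised
  X <- matrix(c(1, 3, 2, 6), 2, 2)
  st <- fit(mlm_standardize(), X)
  expect_equal(unname(st$params$c), c(2, 4))
  expect_equal(unname(st$params$s), c(sqrt(2), sqrt(8)))
  expect_equal(mlm_apply(st, c(5, 4)),
               c((5 - 2) / sqrt(2), (4 - 4) / sqrt(8)))

  # PCA fits with empty outcome realizations
  Xp <- matrix(rnorm(60), 20, 3)
  expect_silent(p <- fit(mlm_pca(c = 2L), Xp))
  expect_true(p$fitted)

  # identity morphism
  id <- fit(mlm_identity(), matrix(1:4, 2, 2))
  expect_identical(mlm_apply(id, matrix(1:4, 2, 2)), matrix(1:4, 2, 2))
})

test_that("fitted parameters minimize the declared risk", {
  withr::with_seed(11, {
    X <- matrix(rnorm(40), 20, 2)
    Y <- as.numeric(X %*% c(1.5, -0.5) + rnorm(20, 0, 0.2))
  })
  lr <- fit(mlm_linear_regression(), X, Y)
  r_star <- lr$risk(lr$params, X, Y)
  for (probe in list(c(0, 0), c(1.5, -0.5), c(2, 1), c(-1, 3)))
    expect_lte(r_star, lr$risk(probe, X, Y) + 1e-8)

  st <- fit(mlm_standardize(), X)
  r_star <- st$risk(st$params, X, NULL)
  for (dc in c(-0.3, 0, 0.4)) for (ds in c(0.8, 1, 1.3)) {
    probe <- list(c = st$params$c + dc, s = st$params$s * ds)
    expect_lte(r_star, st$risk(probe, X, NULL) + 1e-8)
  }
})

test_that("closed-form fits agree with a brute-force grid minimizer", {
  # 1-parameter least squares vs the generic uniform-box grid solver
  X <- matrix(c(1, 2, 4), 3, 1)
  Y <- c(2.2, 3.9, 8.1)
  closed <- fit(mlm_linear_regression(), X, Y)
  gridded <- new_mlm("lr_grid", mlm_space("continuous", 1L),
                     mlm_space("continuous", 1L),
                     morphism = function(x, p) as.numeric(as.matrix(x) %*% p),
                     risk = function(p, X, Y) sum((Y - X %*% p)^2),
                     prior = mlm_prior("uniform-box", lower = 0, upper = 4,
                                       grid_n = 4001L))
  gridded <- fit(gridded, X, Y)
  expect_equal(unname(gridded$params), unname(closed$params),
               tolerance = 4 / 4000)
})

test_that("sequential composition equals manual chaining and is associative", {
  withr::with_seed(5, {
    X <- matrix(rnorm(60), 30, 2)
    Y <- as.numeric(X %*% c(2, -1) + rnorm(30, 0, 0.1))
  })
  comp <- fit(compose_mlm(mlm_linear_regression(), mlm_standardize()), X, Y)
  st <- fit(mlm_standardize(), X)
  Z <- mlm_apply(st, X)
  lr <- fit(mlm_linear_regression(), Z, Y)
  expect_equal(mlm_apply(comp, X), mlm_apply(lr, Z), tolerance = 1e-12)

  # composed form is (x - c) diag(s)^-1 . p
  x0 <- X[7, ]
  expect_equal(mlm_apply(comp, x0),
               sum((x0 - st$params$c) / st$params$s * lr$params),
               tolerance = 1e-12)

  # identity is neutral
  f_id <- fit(compose_mlm(mlm_linear_regression(), mlm_identity()), X, Y)
  f <- fit(mlm_linear_regression(), X, Y)
  expect_equal(mlm_apply(f_id, X), mlm_apply(f, X), tolerance = 1e-12)

  # associativity under sequential fitting
  h_gf <- fit(compose_mlm(mlm_linear_regression(),
                          compose_mlm(mlm_standardize(), mlm_identity())), X, Y)
  hg_f <- fit(compose_mlm(compose_mlm(mlm_linear_regression(), mlm_standardize()),
                          mlm_identity()), X, Y)
  expect_equal(mlm_apply(h_gf, X), mlm_apply(hg_f, X), tolerance = 1e-12)

  expect_error(compose_mlm(mlm_linear_regression(m = 3L), mlm_pca(c = 2L, m = 5L)),
               "mismatch")
})

test_that("joint composition grid search finds the product-grid minimizer", {
  X <- matrix(c(1, 2, 3, 4), 4, 1)
  Y <- c(3, 6, 9, 12)   # truth: combined slope 3
  scale_m <- new_mlm("scale", mlm_space("continuous", 1L),
                     mlm_space("continuous", 1L),
                     morphism = function(x, p) as.matrix(x) * p,
                     risk = function(p, X, Y) 0,
                     prior = mlm_prior("uniform-box", 0.5, 2.5, grid_n = 5L),
                     supervised = FALSE)
  lr_m <- new_mlm("slope", mlm_space("continuous", 1L),
                  mlm_space("continuous", 1L),
                  morphism = function(x, p) as.numeric(as.matrix(x) * p),
                  risk = function(p, X, Y) sum((Y - as.matrix(X) * p)^2),
                  prior = mlm_prior("uniform-box", 0, 4, grid_n = 9L))
  joint <- fit(compose_mlm(lr_m, scale_m, mode = "joint"), X, Y)
  # independent exhaustive search over the same grids
  g1 <- seq(0.5, 2.5, length.out = 5)
  g2 <- seq(0, 4, length.out = 9)
  vals <- outer(g1, g2, Vectorize(function(p1, p2) sum((Y - X * p1 * p2)^2)))
  best <- arrayInd(which.min(vals), dim(vals))
  expect_equal(unname(joint$params$inner * joint$params$outer),
               g1[best[1]] * g2[best[2]], tolerance = 1e-12)
})

test_that("direct sums fit members independently (decomposable risk)", {
  # orthogonal design: X columns [1,1] and [1,-1], Y = [3,1]
  X <- matrix(c(1, 1, 1, -1), 2, 2)
  Y <- c(3, 1)
  full <- fit_linear_regression(X, Y)
  expect_equal(full, c(2, 1), tolerance = 1e-12)   # hand normal equations

  ds <- direct_sum_mlm(mlm_linear_regression(m = 1L), mlm_linear_regression(m = 1L))
  fitted <- fit(ds, X, Y)
  expect_equal(unname(c(fitted$params$p1, fitted$params$p2)), c(2, 1),
               tolerance = 1e-12)
  # joint risk at the independent fits is a*R1 + b*R2 with a = b = 1
  r1 <- sum((Y - X[, 1] * 2)^2)
  r2 <- sum((Y - X[, 2] * 1)^2)
  expect_equal(fitted$risk(fitted$params, X, Y), r1 + r2, tolerance = 1e-12)

  # same member on the same data: both halves identical
  X2 <- cbind(c(1, 2, 3), c(1, 2, 3))
  f2 <- fit(direct_sum_mlm(mlm_linear_regression(m = 1L),
                           mlm_linear_regression(m = 1L)), X2, c(2, 4, 6))
  expect_equal(f2$params$p1, f2$params$p2)

  expect_error(direct_sum_mlm(mlm_linear_regression(m = 1L), mlm_threshold()),
               "output space")
})

test_that("collections evaluate members in order and break ties low", {
  X <- matrix(c(0.1, 0.4, 0.35, 0.8), 4, 1)
  y <- c(0, 0, 1, 1)
  good <- fit(mlm_linear_regression(), X, as.numeric(y))
  bad <- good
  bad$params <- -bad$params
  expect_error(mlm_collection(list()), "at least one")

  coll1 <- mlm_collection(list(good))
  s1 <- evaluate_collection(coll1, "auc", X, y)
  expect_length(s1, 1)
  expect_equal(select_best(coll1, "auc", X, y)$index, 1L)

  coll <- mlm_collection(list(bad, good))
  s <- evaluate_collection(coll, "auc", X, y)
  expect_true(s[2] > s[1])
  expect_equal(select_best(coll, "auc", X, y)$index, 2L)

  # exact tie goes to the lowest index
  tie <- mlm_collection(list(good, good))
  expect_equal(select_best(tie, "auc", X, y)$index, 1L)
})

test_that("morphisms round-trip through JSON", {
  X <- matrix(rnorm(40), 20, 2)
  Y <- as.numeric(X %*% c(1, 2))
  for (proto in list(fit(mlm_linear_regression(), X, Y),
                     fit(mlm_standardize(), X),
                     fit(mlm_pca(c = 1L), X))) {
    back <- mlm_from_json(mlm_to_json(proto))
    expect_true(back$fitted)
    expect_equal(as.numeric(mlm_apply(back, X)), as.numeric(mlm_apply(proto, X)),
                 tolerance = 1e-10, label = proto$kind)
  }
  thr <- fit(mlm_threshold(), matrix(c(.1, .2, .8, .9)), c(0, 0, 1, 1))
  thr_back <- mlm_from_json(mlm_to_json(thr))
  scores <- matrix(c(0.05, 0.45, 0.55, 0.95))
  expect_equal(mlm_apply(thr_back, scores), mlm_apply(thr, scores))
})
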