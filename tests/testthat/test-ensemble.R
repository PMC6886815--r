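# Node models, convex weighting, ensemble prediction, workflow fitting.

small_cohort <- function(n = 300, seed = 1) {
  generate_mixed_imbalanced(cohort_spec(n = n, minority_frac = 0.3, seed = seed))
}

test_that("fit_node_models trains one model per retained node", {
  coh <- small_cohort(300, seed = 2)
  enc <- fit_encoder(coh$X_table)
  Xe <- encode(enc, coh$X_table)
  g <- build_mapper_graph(coh$X_table, Xe,
                          mapper_params(k = 3, o = 0.3, b = 2, min_node_size = 20))
  nms <- suppressWarnings(fit_node_models(g, Xe, coh$y, node_pipeline(),
                                          cv_folds = 5, seed = 3))
  expect_length(nms, length(g$nodes))
  for (nm in nms) {
    expect_gte(nm$cv_auc, 0); expect_lte(nm$cv_auc, 1)
    p <- mlmapper:::node_model_predict(nm, Xe[1:5, ])
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("node models on planted flipped-effect groups recover the signs", {
  spec <- cohort_spec(n = 1200, minority_frac = 0.3, seed = 11)
  coh <- generate_mixed_imbalanced(spec)
  enc <- fit_encoder(coh$X_table)
  Xe <- encode(enc, coh$X_table)
  g <- build_mapper_graph(coh$X_table, Xe,
                          mapper_params(k = 2, o = 0.1, b = 1, min_node_size = 40))
  nms <- suppressWarnings(fit_node_models(g, Xe, coh$y, node_pipeline(),
                                          cv_folds = 5, seed = 7))
  # the two dominant nodes align with the two groups; their logistic
  # coefficients on the effect features must carry the group's sign
  eff_idx <- which(spec$base_coefs != 0)
  eff_names <- paste0("num", eff_idx)
  for (nm in nms) {
    members <- g$nodes[[nm$node_id]]$members
    gmaj <- as.integer(names(which.max(table(coh$group[members]))))
    expected <- spec$effect_flip[gmaj] * spec$base_coefs[eff_idx]
    co <- stats::coef(nm$model$glm)[eff_names]
    expect_equal(unname(sign(co)), unname(sign(expected)),
                 label = sprintf("node %d (group %d)", nm$node_id, gmaj))
  }
})

test_that("compute_weights implements the convex schemes", {
  one <- data.frame(node_id = 1L, distance = 0.2)
  two <- data.frame(node_id = c(1L, 2L), distance = c(0.1, 0.3))
  expect_equal(compute_weights(one, "closest"), 1)
  expect_equal(compute_weights(two, "closest"), c(1, 0))
  expect_equal(compute_weights(two, "equal"), c(0.5, 0.5))
  wid <- compute_weights(two, "inverse_distance")
  expect_equal(wid, (1 / (two$distance + 1e-9)) / sum(1 / (two$distance + 1e-9)))
  expect_equal(sum(wid), 1)

  fake_models <- list(list(node_id = 1L, cv_auc = 0.8),
                      list(node_id = 2L, cv_auc = 0.6))
  expect_equal(compute_weights(two, "auc_proportional", fake_models),
               c(4 / 7, 3 / 7))
  expect_error(compute_weights(two, "cv_trained"), "not implemented")
  expect_error(compute_weights(two[0, ], "equal"), "empty")
})

test_that("ensemble probabilities are convex combinations of node outputs", {
  coh <- small_cohort(400, seed = 5)
  cfg <- workflow_config(mapper = list(params = mapper_params(k = 3, o = 0.4,
                                                              b = 2,
                                                              min_node_size = 30)),
                         cv_folds = 5)
  wf <- suppressWarnings(fit_workflow(coh$X_table, coh$y, cfg, seed = 9))
  new <- small_cohort(150, seed = 6)
  res <- ensemble_predict_proba(wf, new$X_table, return_details = TRUE)
  expect_length(res$proba, 150)
  for (i in seq_along(res$details)) {
    d <- res$details[[i]]
    expect_equal(sum(d$weights), 1, tolerance = 1e-12)
    expect_true(all(d$weights >= 0))
    expect_lte(length(d$weights), wf$max_nodes)
    expect_gte(res$proba[i] + 1e-12, min(d$node_probs))
    expect_lte(res$proba[i] - 1e-12, max(d$node_probs))
  }
})

test_that("workflow grid search keeps the first best point and thresholds pooled scores", {
  coh <- small_cohort(350, seed = 8)
  cfg <- workflow_config(
    mapper = list(grid = list(k = c(2, 3), o = 0.3, b = 2), min_node_size = 30),
    cv_folds = 5)
  wf <- suppressWarnings(fit_workflow(coh$X_table, coh$y, cfg, seed = 4))
  gr <- wf$grid_results
  expect_equal(nrow(gr), 2)
  best_score <- max(gr$score, na.rm = TRUE)
  expect_equal(gr$score[gr$k == wf$graph$params$k][1], best_score)
  # first maximum wins in iteration order
  expect_equal(which(gr$score == best_score)[1],
               which(gr$k == wf$graph$params$k & gr$o == wf$graph$params$o &
                     gr$b == wf$graph$params$b)[1])
  expect_gte(wf$threshold$T, 0)
  expect_lte(wf$threshold$T, 1)
  expect_error(fit_workflow(coh$X_table, coh$y,
                            workflow_config(mapper = list(grid = list(k = integer(0),
                                                                      o = 0.3, b = 2)))),
               "empty")
})

test_that("thresholded prediction is boundary inclusive and monotone", {
  coh <- small_cohort(250, seed = 12)
  cfg <- workflow_config(mapper = list(enabled = FALSE), cv_folds = 5)
  wf <- suppressWarnings(fit_workflow(coh$X_table, coh$y, cfg, seed = 2))
  p <- ensemble_predict_proba(wf, coh$X_table)
  lab <- predict(wf, coh$X_table)
  expect_equal(lab, threshold_apply(p, wf$threshold$T))
  # boundary: a probability exactly at T predicts 1
  expect_equal(threshold_apply(wf$threshold$T, wf$threshold$T), 1L)
  # monotone in T: raising T never turns a 0 into a 1
  for (Tup in c(wf$threshold$T + 0.1, 0.9)) {
    expect_true(all(threshold_apply(p, Tup) <= lab))
  }
})

test_that("samplers see training folds only, never validation rows", {
  withr::with_seed(51, {
    X <- cbind(id = 1:120, matrix(rnorm(240), 120, 2))
    y <- rbinom(120, 1, 0.4)
  })
  seen_train_ids <- list()
  spy <- function(Xtr, ytr, seed) {
    seen_train_ids[[length(seen_train_ids) + 1L]] <<- Xtr[, 1]
    list(X = Xtr, y = ytr)
  }
  tuned <- mlmapper:::cv_tune_classifier("logistic", X, y, cv_folds = 4,
                                         sampler = spy, seed = 3)
  # the last spy call is the full-data refit; fold calls precede it
  fold_calls <- seen_train_ids[seq_len(length(seen_train_ids) - 1L)]
  expect_length(fold_calls, 4L)
  for (ids in fold_calls) {
    val_ids <- setdiff(X[, 1], ids)
    expect_gt(length(val_ids), 0)
    expect_length(intersect(ids, val_ids), 0)
  }
  # every row is validation exactly once across folds
  all_val <- unlist(lapply(fold_calls, function(ids) setdiff(X[, 1], ids)))
  expect_setequal(all_val, X[, 1])
  expect_equal(anyDuplicated(all_val), 0)
})

test_that("workflows persist to disk and reload", {
  coh <- small_cohort(200, seed = 14)
  cfg <- workflow_config(mapper = list(params = mapper_params(k = 2, o = 0.3, b = 1,
                                                              min_node_size = 20)),
                         cv_folds = 4)
  wf <- suppressWarnings(fit_workflow(coh$X_table, coh$y, cfg, seed = 6))
  dir <- tempfile("wf")
  workflow_save(wf, dir)
  expect_true(file.exists(file.path(dir, "workflow.json")))
  wf2 <- workflow_load(dir)
  expect_equal(ensemble_predict_proba(wf2, coh$X_table[1:20, ]),
               ensemble_predict_proba(wf, coh$X_table[1:20, ]))
})
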