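# The flagship workflow: one-hot encoder, Mapper partition of the training
# data, a tuned classifier pipeline per retained node, convex node
# weighting of the node probabilities, and a decision threshold fitted on
# pooled cross-validation hold-out scores. Mapper parameters are selected
# by grid search on mean CV hold-out AUC.

#' Node pipeline specification
#'
#' @param classifier classifier family for the node models.
#' @param sampler `"none"`, `"smote"`, `"rose"`, or a
#'   `function(X, y, seed) -> list(X, y)`; applied to CV training folds
#'   only, never to validation folds.
#' @param use_pca project node data onto principal components first.
#' @param pca_dims PCA target dimension (capped at the node's column count).
#' @param hyper_grid optional list of hyperparameter lists.
#' @export
node_pipeline <- function(classifier = "logistic", sampler = "none",
                          use_pca = FALSE, pca_dims = 2L, hyper_grid = NULL) {
  structure(list(classifier = match.arg(classifier, classifier_kinds),
                 sampler = sampler, use_pca = isTRUE(use_pca),
                 pca_dims = as.integer(pca_dims), hyper_grid = hyper_grid),
            class = "node_pipeline")
}

#' Workflow configuration
#'
#' Defaults mirror the protocol the package's evaluation module assumes:
#' Mapper with a first-principal-component filtration and Gower metric,
#' grid `k` in 5..20, `o` in 0.2..0.6, `b` in 5..30, minimum node size 40,
#' 10-fold CV, equal weights over at most two assigned nodes, Youden
#' threshold. Pass `mapper = list(enabled = FALSE)` for a single global
#' pipeline, or `mapper = list(params = mapper_params(...))` to skip the
#' grid search.
#'
#' @param mapper,node_pipeline,weights,threshold,cv_folds overrides merged
#'   into the defaults.
#' @export
workflow_config <- function(mapper = list(), node_pipeline = NULL,
                            weights = list(), threshold = list(),
                            cv_folds = 10L) {
  if (is.null(node_pipeline)) node_pipeline <- mlmapper::node_pipeline()
  m_def <- list(enabled = TRUE, params = NULL,
                grid = list(k = 5:20, o = seq(0.2, 0.6, by = 0.1),
                            b = seq(5L, 30L, by = 5L)),
                min_node_size = 40L, filtration = "pca", distance = "gower",
                cluster_method = "kmedoids")
  w_def <- list(scheme = "equal", max_nodes = 2L)
  t_def <- list(criterion = "youden")
  structure(list(mapper = utils::modifyList(m_def, mapper),
                 node_pipeline = node_pipeline,
                 weights = utils::modifyList(w_def, weights),
                 threshold = utils::modifyList(t_def, threshold),
                 cv_folds = as.integer(cv_folds)),
            class = "workflow_config")
}

# Fit one node pipeline (optional PCA + CV-tuned classifier) on rows X, y.
fit_one_node_model <- function(node_id, X, y, spec, cv_folds, seed) {
  pca <- NULL
  if (spec$use_pca) {
    dims <- min(spec$pca_dims, ncol(X))
    pca <- suppressWarnings(fit_pca(X, dims))
    X <- pca_project(pca, X)
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    warnf("node %d has a single class; using a constant-prior predictor", node_id)
    return(structure(list(node_id = node_id, spec = spec, pca = pca,
                          model = list(kind = spec$classifier, constant = mean(y)),
                          cv_auc = 0.5, hyper = NULL,
                          pooled = data.frame(score = numeric(0), label = integer(0))),
                     class = "node_model"))
  }
  tuned <- cv_tune_classifier(spec$classifier, X, y, spec$hyper_grid, cv_folds,
                              sampler = resolve_sampler(spec$sampler), seed = seed)
  structure(list(node_id = node_id, spec = spec, pca = pca,
                 model = tuned$model, cv_auc = tuned$cv_auc,
                 hyper = tuned$hyper, pooled = tuned$pooled),
            class = "node_model")
}

node_model_predict <- function(nm, X) {
  X <- as_matrix(X)
  if (!is.null(nm$pca)) X <- pca_project(nm$pca, X)
  predict_classifier(nm$model, X)
}

#' Fit one model pipeline per retained Mapper node
#'
#' Each node's model is trained only on that node's member samples.
#' Hyperparameters are tuned by stratified `cv_folds`-fold CV maximizing
#' hold-out AUC (folds reduced with a message when a node is smaller);
#' any sampler is applied to training folds only. Nodes whose members are
#' single-class get a constant-prior fallback.
#'
#' @param graph a [build_mapper_graph()] result.
#' @param X encoded numeric matrix of all training samples.
#' @param y binary 0/1 outcome vector.
#' @param pipeline_spec a [node_pipeline()].
#' @param cv_folds folds (default 10).
#' @param seed integer seed.
#' @return List of `node_model` objects, one per retained node, each with
#'   its mean CV hold-out AUC (`cv_auc`) and pooled hold-out scores.
#' @export
fit_node_models <- function(graph, X, y, pipeline_spec = node_pipeline(),
                            cv_folds = 10L, seed = 1L) {
  stopifnot(inherits(graph, "mapper_graph"))
  X <- as_matrix(X)
  lapply(graph$nodes, function(nd) {
    fit_one_node_model(nd$id, X[nd$members, , drop = FALSE], y[nd$members],
                       pipeline_spec, cv_folds, child_seed(seed, nd$id))
  })
}

#' Convex node weights for one prediction
#'
#' @param assignments data frame (`node_id`, `distance`) ordered by
#'   distance, as produced by [assign_new_points()].
#' @param scheme `"closest"`, `"equal"`, `"inverse_distance"`,
#'   `"auc_proportional"` (weights `AUC_i / (AUC_i + AUC_j)` over the
#'   assigned pair), or the unimplemented `"cv_trained"` stub.
#' @param node_models list of `node_model`s (needed for
#'   `auc_proportional`).
#' @return Nonnegative weights summing to 1, one per assignment row.
#' @export
compute_weights <- function(assignments, scheme, node_models = NULL) {
  m <- nrow(assignments)
  if (is.null(m) || m == 0L) stopf("compute_weights: empty assignment")
  w <- switch(scheme,
    closest = c(1, rep(0, m - 1L)),
    equal = rep(1 / m, m),
    inverse_distance = {
      raw <- 1 / (assignments$distance + 1e-9)
      raw / sum(raw)
    },
    auc_proportional = {
      aucs <- vapply(assignments$node_id, function(id) {
        nm <- node_models[[which(vapply(node_models, `[[`, integer(1), "node_id") == id)]]
        nm$cv_auc
      }, numeric(1))
      if (sum(aucs) == 0) rep(1 / m, m) else aucs / sum(aucs)
    },
    cv_trained = stopf("weight scheme 'cv_trained' is an interface stub and is not implemented"),
    stopf("unknown weight scheme '%s'", scheme))
  w
}

#' Fit the full ensemble workflow
#'
#' Encodes the data, grid-searches the Mapper parameters (scoring each
#' grid point by the unweighted mean of its node models' CV hold-out AUCs;
#' ties go to the first grid point in iteration order, `k` varying
#' fastest), fits per-node pipelines for the winning configuration, and
#' fits the decision threshold on the pooled CV hold-out scores. With
#' `mapper$enabled = FALSE` the workflow degenerates to a single global
#' pipeline.
#'
#' @param X_table raw mixed-type training data frame.
#' @param y binary 0/1 outcome vector.
#' @param config a [workflow_config()].
#' @param seed integer seed for all internal randomness.
#' @param column_spec optional encoder sidecar.
#' @return Object of class `ensemble_workflow`.
#' @export
fit_workflow <- function(X_table, y, config = workflow_config(), seed = 1L,
                         column_spec = NULL) {
  stopifnot(inherits(config, "workflow_config"))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stopf("fit_workflow: y must be binary 0/1")
  enc <- fit_encoder(X_table, column_spec)
  Xe <- encode(enc, X_table)
  mp <- config$mapper

  if (!isTRUE(mp$enabled)) {
    nm <- fit_one_node_model(1L, Xe, y, config$node_pipeline, config$cv_folds,
                             child_seed(seed, 1L))
    thr <- fit_threshold_pooled(list(nm), config$threshold$criterion)
    return(structure(list(encoder = enc, graph = NULL, node_models = list(nm),
                          weight_scheme = config$weights$scheme,
                          max_nodes = config$weights$max_nodes,
                          threshold = thr, config = config, seed = seed,
                          grid_results = NULL),
                     class = "ensemble_workflow"))
  }

  grid <- if (!is.null(mp$params)) {
    p <- mp$params
    data.frame(k = p$k, o = p$o, b = p$b)
  } else {
    if (length(mp$grid$k) == 0L) stopf("fit_workflow: empty Mapper grid")
    expand.grid(k = mp$grid$k, o = mp$grid$o, b = mp$grid$b,
                KEEP.OUT.ATTRS = FALSE)
  }
  best <- NULL
  results <- data.frame(k = grid$k, o = grid$o, b = grid$b,
                        score = NA_real_, nodes = NA_integer_)
  for (gidx in seq_len(nrow(grid))) {
    params <- mapper_params(k = grid$k[gidx], o = grid$o[gidx], b = grid$b[gidx],
                            min_node_size = mp$min_node_size,
                            filtration = mp$filtration, distance = mp$distance,
                            cluster_method = mp$cluster_method)
    graph <- tryCatch(build_mapper_graph(X_table, Xe, params),
                      error = function(e) NULL)
    if (is.null(graph)) next
    nms <- suppressWarnings(
      fit_node_models(graph, Xe, y, config$node_pipeline, config$cv_folds, seed))
    score <- mean(vapply(nms, `[[`, numeric(1), "cv_auc"))
    results$score[gidx] <- score
    results$nodes[gidx] <- length(graph$nodes)
    if (is.null(best) || score > best$score)   # strict >: first maximum wins
      best <- list(score = score, graph = graph, node_models = nms,
                   params = params)
  }
  if (is.null(best))
    stopf("fit_workflow: no Mapper grid point produced retained nodes")
  thr <- fit_threshold_pooled(best$node_models, config$threshold$criterion)
  structure(list(encoder = enc, graph = best$graph,
                 node_models = best$node_models,
                 weight_scheme = config$weights$scheme,
                 max_nodes = config$weights$max_nodes,
                 threshold = thr, config = config, seed = seed,
                 grid_results = results),
            class = "ensemble_workflow")
}

# Threshold on the pooled CV hold-out scores of all node models; falls
# back to T = 0.5 (with a warning from threshold_fit) on degenerate pools.
fit_threshold_pooled <- function(node_models, criterion) {
  pooled <- do.call(rbind, lapply(node_models, `[[`, "pooled"))
  pooled <- pooled[stats::complete.cases(pooled), , drop = FALSE]
  if (is.null(pooled) || nrow(pooled) == 0L) {
    warnf("no pooled CV scores available; threshold defaults to 0.5")
    return(structure(list(T = 0.5), class = "threshold_params"))
  }
  suppressWarnings(threshold_fit(pooled$score, pooled$label, criterion))
}

#' @export
print.ensemble_workflow <- function(x, ...) {
  cat(sprintf("<ensemble_workflow> %s | %d node model(s) | weights=%s | T=%.3f\n",
              if (is.null(x$graph)) "mapper off"
              else sprintf("mapper k=%d o=%.2f b=%d", x$graph$params$k,
                           x$graph$params$o, x$graph$params$b),
              length(x$node_models), x$weight_scheme, x$threshold$T))
  invisible(x)
}

#' Ensemble class-1 probabilities
#'
#' For each point: assign up to `max_nodes` Mapper nodes, compute convex
#' weights under the workflow's scheme, and return the weighted sum of the
#' node models' probabilities (a convex combination, hence in `[0, 1]`).
#'
#' @param workflow a fitted [fit_workflow()] object.
#' @param X_new data frame of new points.
#' @param return_details also return per-point weights and node
#'   probabilities (used by the package's convexity tests).
#' @return Probability vector, or a list with `proba` and `details`.
#' @export
ensemble_predict_proba <- function(workflow, X_new, return_details = FALSE) {
  stopifnot(inherits(workflow, "ensemble_workflow"))
  Xe <- encode(workflow$encoder, X_new)
  n <- nrow(Xe)
  if (is.null(workflow$graph)) {
    p <- node_model_predict(workflow$node_models[[1L]], Xe)
    if (!return_details) return(p)
    return(list(proba = p,
                details = lapply(seq_len(n), function(i)
                  list(weights = 1, node_probs = p[i]))))
  }
  assigns <- assign_new_points(workflow$graph, X_new, Xe, workflow$max_nodes)
  node_ids <- vapply(workflow$node_models, `[[`, integer(1), "node_id")
  # batch per-node predictions over the points assigned to each node
  need <- lapply(seq_along(node_ids), function(j)
    which(vapply(assigns, function(a) node_ids[j] %in% a$node_id, logical(1))))
  probs_by_node <- vector("list", length(node_ids))
  for (j in seq_along(node_ids)) {
    if (length(need[[j]]))
      probs_by_node[[j]] <- stats::setNames(
        node_model_predict(workflow$node_models[[j]], Xe[need[[j]], , drop = FALSE]),
        need[[j]])
  }
  out <- numeric(n)
  details <- if (return_details) vector("list", n)
  for (i in seq_len(n)) {
    a <- assigns[[i]]
    w <- compute_weights(a, workflow$weight_scheme, workflow$node_models)
    p_i <- vapply(seq_len(nrow(a)), function(r) {
      j <- which(node_ids == a$node_id[r])
      probs_by_node[[j]][[as.character(i)]]
    }, numeric(1))
    out[i] <- sum(w * p_i)
    if (return_details) details[[i]] <- list(weights = w, node_probs = p_i)
  }
  if (return_details) list(proba = out, details = details) else out
}

#' Predict binary labels with the fitted workflow
#'
#' Applies the fitted decision threshold (boundary inclusive: probability
#' exactly at the threshold yields 1) to the ensemble probabilities.
#'
#' @param object a fitted `ensemble_workflow`; `newdata` a data frame.
#' @param ... unused.
#' @return Integer vector in `{0, 1}`.
#' @export
predict.ensemble_workflow <- function(object, newdata, ...) {
  threshold_apply(ensemble_predict_proba(object, newdata), object$threshold$T)
}

#' Persist a fitted workflow
#'
#' Writes a JSON manifest (configuration, threshold, Mapper parameters,
#' encoder levels) plus one binary blob per node model under `dir`.
#'
#' @param workflow fitted `ensemble_workflow`; `dir` output directory.
#' @export
workflow_save <- function(workflow, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    threshold = workflow$threshold$T,
    weight_scheme = workflow$weight_scheme,
    max_nodes = workflow$max_nodes,
    mapper = if (is.null(workflow$graph)) NULL else
      workflow$graph$params[c("k", "o", "b", "min_node_size")],
    encoder = workflow$encoder$columns,
    n_node_models = length(workflow$node_models))
  jsonlite::write_json(manifest, file.path(dir, "workflow.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(workflow, file.path(dir, "workflow.rds"))
  for (i in seq_along(workflow$node_models))
    saveRDS(workflow$node_models[[i]], file.path(dir, sprintf("node_model_%03d.rds", i)))
  invisible(dir)
}

#' Reload a persisted workflow
#' @param dir directory written by [workflow_save()].
#' @export
workflow_load <- function(dir) readRDS(file.path(dir, "workflow.rds"))
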