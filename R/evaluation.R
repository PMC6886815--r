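# Metrics and the repeated stratified-holdout protocol: ROC AUC by the
# rank (Mann-Whitney) statistic with midranks for ties, threshold metrics
# at a boundary-inclusive cut, and paired workflow comparison tables.

#' Binary classification metrics
#'
#' AUC is the Mann-Whitney statistic computed from midranks (ties counted
#' half); sensitivity, specificity and accuracy are evaluated at threshold
#' `T` with the boundary-inclusive rule (`score >= T` predicts 1).
#'
#' @param y_true binary 0/1 labels (both classes must be present).
#' @param scores probability scores.
#' @param T decision threshold (default 0.5).
#' @return List with `roc_auc`, `sensitivity`, `specificity`, `accuracy`.
#' @export
binary_metrics <- function(y_true, scores, T = 0.5) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores))
    stopf("binary_metrics: length mismatch")
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("roc_auc undefined: y_true contains a single class")
  r <- rank(scores)   # midranks for ties
  auc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= T)
  tp <- sum(pred == 1L & y_true == 1L); fn <- n1 - tp
  tn <- sum(pred == 0L & y_true == 0L); fp <- n0 - tn
  list(roc_auc = auc,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(y_true))
}

#' Stratified repeated-holdout splits
#'
#' The test set has exactly `floor((1 - train_frac) * n)` samples,
#' apportioned over the classes by largest remainder so both classes
#' appear in every split; run `r` uses seed `base_seed + r`.
#'
#' @param y binary outcome vector.
#' @param n_runs number of splits; `train_frac` training fraction;
#'   `base_seed` integer seed.
#' @return List of `n_runs` lists with integer `train` and `test` indices.
#' @export
holdout_splits <- function(y, n_runs = 10L, train_frac = 0.8, base_seed = 1L) {
  y <- as.integer(y)
  n <- length(y)
  n_test <- floor((1 - train_frac) * n)
  classes <- sort(unique(y))
  quota <- n_test * (vapply(classes, function(c) sum(y == c), numeric(1)) / n)
  take <- floor(quota)
  rem <- n_test - sum(take)
  if (rem > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  lapply(seq_len(n_runs), function(r) {
    with_seed(base_seed + r, {
      test <- unlist(Map(function(cls, k) {
        idx <- which(y == cls)
        idx[sample.int(length(idx), k)]
      }, classes, take))
      test <- sort(test)
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
}

metric_names <- c("roc_auc", "sensitivity", "specificity", "accuracy")

#' Repeated stratified holdout evaluation of one workflow
#'
#' Fits the workflow on each training split and evaluates on the held-out
#' test split at the workflow's own fitted threshold; reports mean and
#' sample (n-1) standard deviation of ROC AUC, sensitivity, specificity
#' and accuracy over the runs.
#'
#' @param X_table data frame; `y` binary outcome.
#' @param workflow_config a [workflow_config()].
#' @param n_runs split count (default 10); `train_frac` training fraction
#'   (default 0.8); `base_seed` seed shared across workflows for paired
#'   comparisons.
#' @param name row label; `splits` optional precomputed
#'   [holdout_splits()] (used by [compare_workflows()] to pair rows).
#' @param column_spec optional encoder sidecar.
#' @return One-row data frame (a `MetricsTable` row): split sizes plus
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
repeated_holdout <- function(X_table, y, workflow_config, n_runs = 10L,
                             train_frac = 0.8, base_seed = 1L,
                             name = "workflow", splits = NULL,
                             column_spec = NULL) {
  y <- as.integer(y)
  if (is.null(splits)) splits <- holdout_splits(y, n_runs, train_frac, base_seed)
  vals <- matrix(NA_real_, length(splits), length(metric_names),
                 dimnames = list(NULL, metric_names))
  for (r in seq_along(splits)) {
    t0 <- proc.time()[["elapsed"]]
    tr <- splits[[r]]$train; te <- splits[[r]]$test
    wf <- suppressWarnings(
      fit_workflow(X_table[tr, , drop = FALSE], y[tr], workflow_config,
                   seed = child_seed(base_seed, r), column_spec = column_spec))
    proba <- ensemble_predict_proba(wf, X_table[te, , drop = FALSE])
    m <- binary_metrics(y[te], proba, wf$threshold$T)
    vals[r, ] <- unlist(m)[metric_names]
    message(sprintf("[%s] run %d/%d: AUC %.3f (%.1fs)", name, r, length(splits),
                    m$roc_auc, proc.time()[["elapsed"]] - t0))
  }
  if (length(splits) == 1L)
    warnf("repeated_holdout: single run; standard deviations reported as 0")
  sds <- if (length(splits) == 1L) rep(0, length(metric_names))
         else apply(vals, 2L, stats::sd)
  out <- data.frame(workflow = name,
                    n_train = length(splits[[1L]]$train),
                    n_test = length(splits[[1L]]$test),
                    n_runs = length(splits))
  for (i in seq_along(metric_names)) {
    out[[paste0(metric_names[i], "_mean")]] <- mean(vals[, i])
    out[[paste0(metric_names[i], "_sd")]] <- sds[i]
  }
  out
}

#' Compare workflows under shared splits
#'
#' Runs [repeated_holdout()] for every named configuration with the same
#' split indices (a paired comparison), one table row per configuration.
#'
#' @param configs named list of [workflow_config()] objects (duplicate
#'   names are an error).
#' @inheritParams repeated_holdout
#' @return A `MetricsTable` data frame, one row per configuration.
#' @export
compare_workflows <- function(configs, X_table, y, n_runs = 10L,
                              train_frac = 0.8, base_seed = 1L,
                              column_spec = NULL) {
  if (length(configs) == 0L) stopf("compare_workflows: no configurations")
  nms <- names(configs)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stopf("compare_workflows: configs must have unique non-empty names")
  splits <- holdout_splits(as.integer(y), n_runs, train_frac, base_seed)
  rows <- lapply(nms, function(nm)
    repeated_holdout(X_table, y, configs[[nm]], name = nm, splits = splits,
                     base_seed = base_seed, column_spec = column_spec))
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_table", class(out))
  out
}
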