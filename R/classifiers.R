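# Binary classifiers behind the morphism interface. The environment ships
# no standalone SVM / tree packages, so compact native implementations are
# provided: logistic regression via stats::glm, a soft-margin linear SVM
# solved as a dual QP (quadprog) with logistic calibration of its margins,
# a bagged-CART random forest, and AdaBoost over decision stumps. All emit
# a class-1 probability in [0, 1].

# ---- logistic --------------------------------------------------------------

logistic_frame <- function(X, cols = NULL) {
  X <- as_matrix(X)
  if (is.null(cols)) {
    cols <- colnames(X)
    if (is.null(cols)) cols <- paste0("x", seq_len(ncol(X)))
    cols <- make.names(cols, unique = TRUE)
  }
  colnames(X) <- cols
  as.data.frame(X)
}

train_logistic <- function(X, y, hyper = list()) {
  lambda <- hyper$lambda %||% 0
  if (lambda > 0) {
    fitg <- glmnet::glmnet(as_matrix(X), y, family = "binomial", alpha = 0,
                           lambda = lambda, standardize = FALSE)
    list(kind = "logistic", glmnet = fitg, lambda = lambda)
  } else {
    df <- logistic_frame(X)
    fitg <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                        family = stats::binomial()))
    list(kind = "logistic", glm = fitg, cols = colnames(df))
  }
}

prob_logistic <- function(model, X) {
  if (!is.null(model$glmnet))
    as.numeric(stats::predict(model$glmnet, newx = as_matrix(X), type = "response"))
  else {
    nd <- logistic_frame(X, cols = model$cols)
    as.numeric(suppressWarnings(stats::predict(model$glm, newdata = nd,
                                               type = "response")))
  }
}

# ---- linear SVM (dual QP) --------------------------------------------------

train_svm <- function(X, y, hyper = list()) {
  C <- hyper$C %||% 1
  X <- as_matrix(X); n <- nrow(X)
  ys <- ifelse(y == 1, 1, -1)
  K <- tcrossprod(X)
  D <- (ys %o% ys) * K + diag(1e-8, n)
  # maximize sum(a) - a'Da/2 s.t. a'y = 0, 0 <= a <= C
  A <- cbind(ys, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A, bvec = b0, meq = 1)
  a <- pmax(pmin(sol$solution, C), 0)
  w <- as.numeric(t(X) %*% (a * ys))
  sv <- which(a > 1e-6 & a < C - 1e-6)
  if (length(sv) == 0L) sv <- which(a > 1e-6)
  b <- if (length(sv)) mean(ys[sv] - X[sv, , drop = FALSE] %*% w) else 0
  margin <- as.numeric(X %*% w + b)
  # calibrate margins to probabilities with a logistic link
  cal <- suppressWarnings(stats::glm(y ~ m, data = data.frame(y = y, m = margin),
                                     family = stats::binomial()))
  list(kind = "svm", w = w, b = b, cal = stats::coef(cal))
}

prob_svm <- function(model, X) {
  margin <- as.numeric(as_matrix(X) %*% model$w + model$b)
  eta <- model$cal[1] + model$cal[2] * margin
  if (anyNA(eta)) eta[is.na(eta)] <- 0
  stats::plogis(eta)
}

# ---- CART + random forest --------------------------------------------------

gini_split_gain <- function(x, y) {
  # best threshold on one feature; returns c(gain, threshold) or NULL
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  valid <- which(xs[-n] < xs[-1])      # split between distinct values only
  if (length(valid) == 0L) return(NULL)
  nl <- valid
  nr <- n - nl
  p1l <- cum1[valid] / nl
  p1r <- (tot1 - cum1[valid]) / nr
  gini <- function(p) 2 * p * (1 - p)
  parent <- gini(tot1 / n)
  gain <- parent - (nl / n) * gini(p1l) - (nr / n) * gini(p1r)
  j <- which.max(gain)
  c(gain = gain[j], thr = (xs[valid[j]] + xs[valid[j] + 1]) / 2,
    at = valid[j])
}

build_cart <- function(X, y, depth, max_depth, min_split, mtry) {
  n <- length(y)
  p1 <- mean(y)
  if (depth >= max_depth || n < min_split || p1 == 0 || p1 == 1)
    return(list(leaf = TRUE, p = p1))
  feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
  best <- NULL; best_gain <- 1e-12; best_f <- NA
  for (f in feats) {
    sp <- gini_split_gain(X[, f], y)
    if (!is.null(sp) && sp[["gain"]] > best_gain) {
      best_gain <- sp[["gain"]]; best <- sp; best_f <- f
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, p = p1))
  left <- X[, best_f] <= best[["thr"]]
  list(leaf = FALSE, feature = best_f, thr = best[["thr"]],
       left = build_cart(X[left, , drop = FALSE], y[left], depth + 1,
                         max_depth, min_split, mtry),
       right = build_cart(X[!left, , drop = FALSE], y[!left], depth + 1,
                          max_depth, min_split, mtry))
}

predict_cart <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) { out[idx] <<- node$p; return() }
    left <- X[idx, node$feature] <= node$thr
    rec(node$left, idx[left]); rec(node$right, idx[!left])
  }
  rec(tree, seq_len(n))
  out
}

train_random_forest <- function(X, y, hyper = list()) {
  ntree <- hyper$ntree %||% 50L
  max_depth <- hyper$max_depth %||% 6L
  min_split <- hyper$min_split %||% 5L
  X <- as_matrix(X); n <- nrow(X)
  mtry <- hyper$mtry %||% max(1L, floor(sqrt(ncol(X))))
  trees <- lapply(seq_len(ntree), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    build_cart(X[idx, , drop = FALSE], y[idx], 0L, max_depth, min_split, mtry)
  })
  list(kind = "random_forest", trees = trees)
}

prob_random_forest <- function(model, X) {
  X <- as_matrix(X)
  probs <- vapply(model$trees, function(tr) predict_cart(tr, X), numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(X))
  rowMeans(probs)
}

# ---- AdaBoost over decision stumps ----------------------------------------

train_adaboost <- function(X, y, hyper = list()) {
  rounds <- hyper$rounds %||% 50L
  X <- as_matrix(X); n <- nrow(X)
  ys <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  stumps <- list()
  for (r in seq_len(rounds)) {
    best <- NULL; best_err <- Inf
    for (f in seq_len(ncol(X))) {
      xs <- X[, f]
      for (thr in unique(stats::quantile(xs, probs = seq(0.05, 0.95, 0.1),
                                         names = FALSE, type = 1))) {
        for (pol in c(1, -1)) {
          pred <- ifelse(pol * (xs - thr) >= 0, 1, -1)
          err <- sum(w[pred != ys])
          if (err < best_err) {
            best_err <- err
            best <- list(feature = f, thr = thr, pol = pol)
          }
        }
      }
    }
    best_err <- max(min(best_err, 1 - 1e-10), 1e-10)
    alpha <- 0.5 * log((1 - best_err) / best_err)
    pred <- ifelse(best$pol * (X[, best$feature] - best$thr) >= 0, 1, -1)
    w <- w * exp(-alpha * ys * pred)
    w <- w / sum(w)
    best$alpha <- alpha
    stumps[[r]] <- best
    if (best_err < 1e-9) break
  }
  list(kind = "adaboost", stumps = stumps)
}

prob_adaboost <- function(model, X) {
  X <- as_matrix(X)
  f <- rowSums(vapply(model$stumps, function(s)
    s$alpha * ifelse(s$pol * (X[, s$feature] - s$thr) >= 0, 1, -1),
    numeric(nrow(X))))
  stats::plogis(2 * f)   # logistic link on the boosted margin
}

# ---- dispatch + CV tuning --------------------------------------------------

classifier_kinds <- c("logistic", "svm", "random_forest", "adaboost")

train_classifier <- function(kind, X, y, hyper = list()) {
  switch(kind,
         logistic = train_logistic(X, y, hyper),
         svm = train_svm(X, y, hyper),
         random_forest = train_random_forest(X, y, hyper),
         adaboost = train_adaboost(X, y, hyper),
         stopf("unknown classifier kind '%s'", kind))
}

predict_classifier <- function(model, X) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(as_matrix(X))))
  p <- switch(model$kind,
              logistic = prob_logistic(model, X),
              svm = prob_svm(model, X),
              random_forest = prob_random_forest(model, X),
              adaboost = prob_adaboost(model, X))
  pmin(pmax(p, 0), 1)
}

default_hyper_grid <- function(kind) {
  switch(kind,
         logistic = list(list(lambda = 0)),
         svm = list(list(C = 0.1), list(C = 1), list(C = 10)),
         random_forest = list(list(ntree = 50L, max_depth = 6L)),
         adaboost = list(list(rounds = 50L)))
}

# Cross-validated hyperparameter selection maximizing hold-out AUC.
# `sampler` (function(X, y, seed) -> list(X, y)) is applied to the training
# folds only; validation folds are scored untouched. Returns the winning
# hyper, its mean CV AUC, and the pooled hold-out (score, label) pairs of
# the winner for downstream threshold fitting.
cv_tune_classifier <- function(kind, X, y, hyper_grid = NULL, cv_folds = 10L,
                               sampler = NULL, seed = 1L) {
  X <- as_matrix(X); y <- as.integer(y)
  hyper_grid <- hyper_grid %||% default_hyper_grid(kind)
  n_min_class <- min(table(y))
  folds_eff <- min(cv_folds, n_min_class, length(y))
  if (folds_eff < cv_folds)
    message(sprintf("cv_tune_classifier: reducing folds from %d to %d (class/sample counts)",
                    cv_folds, folds_eff))
  if (folds_eff < 2L) {
    model <- with_seed(child_seed(seed, 0), train_classifier(kind, X, y, hyper_grid[[1L]]))
    return(list(hyper = hyper_grid[[1L]], cv_auc = 0.5, model = model,
                pooled = data.frame(score = numeric(0), label = integer(0))))
  }
  folds <- stratified_folds(y, folds_eff, child_seed(seed, 1))
  results <- lapply(seq_along(hyper_grid), function(h) {
    hy <- hyper_grid[[h]]
    scores <- rep(NA_real_, length(y))
    aucs <- numeric(0)
    for (f in seq_len(folds_eff)) {
      tr <- which(folds != f); va <- which(folds == f)
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (!is.null(sampler)) {
        res <- sampler(Xtr, ytr, child_seed(seed, 100 * h + f))
        Xtr <- res$X; ytr <- res$y
      }
      model <- if (length(unique(ytr)) < 2L)
        list(kind = kind, constant = mean(ytr))
      else with_seed(child_seed(seed, 1000 * h + f),
                     train_classifier(kind, Xtr, ytr, hy))
      scores[va] <- predict_classifier(model, X[va, , drop = FALSE])
      if (length(unique(y[va])) == 2L)
        aucs <- c(aucs, binary_metrics(y[va], scores[va], 0.5)$roc_auc)
    }
    list(hyper = hy, auc = if (length(aucs)) mean(aucs) else 0.5, scores = scores)
  })
  best <- which.max(vapply(results, `[[`, numeric(1), "auc"))
  winner <- results[[best]]
  Xfull <- X; yfull <- y
  if (!is.null(sampler)) {
    res <- sampler(Xfull, yfull, child_seed(seed, 7))
    Xfull <- res$X; yfull <- res$y
  }
  model <- with_seed(child_seed(seed, 2),
                     train_classifier(kind, Xfull, yfull, winner$hyper))
  list(hyper = winner$hyper, cv_auc = winner$auc, model = model,
       pooled = data.frame(score = winner$scores, label = y))
}

#' Classifier as a morphism
#'
#' Wraps a binary classifier (`logistic`, `svm`, `random_forest`,
#' `adaboost`) behind the morphism interface. Fitting tunes hyperparameters
#' by stratified `cv_folds`-fold cross validation maximizing ROC AUC, then
#' refits the winner on all data; the morphism outputs a class-1
#' probability in `[0, 1]` (margin classifiers are calibrated through a
#' logistic link). Single-class training data yields a constant predictor
#' at the class prior, with a warning.
#'
#' @param kind classifier family.
#' @param hyper_grid list of hyperparameter lists; `NULL` = a small default
#'   grid per family.
#' @param cv_folds folds for hyperparameter tuning (reduced with a message
#'   when a class has fewer members).
#' @param seed integer seed controlling fold assignment and any stochastic
#'   trainer.
#' @return An unfitted `mlm` whose fitted params carry the trained model
#'   and its mean CV hold-out AUC (`params$cv_auc`).
#' @export
classifier_mlm <- function(kind = classifier_kinds, hyper_grid = NULL,
                           cv_folds = 10L, seed = 1L) {
  kind <- match.arg(kind)
  new_mlm(paste0("classifier_", kind),
          mlm_space("continuous", NA_integer_), mlm_space("probability", 1L),
          morphism = function(x, params) predict_classifier(params$model, as_matrix(x)),
          risk = function(params, X, Y) {
            p <- pmin(pmax(predict_classifier(params$model, as_matrix(X)), 1e-12), 1 - 1e-12)
            -mean(Y * log(p) + (1 - Y) * log(1 - p))   # negative log-likelihood
          },
          solver = function(X, Y, prior) {
            Y <- as.integer(Y)
            if (length(unique(Y)) < 2L) {
              warnf("classifier_mlm: single-class training data; constant-prior predictor")
              return(list(model = list(kind = kind, constant = mean(Y)),
                          cv_auc = 0.5, hyper = NULL))
            }
            tuned <- cv_tune_classifier(kind, X, Y, hyper_grid, cv_folds,
                                        sampler = NULL, seed = seed)
            list(model = tuned$model, cv_auc = tuned$cv_auc, hyper = tuned$hyper)
          })
}
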