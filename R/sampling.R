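# Class-imbalance resampling used inside node risks: SMOTE interpolation
# and a ROSE-style smoothed bootstrap. Both operate on the encoded numeric
# matrix and are pure functions of (input, seed).

#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic point is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0,1)`
#' and `x_nn` one of the `k_neighbors` nearest minority neighbors of `x_i`
#' (Euclidean distance in the encoded space). When the minority count is
#' too small, `k` is reduced to `count - 1` with a warning.
#'
#' @param X_minority numeric matrix of minority-class rows.
#' @param k_neighbors neighbor count.
#' @param n_synthetic number of synthetic rows to generate.
#' @param seed integer seed.
#' @return Matrix with `n_synthetic` rows; attribute `parents` records the
#'   (base, neighbor) row indices each synthetic point interpolates.
#' @export
smote <- function(X_minority, k_neighbors = 5L, n_synthetic, seed = 1L) {
  X <- as_matrix(X_minority)
  n <- nrow(X)
  if (n < 2L) stopf("smote needs at least 2 minority points")
  if (n <= k_neighbors) {
    warnf("smote: minority count %d <= k_neighbors %d; using k = %d",
          n, k_neighbors, n - 1L)
    k_neighbors <- n - 1L
  }
  nn <- FNN::get.knn(X, k = k_neighbors)$nn.index
  with_seed(seed, {
    base <- sample.int(n, n_synthetic, replace = TRUE)
    pick <- sample.int(k_neighbors, n_synthetic, replace = TRUE)
    u <- stats::runif(n_synthetic)
    nbr <- nn[cbind(base, pick)]
    out <- X[base, , drop = FALSE] +
      u * (X[nbr, , drop = FALSE] - X[base, , drop = FALSE])
    attr(out, "parents") <- cbind(base = base, neighbor = nbr)
    out
  })
}

#' Balance a binary sample with SMOTE
#'
#' Oversamples the minority class to an exact 1:1 ratio; the majority rows
#' are untouched.
#'
#' @param X numeric matrix; `y` binary 0/1 labels.
#' @param k_neighbors,seed passed to [smote()].
#' @return List with balanced `X` and `y`.
#' @export
smote_balance <- function(X, y, k_neighbors = 5L, seed = 1L) {
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  need <- abs(tab[["0"]] - tab[["1"]])
  if (need == 0L) return(list(X = X, y = y))
  syn <- smote(X[y == minority, , drop = FALSE], k_neighbors, need, seed)
  list(X = rbind(as_matrix(X), syn), y = c(y, rep(minority, need)))
}

# Silverman's rule-of-thumb bandwidth per feature.
silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  if (is.na(spread) || spread == 0) return(0)
  0.9 * spread * n^(-1 / 5)
}

#' ROSE-style smoothed bootstrap
#'
#' Draws each output row by picking a class with probability 1/2, resampling
#' a row of that class, and perturbing every coordinate with Gaussian noise
#' of per-feature Silverman bandwidth scaled by `h_scale`. `h_scale = 0`
#' degenerates to a plain class-balanced bootstrap.
#'
#' @param X numeric matrix; `y` binary 0/1 labels (both classes required).
#' @param n_out output sample size.
#' @param h_scale nonnegative bandwidth multiplier.
#' @param seed integer seed.
#' @return List with resampled `X_res` and `y_res`.
#' @export
rose_sample <- function(X, y, n_out = length(y), h_scale = 1, seed = 1L) {
  X <- as_matrix(X); y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("rose_sample: both classes must be present")
  if (h_scale < 0) stopf("rose_sample: h_scale must be nonnegative")
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  bw <- list(`0` = apply(X[idx0, , drop = FALSE], 2L, silverman_bw),
             `1` = apply(X[idx1, , drop = FALSE], 2L, silverman_bw))
  with_seed(seed, {
    cls <- stats::rbinom(n_out, 1L, 0.5)
    rows <- ifelse(cls == 1L,
                   idx1[sample.int(length(idx1), n_out, replace = TRUE)],
                   idx0[sample.int(length(idx0), n_out, replace = TRUE)])
    Xr <- X[rows, , drop = FALSE]
    if (h_scale > 0) {
      for (cl in c(0L, 1L)) {
        sel <- which(cls == cl)
        if (length(sel)) {
          h <- bw[[as.character(cl)]] * h_scale
          noise <- matrix(stats::rnorm(length(sel) * ncol(X)), length(sel)) *
            rep(h, each = length(sel))
          Xr[sel, ] <- Xr[sel, , drop = FALSE] + noise
        }
      }
    }
    list(X_res = Xr, y_res = cls)
  })
}

# Resolve a pipeline sampler spec ("none" | "smote" | "rose" | function)
# into a function(X, y, seed) -> list(X, y) applied to training folds only.
resolve_sampler <- function(spec) {
  if (is.function(spec)) return(spec)
  switch(spec %||% "none",
         none = NULL,
         smote = function(X, y, seed) smote_balance(X, y, seed = seed),
         rose = function(X, y, seed) {
           res <- rose_sample(X, y, n_out = length(y), h_scale = 1, seed = seed)
           list(X = res$X_res, y = res$y_res)
         },
         stopf("unknown sampler '%s'", spec))
}
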