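# Concrete morphisms: one-hot encoding, standardization (KL risk), PCA,
# least-squares regression, identity, and the decision threshold. Each
# exposes both a plain fit_*/apply pair and (where useful) an mlm wrapper.

#' Fit a mixed-type one-hot encoder
#'
#' Declared categorical columns are expanded into full indicator blocks
#' (one column per level, no reference level dropped); continuous columns
#' pass through. Level order is first-appearance order in the training
#' data. Encoding a level unseen at training time yields an all-zero block
#' and a warning.
#'
#' @param X_raw data frame with mixed columns.
#' @param column_spec optional data frame with columns `name`, `kind`
#'   (`"continuous"`/`"categorical"`), e.g. read from a sidecar JSON; if
#'   `NULL`, factor/character/logical columns are treated as categorical.
#' @return An object of class `encoder_map` with fields `columns` (per-column
#'   spec with levels) and `out_dim`.
#' @export
fit_encoder <- function(X_raw, column_spec = NULL) {
  stopifnot(is.data.frame(X_raw))
  kinds <- if (is.null(column_spec)) {
    vapply(X_raw, function(col)
      if (is.numeric(col)) "continuous" else "categorical", character(1))
  } else {
    k <- column_spec$kind[match(names(X_raw), column_spec$name)]
    if (anyNA(k)) stopf("column_spec is missing columns: %s",
                        paste(names(X_raw)[is.na(k)], collapse = ", "))
    k
  }
  columns <- Map(function(nm, kind) {
    if (kind == "continuous") list(name = nm, kind = kind, levels = NULL)
    else {
      col <- X_raw[[nm]]
      lev <- as.character(unique(as.character(col)))  # first-appearance order
      list(name = nm, kind = kind, levels = lev)
    }
  }, names(X_raw), kinds)
  out_dim <- sum(vapply(columns, function(cs)
    if (cs$kind == "continuous") 1L else length(cs$levels), integer(1)))
  structure(list(columns = unname(columns), out_dim = out_dim,
                 names = names(X_raw)), class = "encoder_map")
}

#' Apply a fitted encoder
#'
#' @param enc an [fit_encoder()] object.
#' @param X_raw data frame with the training columns.
#' @return Numeric matrix with `enc$out_dim` columns.
#' @export
encode <- function(enc, X_raw) {
  stopifnot(inherits(enc, "encoder_map"), is.data.frame(X_raw))
  if (!all(enc$names %in% names(X_raw)))
    stopf("encode: missing columns: %s",
          paste(setdiff(enc$names, names(X_raw)), collapse = ", "))
  n <- nrow(X_raw)
  blocks <- lapply(enc$columns, function(cs) {
    col <- X_raw[[cs$name]]
    if (cs$kind == "continuous") {
      m <- matrix(as.numeric(col), ncol = 1)
      colnames(m) <- cs$name
      m
    } else {
      chr <- as.character(col)
      unseen <- !is.na(chr) & !(chr %in% cs$levels)
      if (any(unseen))
        warnf("encode: column '%s' has %d value(s) with unseen level(s) (%s); emitting zero blocks",
              cs$name, sum(unseen),
              paste(unique(chr[unseen]), collapse = ", "))
      m <- matrix(0, n, length(cs$levels))
      hit <- match(chr, cs$levels)
      ok <- which(!is.na(hit))
      m[cbind(ok, hit[ok])] <- 1
      colnames(m) <- paste(cs$name, cs$levels, sep = ".")
      m
    }
  })
  do.call(cbind, blocks)
}

#' KL divergence of a sample from the standard normal
#'
#' Evaluated under a Gaussian model of the data:
#' `KL(N(m, S) || N(0, I)) = (tr(S) + m'm - d - log det S) / 2`
#' with the sample covariance regularized by `+1e-9 I`. This is the
#' empirical risk driving the standardization morphism: it is zero exactly
#' when the sample has mean zero and identity covariance (up to the
#' regularization).
#'
#' @param X numeric matrix with at least two rows.
#' @return Nonnegative scalar.
#' @export
kl_to_standard_normal <- function(X) {
  X <- as_matrix(X)
  if (nrow(X) < 2L) stopf("kl_to_standard_normal needs at least 2 rows")
  d <- ncol(X)
  m <- colMeans(X)
  S <- stats::cov(X) + diag(1e-9, d)
  ld <- determinant(S, logarithm = TRUE)
  0.5 * (sum(diag(S)) + sum(m^2) - d - as.numeric(ld$modulus))
}

#' Fit standardization parameters
#'
#' Shift `c` = column means, scale `s` = column sample standard deviations
#' (n-1 denominator). Constant columns get `s = 1` with a warning so the
#' map stays defined.
#'
#' @param X numeric matrix.
#' @return List of class `standardize_params` with fields `c` and `s`.
#' @export
fit_standardize <- function(X) {
  X <- as_matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stopf("fit_standardize: empty X")
  cc <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  if (nrow(X) == 1L) s[] <- NA_real_
  zero <- is.na(s) | s == 0
  if (any(zero)) {
    warnf("fit_standardize: %d constant column(s); using scale 1", sum(zero))
    s[zero] <- 1
  }
  structure(list(c = cc, s = s), class = "standardize_params")
}

#' Apply standardization `(x - c) diag(s)^-1`
#'
#' @param params a [fit_standardize()] result.
#' @param x vector or matrix.
#' @export
apply_standardize <- function(params, x) {
  if (is.null(dim(x))) (x - params$c) / params$s
  else sweep(sweep(as_matrix(x), 2L, params$c, `-`), 2L, params$s, `/`)
}

#' Fit principal components on standardized data
#'
#' Standardizes internally, then extracts the top `c` eigenvectors of the
#' sample covariance. The returned loading matrix `A` (c x m) has
#' orthonormal rows; the reconstruction error of the projection equals the
#' sum of the discarded covariance eigenvalues.
#'
#' @param X numeric matrix; `c` target dimension, `1 <= c <= ncol(X)`.
#' @param standardize standardize first (default `TRUE`).
#' @return Object of class `pca_map`: `A`, eigenvalues, standardization
#'   params.
#' @export
fit_pca <- function(X, c, standardize = TRUE) {
  X <- as_matrix(X)
  m <- ncol(X)
  if (c < 1L || c > m) stopf("fit_pca: c must lie in [1, %d]", m)
  std <- if (standardize) fit_standardize(X) else
    structure(list(c = rep(0, m), s = rep(1, m)), class = "standardize_params")
  Z <- apply_standardize(std, X)
  eg <- eigen(stats::cov(Z), symmetric = TRUE)
  A <- t(eg$vectors[, seq_len(c), drop = FALSE])
  # deterministic sign: largest-magnitude loading of each component positive
  for (i in seq_len(c)) {
    j <- which.max(abs(A[i, ]))
    if (A[i, j] < 0) A[i, ] <- -A[i, ]
  }
  structure(list(A = A, eigenvalues = eg$values, std = std, c = c, m = m),
            class = "pca_map")
}

#' Project points onto fitted principal components
#'
#' @param pca a [fit_pca()] object.
#' @param x vector or matrix in the original space.
#' @return Score matrix (n x c).
#' @export
pca_project <- function(pca, x) {
  Z <- apply_standardize(pca$std, as_matrix(x))
  Z %*% t(pca$A)
}

#' Least-squares linear regression coefficients
#'
#' Normal-equations solution; when X'X is singular the minimum-norm
#' solution via the pseudoinverse is returned.
#'
#' @param X design matrix; `Y` response vector.
#' @return Coefficient vector of length `ncol(X)`.
#' @export
fit_linear_regression <- function(X, Y) {
  X <- as_matrix(X)
  if (nrow(X) != length(Y)) stopf("fit_linear_regression: X rows != length(Y)")
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  p <- tryCatch(solve(XtX, XtY), error = function(e) {
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  })
  as.numeric(p)
}

# --- mlm wrappers -----------------------------------------------------------

#' Identity morphism
#' @param dim declared dimension (NA = any).
#' @export
mlm_identity <- function(dim = NA_integer_) {
  m <- new_mlm("identity", mlm_space("continuous", dim), mlm_space("continuous", dim),
               morphism = function(x, params) x,
               risk = function(params, X, Y) 0,
               solver = function(X, Y, prior) numeric(0),
               supervised = FALSE)
  m
}

#' Linear regression as a morphism
#'
#' Morphism `x . p` with squared-error risk `||Y - Xp||^2`; closed-form
#' normal-equations solver.
#' @param m input dimension (NA = inferred at fit time).
#' @export
mlm_linear_regression <- function(m = NA_integer_) {
  new_mlm("linear_regression",
          mlm_space("continuous", m), mlm_space("continuous", 1L),
          morphism = function(x, params) as.numeric(as_matrix(x) %*% params),
          risk = function(params, X, Y) sum((Y - as_matrix(X) %*% params)^2),
          solver = function(X, Y, prior) {
            if (prior$kind == "point-mass") return(prior$value)
            fit_linear_regression(X, Y)
          })
}

#' Standardization as a morphism
#'
#' Morphism `(x - c) diag(s)^-1` with the Gaussian-model KL divergence to
#' the standard normal as risk; closed-form optimum `c = column means`,
#' `s = column standard deviations`.
#' @param m input dimension (NA = inferred at fit time).
#' @export
mlm_standardize <- function(m = NA_integer_) {
  new_mlm("standardize",
          mlm_space("continuous", m), mlm_space("continuous", m),
          morphism = function(x, params)
            apply_standardize(structure(params, class = "standardize_params"), x),
          risk = function(params, X, Y) {
            Z <- apply_standardize(structure(params, class = "standardize_params"), X)
            kl_to_standard_normal(Z)
          },
          solver = function(X, Y, prior) unclass(fit_standardize(X)),
          supervised = FALSE,
          serialize = function(p) p,
          unserialize = function(p) list(c = as.numeric(p$c), s = as.numeric(p$s)))
}

#' PCA as a morphism
#'
#' Morphism `x A'` minimizing Frobenius reconstruction error subject to
#' orthonormal loadings; fitted unsupervised (Y empty).
#' @param c target dimension; `m` input dimension (NA = inferred).
#' @export
mlm_pca <- function(c, m = NA_integer_) {
  new_mlm("pca",
          mlm_space("continuous", m), mlm_space("continuous", as.integer(c)),
          morphism = function(x, params) {
            pca <- structure(params, class = "pca_map")
            pca_project(pca, x)
          },
          risk = function(params, X, Y) {
            pca <- structure(params, class = "pca_map")
            Z <- apply_standardize(pca$std, as_matrix(X))
            sum((Z - (Z %*% t(pca$A)) %*% pca$A)^2)
          },
          solver = function(X, Y, prior) unclass(fit_pca(X, c)),
          supervised = FALSE,
          serialize = function(p) list(A = p$A, eigenvalues = p$eigenvalues,
                                       std = list(c = as.numeric(p$std$c),
                                                  s = as.numeric(p$std$s)),
                                       c = p$c, m = p$m),
          unserialize = function(p) list(
            A = matrix(unlist(p$A), nrow = p$c, byrow = FALSE),
            eigenvalues = as.numeric(p$eigenvalues),
            std = structure(list(c = as.numeric(p$std$c), s = as.numeric(p$std$s)),
                            class = "standardize_params"),
            c = p$c, m = p$m))
}

# --- decision threshold -----------------------------------------------------

#' Apply a decision threshold
#'
#' Returns 1 iff `x >= T` (boundary inclusive).
#' @param x probability vector in `[0, 1]`; `T` threshold.
#' @export
threshold_apply <- function(x, T) as.integer(x >= T)

#' Fit a decision threshold on scored labels
#'
#' Scans all midpoints of adjacent distinct observed scores (plus the
#' extremes) and returns the threshold maximizing the criterion; ties are
#' broken toward the smallest threshold. Degenerate single-class labels
#' fall back to T = 0.5 with a warning.
#'
#' @param scores probability scores in `[0, 1]`; `labels` binary 0/1.
#' @param criterion `"youden"` (sensitivity + specificity - 1, default) or
#'   `"accuracy"`.
#' @return List of class `threshold_params` with field `T`.
#' @export
threshold_fit <- function(scores, labels, criterion = c("youden", "accuracy")) {
  criterion <- match.arg(criterion)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    warnf("threshold_fit: degenerate labels; falling back to T = 0.5")
    return(structure(list(T = 0.5), class = "threshold_params"))
  }
  u <- sort(unique(scores))
  cand <- if (length(u) > 1L) c(u[1], (u[-1] + u[-length(u)]) / 2, u[length(u)])
          else u
  vals <- vapply(cand, function(T) {
    pred <- as.integer(scores >= T)
    tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
    tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
    if (criterion == "youden") tp / (tp + fn) + tn / (tn + fp) - 1
    else (tp + tn) / length(labels)
  }, numeric(1))
  structure(list(T = cand[which.max(vals)]), class = "threshold_params")
}

#' Decision threshold as a morphism
#'
#' Morphism per the boundary-inclusive rule with a risk equal to the
#' negated criterion; solver scans observed score midpoints.
#' @param criterion passed to [threshold_fit()].
#' @export
mlm_threshold <- function(criterion = "youden") {
  new_mlm("threshold",
          mlm_space("probability", 1L), mlm_space("label", 1L),
          morphism = function(x, params) threshold_apply(as.numeric(x), params$T),
          risk = function(params, X, Y) {
            pred <- threshold_apply(as.numeric(X), params$T)
            -mean(pred == Y)
          },
          solver = function(X, Y, prior)
            unclass(threshold_fit(as.numeric(X), Y, criterion)))
}
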