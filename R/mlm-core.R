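# Core morphism abstraction: a parametric map between data spaces bundled
# with an empirical risk function and a parameter prior. Fitting a morphism
# means minimizing its empirical risk over training realizations; everything
# else in the package (standardization, PCA, regression, classifiers, the
# Mapper partition, thresholding) is an instance of this one contract.

#' Describe a data space
#'
#' A space descriptor records the dimension of a space and the kind of each
#' coordinate. Morphism composition and direct sums check compatibility
#' through these descriptors.
#'
#' @param kinds character vector of per-column kinds; one of `"continuous"`,
#'   `"categorical"`, `"probability"`, `"label"`. A single kind is recycled
#'   to `dim` columns.
#' @param dim integer dimension, or `NA` for "any dimension".
#' @return An object of class `mlm_space`.
#' @export
mlm_space <- function(kinds = "continuous", dim = NA_integer_) {
  kinds <- match.arg(kinds, c("continuous", "categorical", "probability", "label"),
                     several.ok = TRUE)
  if (!is.na(dim) && length(kinds) == 1L) kinds <- rep(kinds, dim)
  if (!is.na(dim) && length(kinds) != dim)
    stopf("space kinds length (%d) does not match dim (%d)", length(kinds), dim)
  structure(list(dim = as.integer(dim), kinds = kinds), class = "mlm_space")
}

spaces_compatible <- function(a, b) {
  if (is.na(a$dim) || is.na(b$dim)) return(TRUE)
  a$dim == b$dim
}

#' Parameter prior descriptor
#'
#' Priors are metadata consumed by solvers that understand them: a
#' `uniform-box` prior supplies grid-search bounds, a `point-mass` prior
#' pins a parameter, and the default improper prior P(p) = 1 imposes no
#' constraint. Gaussian priors are carried for documentation and for
#' penalized solvers.
#'
#' @param kind one of `"improper-uniform"`, `"uniform-box"`, `"point-mass"`,
#'   `"gaussian"`.
#' @param lower,upper numeric bounds (uniform-box).
#' @param value fixed value (point-mass).
#' @param mean,sd gaussian hyperparameters.
#' @param grid_n grid resolution per dimension used by grid solvers.
#' @return An object of class `mlm_prior`.
#' @export
mlm_prior <- function(kind = c("improper-uniform", "uniform-box", "point-mass",
                               "gaussian"),
                      lower = NULL, upper = NULL, value = NULL,
                      mean = 0, sd = 1, grid_n = 25L) {
  kind <- match.arg(kind)
  if (kind == "uniform-box" && (is.null(lower) || is.null(upper)))
    stopf("uniform-box prior needs lower and upper bounds")
  if (kind == "point-mass" && is.null(value))
    stopf("point-mass prior needs a value")
  structure(list(kind = kind, lower = lower, upper = upper, value = value,
                 mean = mean, sd = sd, grid_n = as.integer(grid_n)),
            class = "mlm_prior")
}

#' Construct a machine learning morphism
#'
#' Bundles a parametric map `F(x; p)` with an input/output space pair, an
#' empirical risk function, a parameter prior and a solver. `fit()` runs the
#' solver (closed-form where one exists, otherwise grid or iterative
#' minimization of the risk) and stamps the optimal parameters onto the
#' object; `predict()` applies the fitted map.
#'
#' @param kind short string naming the morphism family (used for JSON
#'   round-trips and printing).
#' @param input_space,output_space [mlm_space()] descriptors.
#' @param morphism `function(x, params)` applying the map to one row or a
#'   matrix of rows.
#' @param risk `function(params, X, Y)` returning the empirical risk of
#'   `params` on realizations `(X, Y)`; `Y` may be `NULL` for unsupervised
#'   morphisms.
#' @param solver `function(X, Y, prior)` returning the risk-minimizing
#'   parameters. Defaults to a grid search over a `uniform-box` prior.
#' @param prior an [mlm_prior()].
#' @param supervised logical; supervised morphisms refuse to fit without
#'   outcome realizations.
#' @param serialize,unserialize optional hooks mapping `params` to/from
#'   plain lists for JSON persistence.
#' @return An unfitted object of class `mlm`.
#' @seealso [fit()], [mlm_apply()], [compose_mlm()], [direct_sum_mlm()]
#' @export
new_mlm <- function(kind, input_space, output_space, morphism, risk,
                    solver = NULL, prior = mlm_prior(), supervised = TRUE,
                    serialize = NULL, unserialize = NULL) {
  stopifnot(inherits(input_space, "mlm_space"), inherits(output_space, "mlm_space"),
            is.function(morphism), is.function(risk))
  if (is.null(solver)) solver <- grid_solver(risk)
  structure(list(kind = kind, input_space = input_space,
                 output_space = output_space, morphism = morphism,
                 risk = risk, solver = solver, prior = prior,
                 supervised = isTRUE(supervised), params = NULL,
                 fitted = FALSE, serialize = serialize,
                 unserialize = unserialize),
            class = "mlmorph")
}

# Generic grid-search solver over a uniform-box prior; the fallback for
# morphisms with no closed-form minimizer.
grid_solver <- function(risk) {
  function(X, Y, prior) {
    if (prior$kind == "point-mass") return(prior$value)
    if (prior$kind != "uniform-box")
      stopf("no closed-form solver registered and prior of kind '%s' supplies no grid bounds",
            prior$kind)
    axes <- Map(function(lo, hi) seq(lo, hi, length.out = prior$grid_n),
                prior$lower, prior$upper)
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1L, function(p) risk(p, X, Y))
    grid[which.min(vals), ]
  }
}

#' @export
print.mlmorph <- function(x, ...) {
  cat(sprintf("<mlm:%s> %s -> %s | %s\n", x$kind,
              paste0("R^", x$input_space$dim %||% NA),
              paste0("R^", x$output_space$dim %||% NA),
              if (x$fitted) sprintf("fitted (%d params)", length(unlist(x$params)))
              else "unfitted"))
  invisible(x)
}

#' Fit a morphism by empirical risk minimization
#'
#' Runs the morphism's registered solver on training realizations and
#' returns the fitted object. Unsupervised morphisms (e.g. standardization,
#' PCA) are fitted with `Y = NULL`.
#'
#' @param object an [new_mlm()] object.
#' @param X sample matrix (rows are realizations) or data frame.
#' @param Y outcome vector matched to the rows of `X`, or `NULL`.
#' @param ... unused.
#' @return The fitted `mlm`.
#' @export
fit <- function(object, ...) UseMethod("fit")

#' @rdname fit
#' @export
fit.mlmorph <- function(object, X, Y = NULL, ...) {
  X <- as_matrix(X)
  if (nrow(X) == 0L) stopf("cannot fit '%s' on an empty sample", object$kind)
  if (!is.na(object$input_space$dim) && ncol(X) != object$input_space$dim)
    stopf("'%s': X has %d columns but the input space has dimension %d",
          object$kind, ncol(X), object$input_space$dim)
  if (object$supervised) {
    if (is.null(Y) || length(Y) == 0L)
      stopf("'%s' is supervised; outcome realizations Y are required", object$kind)
    if (length(Y) != nrow(X))
      stopf("'%s': Y has length %d but X has %d rows", object$kind,
            length(Y), nrow(X))
  } else if (!is.null(Y) && length(Y) > 0L && length(Y) != nrow(X)) {
    stopf("'%s': Y, when given, must match the rows of X", object$kind)
  }
  object$params <- object$solver(X, Y, object$prior)
  object$fitted <- TRUE
  object
}

#' Apply a fitted morphism
#'
#' Evaluates `F(x; p*)` at new points, vectorizing row-wise over matrices.
#'
#' @param mlm a fitted `mlm`.
#' @param x input point (vector) or matrix of row points.
#' @return The morphism output; a vector or matrix depending on the morphism.
#' @export
mlm_apply <- function(mlm, x) {
  stopifnot(inherits(mlm, "mlmorph"))
  if (!mlm$fitted) stopf("'%s' must be fitted before it is applied", mlm$kind)
  if (is.null(dim(x)) && !is.na(mlm$input_space$dim) &&
      length(x) != mlm$input_space$dim)
    stopf("'%s': input has length %d but the input space has dimension %d",
          mlm$kind, length(x), mlm$input_space$dim)
  if (!is.null(dim(x)) && !is.na(mlm$input_space$dim) &&
      ncol(x) != mlm$input_space$dim)
    stopf("'%s': input has %d columns but the input space has dimension %d",
          mlm$kind, ncol(x), mlm$input_space$dim)
  mlm$morphism(x, mlm$params)
}

#' @rdname mlm_apply
#' @param object a fitted `mlm`.
#' @param newdata input point or matrix.
#' @param ... unused.
#' @export
predict.mlmorph <- function(object, newdata, ...) mlm_apply(object, newdata)

#' Compose two morphisms
#'
#' Builds the morphism `x -> F_outer(F_inner(x; p1); p2)` whose parameter
#' space is the product of the member spaces. Under `mode = "sequential"`
#' fitting first fits the inner morphism, transforms the realizations, and
#' fits the outer morphism on the transformed data; under `mode = "joint"`
#' the outer risk is minimized over the product grid declared by the two
#' uniform-box priors.
#'
#' @param outer,inner `mlm` objects with `inner$output_space` matching
#'   `outer$input_space`.
#' @param mode `"sequential"` (default) or `"joint"`.
#' @return An unfitted composite `mlm` of kind `"compose"`.
#' @export
compose_mlm <- function(outer, inner, mode = c("sequential", "joint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(outer, "mlmorph"), inherits(inner, "mlmorph"))
  if (!spaces_compatible(inner$output_space, outer$input_space))
    stopf("composition mismatch: inner output space (dim %s) != outer input space (dim %s)",
          inner$output_space$dim, outer$input_space$dim)
  morphism <- function(x, params) {
    outer$morphism(inner$morphism(x, params$inner), params$outer)
  }
  risk <- function(params, X, Y) {
    outer$risk(params$outer, as_matrix(inner$morphism(X, params$inner)), Y)
  }
  solver <- if (mode == "sequential") {
    function(X, Y, prior) {
      fi <- fit(inner, X, if (inner$supervised) Y else NULL)
      Z <- as_matrix(inner$morphism(X, fi$params))
      fo <- fit(outer, Z, if (outer$supervised) Y else NULL)
      list(inner = fi$params, outer = fo$params)
    }
  } else {
    function(X, Y, prior) {
      grids <- lapply(list(inner, outer), function(m) {
        p <- m$prior
        if (p$kind != "uniform-box")
          stopf("joint composition requires uniform-box priors declaring grids (member '%s' has '%s')",
                m$kind, p$kind)
        axes <- Map(function(lo, hi) seq(lo, hi, length.out = p$grid_n),
                    p$lower, p$upper)
        as.matrix(expand.grid(axes))
      })
      best <- NULL; best_val <- Inf
      for (i in seq_len(nrow(grids[[1L]]))) {
        for (j in seq_len(nrow(grids[[2L]]))) {
          cand <- list(inner = grids[[1L]][i, ], outer = grids[[2L]][j, ])
          v <- risk(cand, X, Y)
          if (v < best_val) { best_val <- v; best <- cand }
        }
      }
      best
    }
  }
  new_mlm(kind = paste0(outer$kind, "∘", inner$kind),
          input_space = inner$input_space, output_space = outer$output_space,
          morphism = morphism, risk = risk, solver = solver,
          supervised = outer$supervised || inner$supervised)
}

#' Direct sum of two morphisms
#'
#' For morphisms with a shared output space and a closed binary operation
#' `op` on that space, the direct sum acts on concatenated inputs as
#' `F1(x1; p1) op F2(x2; p2)` with risk `a*R1 + b*R2`. Because the risk is
#' decomposable, fitting the sum fits the two members independently; the
#' package's Property-1 tests verify that this equals the joint minimizer
#' on orthogonal designs.
#'
#' @param ml1,ml2 member morphisms sharing an output space.
#' @param op closed binary operation on the output space (default `+`).
#' @param a,b positive risk weights.
#' @return An unfitted `mlm` over the concatenated input space.
#' @export
direct_sum_mlm <- function(ml1, ml2, op = `+`, a = 1, b = 1) {
  stopifnot(inherits(ml1, "mlmorph"), inherits(ml2, "mlmorph"), a > 0, b > 0)
  if (!spaces_compatible(ml1$output_space, ml2$output_space) ||
      !identical(ml1$output_space$kinds[1], ml2$output_space$kinds[1]))
    stopf("direct sum requires a shared output space")
  d1 <- ml1$input_space$dim
  if (is.na(d1)) stopf("direct sum needs a declared input dimension for the first member")
  split_x <- function(x) {
    if (is.null(dim(x))) list(x[seq_len(d1)], x[-seq_len(d1)])
    else list(x[, seq_len(d1), drop = FALSE], x[, -seq_len(d1), drop = FALSE])
  }
  morphism <- function(x, params) {
    xs <- split_x(x)
    op(ml1$morphism(xs[[1L]], params$p1), ml2$morphism(xs[[2L]], params$p2))
  }
  risk <- function(params, X, Y) {
    xs <- split_x(as_matrix(X))
    a * ml1$risk(params$p1, xs[[1L]], Y) + b * ml2$risk(params$p2, xs[[2L]], Y)
  }
  solver <- function(X, Y, prior) {
    xs <- split_x(as_matrix(X))
    f1 <- fit(ml1, xs[[1L]], if (ml1$supervised) Y else NULL)
    f2 <- fit(ml2, xs[[2L]], if (ml2$supervised) Y else NULL)
    list(p1 = f1$params, p2 = f2$params)
  }
  dim2 <- ml2$input_space$dim
  new_mlm(kind = paste0(ml1$kind, "⊕", ml2$kind),
          input_space = mlm_space("continuous",
                                  if (is.na(dim2)) NA_integer_ else d1 + dim2),
          output_space = ml1$output_space, morphism = morphism, risk = risk,
          solver = solver, supervised = ml1$supervised || ml2$supervised)
}

#' Collections of morphisms
#'
#' A collection is an ordered set of fitted morphisms with a shared output
#' space, used for model evaluation and selection.
#'
#' @param members list of fitted `mlm` objects.
#' @return An object of class `mlm_collection`.
#' @export
mlm_collection <- function(members) {
  stopifnot(is.list(members))
  if (length(members) == 0L) stopf("a collection needs at least one member")
  ok <- vapply(members, inherits, logical(1), "mlmorph")
  if (!all(ok)) stopf("all collection members must be mlm objects")
  kind1 <- members[[1L]]$output_space$kinds[1]
  same <- vapply(members, function(m) identical(m$output_space$kinds[1], kind1),
                 logical(1))
  if (!all(same)) stopf("collection members must share the declared output space")
  structure(list(members = members, dimension = length(members)),
            class = "mlm_collection")
}

collection_metrics <- c("auc", "sensitivity", "specificity", "accuracy")

#' Score every member of a collection
#'
#' Applies each fitted member to `X` and scores its probability output
#' against `Y` with a registered performance measure. Threshold-based
#' metrics use T = 0.5.
#'
#' @param coll an [mlm_collection()].
#' @param metric one of `"auc"`, `"sensitivity"`, `"specificity"`,
#'   `"accuracy"`.
#' @param X input matrix; `Y` binary labels.
#' @return Numeric score vector in member declaration order.
#' @export
evaluate_collection <- function(coll, metric = "auc", X, Y) {
  stopifnot(inherits(coll, "mlm_collection"))
  metric <- match.arg(metric, collection_metrics)
  vapply(coll$members, function(m) {
    if (!m$fitted) stopf("all collection members must be fitted")
    scores <- as.numeric(mlm_apply(m, as_matrix(X)))
    binary_metrics(Y, scores, T = 0.5)[[if (metric == "auc") "roc_auc" else metric]]
  }, numeric(1))
}

#' Select the best member of a collection
#'
#' @inheritParams evaluate_collection
#' @return List with `index` (1-based, ties broken by the lowest index) and
#'   `mlm`, the winning member.
#' @export
select_best <- function(coll, metric = "auc", X, Y) {
  scores <- evaluate_collection(coll, metric, X, Y)
  idx <- which.max(scores)   # which.max returns the first maximum: lowest index
  list(index = idx, mlm = coll$members[[idx]], scores = scores)
}

#' Serialize a fitted morphism to JSON
#'
#' Captures kind, space descriptors and parameters. Morphism families
#' registered by the package can be rebuilt with [mlm_from_json()].
#'
#' @param mlm a fitted `mlm`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
mlm_to_json <- function(mlm, path = NULL) {
  stopifnot(inherits(mlm, "mlmorph"))
  params <- if (!is.null(mlm$serialize)) mlm$serialize(mlm$params) else mlm$params
  obj <- list(kind = mlm$kind,
              input_space = list(dim = mlm$input_space$dim,
                                 kinds = mlm$input_space$kinds),
              output_space = list(dim = mlm$output_space$dim,
                                  kinds = mlm$output_space$kinds),
              fitted = mlm$fitted, params = params)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Rebuild a registered morphism from JSON
#'
#' Supports the concrete families shipped by the package:
#' `linear_regression`, `standardize`, `pca`, `threshold`, `identity`.
#'
#' @param json JSON string or file path produced by [mlm_to_json()].
#' @export
mlm_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  dim_or_na <- function(d) {
    d <- suppressWarnings(as.integer(d))
    if (length(d) != 1L || is.na(d)) NA_integer_ else d
  }
  in_dim <- dim_or_na(obj$input_space$dim)
  out_dim <- dim_or_na(obj$output_space$dim)
  proto <- switch(obj$kind,
    linear_regression = mlm_linear_regression(m = in_dim),
    standardize = mlm_standardize(m = in_dim),
    pca = mlm_pca(c = out_dim, m = in_dim),
    threshold = mlm_threshold(),
    identity = mlm_identity(dim = in_dim),
    stopf("no registered constructor for morphism kind '%s'", obj$kind))
  if (isTRUE(obj$fitted)) {
    proto$params <- if (!is.null(proto$unserialize)) proto$unserialize(obj$params)
                    else obj$params
    proto$fitted <- TRUE
  }
  proto
}
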