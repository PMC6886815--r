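# Gower dissimilarity for mixed continuous/categorical data: the unweighted
# mean over columns of |difference|/range for numeric columns and a 0/1
# mismatch indicator for categorical ones. Ranges are frozen on training
# data; zero-range numeric columns are excluded (with a warning at context
# construction).

#' Build a Gower distance context
#'
#' Precomputes column kinds and numeric ranges on training data so that
#' later point-to-point distances (including to unseen points) use frozen
#' normalization.
#'
#' @param X_table training data frame.
#' @param column_spec optional sidecar data frame (`name`, `kind`); `NULL`
#'   infers kinds from column classes.
#' @return Object of class `gower_context`.
#' @export
gower_context <- function(X_table, column_spec = NULL) {
  stopifnot(is.data.frame(X_table))
  kinds <- if (is.null(column_spec)) {
    vapply(X_table, function(col)
      if (is.numeric(col)) "continuous" else "categorical", character(1))
  } else column_spec$kind[match(names(X_table), column_spec$name)]
  ranges <- rep(NA_real_, ncol(X_table))
  drop <- logical(ncol(X_table))
  for (j in seq_along(X_table)) {
    if (kinds[j] == "continuous") {
      r <- diff(range(X_table[[j]]))
      if (!is.finite(r) || r == 0) {
        warnf("gower_context: numeric column '%s' has zero range; excluded",
              names(X_table)[j])
        drop[j] <- TRUE
      } else ranges[j] <- r
    }
  }
  structure(list(names = names(X_table), kinds = kinds, ranges = ranges,
                 drop = drop), class = "gower_context")
}

#' Gower distance between two points
#'
#' @param x1,x2 single-row data frames (or named lists) with the context's
#'   columns.
#' @param ctx a [gower_context()].
#' @return Dissimilarity in `[0, 1]`.
#' @export
gower_distance <- function(x1, x2, ctx) {
  stopifnot(inherits(ctx, "gower_context"))
  num <- 0; used <- 0L
  for (j in seq_along(ctx$names)) {
    if (ctx$drop[j]) next
    nm <- ctx$names[j]
    v1 <- if (is.data.frame(x1)) x1[[nm]][1] else x1[[nm]]
    v2 <- if (is.data.frame(x2)) x2[[nm]][1] else x2[[nm]]
    if (ctx$kinds[j] == "continuous") {
      num <- num + abs(as.numeric(v1) - as.numeric(v2)) / ctx$ranges[j]
    } else {
      num <- num + as.numeric(as.character(v1) != as.character(v2))
    }
    used <- used + 1L
  }
  if (used == 0L) stopf("gower_distance: no usable columns")
  num / used
}

#' Gower cross-distance matrix
#'
#' Vectorized column-wise computation of all pairwise dissimilarities
#' between the rows of `Xa` and `Xb` under a frozen context.
#'
#' @param Xa,Xb data frames with the context's columns.
#' @param ctx a [gower_context()].
#' @return `nrow(Xa)` x `nrow(Xb)` matrix.
#' @export
gower_matrix <- function(Xa, Xb = Xa, ctx) {
  stopifnot(inherits(ctx, "gower_context"))
  na <- nrow(Xa); nb <- nrow(Xb)
  acc <- matrix(0, na, nb)
  used <- 0L
  for (j in seq_along(ctx$names)) {
    if (ctx$drop[j]) next
    nm <- ctx$names[j]
    if (ctx$kinds[j] == "continuous") {
      a <- as.numeric(Xa[[nm]]); b <- as.numeric(Xb[[nm]])
      acc <- acc + abs(outer(a, b, `-`)) / ctx$ranges[j]
    } else {
      a <- as.character(Xa[[nm]]); b <- as.character(Xb[[nm]])
      acc <- acc + (outer(a, b, `!=`)) * 1
    }
    used <- used + 1L
  }
  if (used == 0L) stopf("gower_matrix: no usable columns")
  acc / used
}
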