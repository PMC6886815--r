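# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' package functions taking an explicit `seed` argument never perturb the
#' global random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
child_seed <- function(seed, index) {
  (as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix <- function(x) {
  if (is.data.frame(x)) x <- data.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Stratified fold assignment: every class is spread as evenly as possible
# over the folds. Returns an integer vector of fold ids in 1..n_folds.
stratified_folds <- function(y, n_folds, seed) {
  y <- as.integer(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}
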