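# Independent oracles used against the package implementations. These are
# deliberately naive (enumeration / brute force) and share no code with
# the functions they check.

# All-pairs concordance AUC (ties count one half).
brute_force_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Canonical string of an unlabeled simple graph: lexicographic minimum of
# the upper-triangle bits over all node permutations.
canon_graph <- function(A) {
  n <- nrow(A)
  if (is.null(n) || n == 0L) return("0|")
  if (n == 1L) return("1|")
  best <- NULL
  for (p in perms_of(seq_len(n))) {
    Ap <- A[p, p, drop = FALSE]
    s <- paste0(n, "|", paste(Ap[upper.tri(Ap)], collapse = ""))
    if (is.null(best) || s < best) best <- s
  }
  best
}

# One adjacency-matrix representative per isomorphism class on n nodes.
iso_class_reps <- function(n) {
  if (n == 1L) return(list(matrix(0L, 1, 1)))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ne <- nrow(ut)
  seen <- character(0)
  reps <- list()
  for (mask in 0:(2^ne - 1)) {
    A <- matrix(0L, n, n)
    bits <- as.integer(intToBits(mask))[seq_len(ne)]
    sel <- which(bits == 1L)
    if (length(sel)) {
      A[ut[sel, , drop = FALSE]] <- 1L
      A <- A + t(A)
    }
    key <- canon_graph(A)
    if (!key %in% seen) {
      seen <- c(seen, key)
      reps[[length(reps) + 1L]] <- A
    }
  }
  reps
}

# Unit-cost GED oracle: Dijkstra over graph states under single edit moves
# (edge toggle: 1; node deletion: 1 + degree; isolated node insertion: 1),
# states canonicalized up to isomorphism and bounded at max(n1, n2) nodes.
ged_dijkstra_oracle <- function(A1, A2) {
  maxn <- max(nrow(A1), nrow(A2))
  target <- canon_graph(A2)
  frontier <- list(list(A = A1, d = 0))
  done <- character(0)
  repeat {
    if (length(frontier) == 0L) stop("oracle: target unreachable")
    ds <- vapply(frontier, `[[`, numeric(1), "d")
    i <- which.min(ds)
    st <- frontier[[i]]
    frontier[[i]] <- NULL
    key <- canon_graph(st$A)
    if (key %in% done) next
    if (key == target) return(st$d)
    done <- c(done, key)
    push <- function(A, cost) {
      k <- canon_graph(A)
      if (!(k %in% done))
        frontier[[length(frontier) + 1L]] <<- list(A = A, d = st$d + cost)
    }
    n <- nrow(st$A)
    if (n >= 2L) {
      for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
        A <- st$A
        A[a, b] <- A[b, a] <- 1L - A[a, b]
        push(A, 1)
      }
    }
    if (n >= 1L) {
      for (v in seq_len(n)) {
        deg <- sum(st$A[v, ])
        A <- st$A[-v, -v, drop = FALSE]
        push(A, 1 + deg)
      }
    }
    if (n < maxn) {
      A <- matrix(0L, n + 1L, n + 1L)
      if (n >= 1L) A[seq_len(n), seq_len(n)] <- st$A
      push(A, 1)
    }
  }
}

# Small mixed-type table used by several fixtures.
make_mixed_table <- function(n = 60, seed = 1) {
  withr::with_seed(seed, data.frame(
    num1 = rnorm(n), num2 = runif(n, 0, 10),
    cat1 = sample(c("a", "b", "c"), n, replace = TRUE),
    cat2 = sample(c("x", "y"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}
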