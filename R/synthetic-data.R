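# Seeded generators emulating the statistical structure the workflow
# assumes: an imbalanced mixed-type cohort with latent group structure
# along the dominant variance direction and group-dependent (possibly
# sign-flipped) feature-outcome relationships; a noisy circle for Mapper
# geometry checks; and orthogonal regression designs for the decomposable
# direct-sum property.

#' Cohort generator specification
#'
#' The defaults emulate a readmission-style cohort: 776 patients, 17.3%
#' minority class, mixed categorical/continuous features, two latent
#' groups separated along the leading principal direction, with the
#' feature-outcome coefficients sign-flipped between groups.
#'
#' Numeric features split into a "structural" block (group-shifted along a
#' common direction; this is what makes the first principal component
#' separate the groups) and an "effect" block carrying the logistic
#' coefficients `base_coefs`. Categorical features have group-dependent
#' level probabilities and no direct outcome effect.
#'
#' @param n cohort size.
#' @param n_numeric numeric feature count (first half structural, second
#'   half effect-carrying).
#' @param n_categorical categorical feature count.
#' @param cat_levels levels per categorical column (recycled).
#' @param minority_frac target outcome prevalence in (0, 1).
#' @param n_groups latent group count (>= 1).
#' @param effect_flip per-group sign multiplier on `base_coefs`; default
#'   alternating `+1, -1, ...`.
#' @param base_coefs logistic coefficients over the numeric columns;
#'   default 0 on the structural block and alternating ~1-magnitude
#'   values on the effect block.
#' @param group_sep distance between adjacent group centers along the
#'   structural direction, in noise-SD units.
#' @param noise_sd within-group numeric noise SD.
#' @param seed integer seed.
#' @export
cohort_spec <- function(n = 776L, n_numeric = 6L, n_categorical = 3L,
                        cat_levels = c(3L, 2L, 4L), minority_frac = 0.173,
                        n_groups = 2L, effect_flip = NULL, base_coefs = NULL,
                        group_sep = 6, noise_sd = 1, seed = 1L) {
  if (minority_frac <= 0 || minority_frac >= 1)
    stopf("cohort_spec: minority_frac must lie in (0, 1)")
  if (n_groups < 1L) stopf("cohort_spec: n_groups must be >= 1")
  if (is.null(effect_flip)) effect_flip <- rep_len(c(1, -1), n_groups)
  if (length(effect_flip) != n_groups)
    stopf("cohort_spec: effect_flip must have one entry per group")
  n_struct <- max(1L, floor(n_numeric / 2))
  if (is.null(base_coefs)) {
    n_eff <- n_numeric - n_struct
    base_coefs <- c(rep(0, n_struct),
                    rep_len(c(1.5, -1.0, 1.2, -0.8), n_eff))
  }
  if (length(base_coefs) != n_numeric)
    stopf("cohort_spec: base_coefs must have one entry per numeric column")
  structure(list(n = as.integer(n), n_numeric = as.integer(n_numeric),
                 n_categorical = as.integer(n_categorical),
                 cat_levels = rep_len(as.integer(cat_levels),
                                      max(n_categorical, 1L)),
                 minority_frac = minority_frac, n_groups = as.integer(n_groups),
                 effect_flip = effect_flip, base_coefs = base_coefs,
                 n_struct = n_struct, group_sep = group_sep,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Bisection on a common intercept so the mean Bernoulli probability over
# the realized linear predictors equals the target prevalence.
calibrate_intercept <- function(eta, target, tol = 1e-4, bounds = c(-30, 30)) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  lo <- bounds[1]; hi <- bounds[2]
  if (f(lo) > 0 || f(hi) < 0)
    stopf("prevalence %.3f unreachable within intercept bounds [%g, %g]",
          target, lo, hi)
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < tol) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Generate an imbalanced mixed-type cohort with latent groups
#'
#' See [cohort_spec()] for the generative model. The outcome is
#' `Bernoulli(plogis(intercept + flip_g * base_coefs . x_num))` with the
#' intercept calibrated by bisection (tolerance 1e-4 in probability) so
#' the mean probability equals `minority_frac`.
#'
#' @param spec a [cohort_spec()].
#' @param n_positive optional exact positive count; when given, positives
#'   are drawn without replacement with probability proportional to the
#'   model probabilities instead of independent Bernoulli draws.
#' @return List with `X_table` (data frame), `y` (integer 0/1), `group`
#'   (integer labels), `probs`, `intercept`, and the `spec`.
#' @export
generate_mixed_imbalanced <- function(spec, n_positive = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    group <- sample.int(spec$n_groups, n, replace = TRUE)
    centers <- (seq_len(spec$n_groups) - (spec$n_groups + 1) / 2) * spec$group_sep
    u <- rep(1 / sqrt(spec$n_struct), spec$n_struct)
    Xnum <- matrix(stats::rnorm(n * spec$n_numeric, sd = spec$noise_sd),
                   n, spec$n_numeric)
    Xnum[, seq_len(spec$n_struct)] <- Xnum[, seq_len(spec$n_struct)] +
      outer(centers[group], u)
    colnames(Xnum) <- paste0("num", seq_len(spec$n_numeric))
    cats <- list()
    if (spec$n_categorical > 0L) {
      for (j in seq_len(spec$n_categorical)) {
        L <- spec$cat_levels[j]
        lv <- paste0("c", j, "_", letters[seq_len(L)])
        col <- character(n)
        for (g in seq_len(spec$n_groups)) {
          idx <- which(group == g)
          pr <- rep(1, L)
          pr[1 + (g - 1) %% L] <- 2.5   # group-favored level
          col[idx] <- sample(lv, length(idx), replace = TRUE, prob = pr / sum(pr))
        }
        cats[[paste0("cat", j)]] <- col
      }
    }
    eta <- as.numeric(Xnum %*% spec$base_coefs) * spec$effect_flip[group]
    intercept <- calibrate_intercept(eta, spec$minority_frac)
    probs <- stats::plogis(intercept + eta)
    y <- if (is.null(n_positive)) {
      stats::rbinom(n, 1L, probs)
    } else {
      yy <- integer(n)
      yy[sample.int(n, n_positive, prob = probs)] <- 1L
      yy
    }
    X_table <- data.frame(Xnum, cats, stringsAsFactors = FALSE)
    list(X_table = X_table, y = as.integer(y), group = group, probs = probs,
         intercept = intercept, spec = spec)
  })
}

#' Summarize a binary cohort
#'
#' @param y binary outcome vector.
#' @return List with `n`, `n_positive`, `prevalence` (fraction) and
#'   `prevalence_pct` (percent, as tables print it).
#' @export
cohort_summary <- function(y) {
  y <- as.integer(y)
  n <- length(y); npos <- sum(y == 1L)
  list(n = n, n_positive = npos, prevalence = npos / n,
       prevalence_pct = 100 * npos / n)
}

#' Noisy circle point cloud
#'
#' Points at `radius + N(0, noise_sd)` radial distance and uniform angle;
#' the Mapper graph of this cloud under a height filtration should contain
#' a cycle, mirroring the Reeb graph of the circle.
#'
#' @param n points (>= 50); `radius`, `noise_sd`, `seed` as named.
#' @return n x 2 matrix.
#' @export
generate_noisy_circle <- function(n, radius = 1, noise_sd = 0.05, seed = 1L) {
  if (n < 50L) stopf("generate_noisy_circle: n must be >= 50")
  with_seed(seed, {
    theta <- stats::runif(n, 0, 2 * pi)
    r <- radius + stats::rnorm(n, sd = noise_sd)
    cbind(x = r * cos(theta), y = r * sin(theta))
  })
}

#' Orthogonal regression design
#'
#' Gram-Schmidt (QR) orthonormalization of a seeded Gaussian matrix gives
#' columns with `X'X` diagonal to machine precision; the response is
#' `X p_true + noise`. The fixture on which independent per-column
#' least-squares fits provably equal the joint fit.
#'
#' @param n rows (>= m); `m` columns; `noise_sd` response noise;
#'   `p_true` optional coefficients (default seeded Uniform(-2, 2));
#'   `seed` integer seed.
#' @return List with `X`, `Y`, `p_true`.
#' @export
generate_orthogonal_design <- function(n, m, noise_sd = 0.1, p_true = NULL,
                                       seed = 1L) {
  if (n < m) stopf("generate_orthogonal_design: need n >= m")
  with_seed(seed, {
    G <- matrix(stats::rnorm(n * m), n, m)
    X <- qr.Q(qr(G))
    if (is.null(p_true)) p_true <- stats::runif(m, -2, 2)
    Y <- as.numeric(X %*% p_true) + stats::rnorm(n, sd = noise_sd)
    list(X = X, Y = Y, p_true = p_true)
  })
}

#' Write a synthetic cohort to CSV with sidecars
#'
#' Writes `<prefix>.csv` (features + outcome column `y`),
#' `<prefix>.columns.json` (column-type sidecar) and
#' `<prefix>.truth.json` (group labels, coefficients, intercept).
#'
#' @param cohort a [generate_mixed_imbalanced()] result; `prefix` path
#'   prefix.
#' @export
write_cohort <- function(cohort, prefix) {
  df <- cbind(cohort$X_table, y = cohort$y)
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  sidecar <- data.frame(
    name = names(cohort$X_table),
    kind = vapply(cohort$X_table, function(col)
      if (is.numeric(col)) "continuous" else "categorical", character(1)))
  jsonlite::write_json(sidecar, paste0(prefix, ".columns.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(group = cohort$group,
                            base_coefs = cohort$spec$base_coefs,
                            effect_flip = cohort$spec$effect_flip,
                            intercept = cohort$intercept),
                       paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a cohort CSV plus its column-type sidecar
#'
#' @param csv path to the CSV; `sidecar` path to the columns JSON
#'   (default `sub(".csv", ".columns.json", csv)`); `outcome` outcome
#'   column name.
#' @return List with `X_table`, `y`, `column_spec`.
#' @export
read_cohort <- function(csv, sidecar = NULL, outcome = "y") {
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  if (!outcome %in% names(df)) stopf("outcome column '%s' not found", outcome)
  y <- as.integer(df[[outcome]])
  X <- df[setdiff(names(df), outcome)]
  spec <- NULL
  if (is.null(sidecar)) {
    cand <- sub("\\.csv$", ".columns.json", csv)
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar)) {
    spec <- jsonlite::fromJSON(sidecar)
    for (nm in spec$name[spec$kind == "categorical"])
      if (nm %in% names(X)) X[[nm]] <- as.character(X[[nm]])
  }
  list(X_table = X, y = y, column_spec = spec)
}
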