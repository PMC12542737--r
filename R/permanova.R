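#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Single-factor PERMANOVA on a distance matrix: the squared distances are
#' Gower double-centered, the total sum of squares is partitioned into the
#' between-group and residual components via the hat matrix of the group
#' model, and the pseudo-F statistic is referred to its permutation
#' distribution over random relabelings of the samples. The p-value uses
#' the add-one estimator `(1 + #{F* >= F}) / (n_perm + 1)`, so p is never 0
#' and is bounded below by `1/(n_perm + 1)`.
#'
#' On one-dimensional Euclidean embeddings the R-squared equals the
#' classical ANOVA between/total sum-of-squares ratio.
#'
#' @param dist_obj A [stats::dist] object or square symmetric matrix.
#' @param indicator Group labels (factor, character or numeric), one per
#'   sample, aligned to the distance matrix.
#' @param n_perm Number of permutations (the study default is 10,000).
#' @param seed Integer seed making the permutation p-value reproducible.
#' @return An object of class `"dm_permanova"`: a list with `f_statistic`,
#'   `r_squared`, `p_value`, `df`, `n_permutations`, `n`.
#' @export
permanova <- function(dist_obj, indicator, n_perm = 10000, seed = 1) {
  d <- as.matrix(dist_obj)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    abort("`dist_obj` must be a square symmetric distance matrix.")
  }
  g <- factor(indicator)
  if (nlevels(g) < 2) abort("PERMANOVA needs a non-constant grouping indicator.")
  n <- nrow(d)
  if (length(g) != n) abort("Indicator length must match the distance matrix.")

  # Gower double-centering of -d^2/2
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  sst <- sum(diag(G))

  f_of <- function(gg) {
    X <- model.matrix(~gg)
    H <- X %*% solve(crossprod(X), t(X))
    ssb <- sum(H * G) # tr(HG), H symmetric idempotent
    df1 <- nlevels(gg) - 1L
    df2 <- n - nlevels(gg)
    list(ssb = ssb, f = (ssb / df1) / ((sst - ssb) / df2), df1 = df1, df2 = df2)
  }
  obs <- f_of(g)

  perm_f <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) f_of(g[sample.int(n)])$f, numeric(1))
  })
  p <- (1 + sum(perm_f >= obs$f - 1e-12)) / (n_perm + 1)

  structure(
    list(f_statistic = obs$f, r_squared = obs$ssb / sst, p_value = p,
         df = c(obs$df1, obs$df2), n_permutations = n_perm, n = n),
    class = "dm_permanova"
  )
}

#' @export
print.dm_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: F(%d, %d) = %.4f, R^2 = %.4g, p = %.4g (%d permutations, n = %d)\n",
    x$df[1], x$df[2], x$f_statistic, x$r_squared, x$p_value,
    x$n_permutations, x$n
  ))
  invisible(x)
}

#' Per-drug PERMANOVA over a cohort
#'
#' Runs a single-factor PERMANOVA of the Aitchison distances against each
#' drug's case/control indicator, on the subjects of that drug's arms.
#'
#' @param groups Case/control tibble from [build_q_groups()].
#' @param dist_obj Distances over the full cohort ([aitchison_distance()]).
#' @param n_perm,seed Passed to [permanova()] (each drug gets a distinct
#'   derived seed).
#' @return Tibble: `drug_code`, `r_squared`, `f_statistic`, `p_value`,
#'   `n_permutations`, `n`.
#' @export
permanova_by_drug <- function(groups, dist_obj, n_perm = 10000, seed = 1) {
  dmat <- as.matrix(dist_obj)
  drugs <- sort(unique(groups$drug_code))
  purrr::imap(split(groups, groups$drug_code), function(g, drug) {
    ids <- intersect(g$subject_id, rownames(dmat))
    g <- g[match(ids, g$subject_id), ]
    if (length(unique(g$role)) < 2) return(NULL)
    sub_seed <- (seed + match(drug, drugs) * 7919L) %% .Machine$integer.max
    res <- permanova(dmat[ids, ids], g$role, n_perm = n_perm, seed = sub_seed)
    tibble(drug_code = drug, r_squared = res$r_squared,
           f_statistic = res$f_statistic, p_value = res$p_value,
           n_permutations = n_perm, n = res$n)
  }) |>
    bind_rows()
}
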