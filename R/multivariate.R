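#' Variance partitioning by distance-based redundancy analysis
#'
#' Community variation (Aitchison distances) is partitioned over candidate
#' factors — active drug usage as binary traits, past drug usage as
#' prescription counts, diseases, lifestyle, dietary and anthropometric
#' factors — by constrained ordination on the distance matrix
#' ([vegan::dbrda()]). Factors enter by forward selection: at each step the
#' candidate with the smallest marginal permutation p-value (given the
#' factors already selected) is added while that p-value clears the entry
#' threshold. Each selected factor's conditional R-squared is the variance
#' it constrains given all other selected factors (via `Condition()`
#' partialling), so the conditional contributions need not sum to the joint
#' constrained R-squared.
#'
#' @param dist_obj Distance object or square matrix; must be Euclidean-
#'   embeddable (Aitchison distances are). Non-Euclidean input is rejected.
#' @param factors Tibble: `subject_id` plus one numeric/binary column per
#'   factor, aligned to the distance matrix by id.
#' @param factor_groups Optional named character vector mapping factor
#'   columns to group labels (e.g. `"active_drug"`, `"past_drug"`,
#'   `"disease"`).
#' @param entry_alpha Permutation p-value a candidate must beat to enter.
#' @param n_perm Permutations per marginal test.
#' @param seed Integer seed for the permutation tests.
#' @param max_steps Cap on the number of selected factors.
#' @param check_euclidean Verify the Gower spectrum is nonnegative first.
#' @return Class `"dm_partition"` tibble: `factor_id`, `factor_group`,
#'   `selected`, `step`, `p_enter`, `conditional_r2`; attribute
#'   `joint_r2` holds the constrained R-squared of the joint selected
#'   model.
#' @export
dbrda_forward <- function(dist_obj, factors, factor_groups = NULL,
                          entry_alpha = 0.05, n_perm = 999, seed = 1,
                          max_steps = Inf, check_euclidean = TRUE) {
  dmat <- as.matrix(dist_obj)
  ids <- intersect(rownames(dmat), factors$subject_id)
  fx <- factors[match(ids, factors$subject_id), , drop = FALSE]
  fx <- fx[complete.cases(fx), , drop = FALSE]
  ids <- fx$subject_id
  dmat <- dmat[ids, ids]
  dd <- stats::as.dist(dmat)
  df <- as.data.frame(select(fx, -"subject_id"))
  cand_all <- names(df)

  if (check_euclidean) {
    A <- -0.5 * dmat^2
    G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev))) {
      abort("Distance matrix is not Euclidean-embeddable; dbRDA variance fractions would be ill-defined.")
    }
  }

  marginal_test <- function(cand, selected, perm_seed) {
    rhs <- cand
    if (length(selected) > 0) {
      rhs <- paste(rhs, "+ Condition(", paste(selected, collapse = " + "), ")")
    }
    m <- vegan::dbrda(stats::as.formula(paste("dd ~", rhs)), data = df)
    an <- withr::with_seed(perm_seed, vegan::anova.cca(m, permutations = n_perm))
    list(p = an[1, "Pr(>F)"], f = an[1, "F"],
         r2 = m$CCA$tot.chi / m$tot.chi)
  }

  selected <- character()
  steps <- list()
  step <- 0L
  while (length(selected) < min(max_steps, length(cand_all)) &&
         length(selected) < nrow(df) - 2L) {
    step <- step + 1L
    remaining <- setdiff(cand_all, selected)
    trials <- purrr::map(remaining, function(cand) {
      perm_seed <- (seed + step * 1009L +
                      match(cand, cand_all) * 97L) %% .Machine$integer.max
      res <- marginal_test(cand, selected, perm_seed)
      tibble(factor_id = cand, p = res$p, f = res$f)
    }) |>
      bind_rows() |>
      arrange(.data$p, dplyr::desc(.data$f))
    best <- trials[1, ]
    if (is.na(best$p) || best$p >= entry_alpha) break
    selected <- c(selected, best$factor_id)
    steps[[best$factor_id]] <- mutate(best, step = step)
  }

  cond_r2 <- purrr::map_dbl(cand_all, function(fid) {
    if (!fid %in% selected) return(NA_real_)
    others <- setdiff(selected, fid)
    marginal_test(fid, others, seed)$r2
  })

  joint_r2 <- if (length(selected) > 0) {
    m <- vegan::dbrda(
      stats::as.formula(paste("dd ~", paste(selected, collapse = " + "))),
      data = df
    )
    m$CCA$tot.chi / m$tot.chi
  } else 0

  enter <- bind_rows(steps)
  out <- tibble(
    factor_id = cand_all,
    factor_group = if (is.null(factor_groups)) NA_character_ else
      unname(factor_groups[cand_all]),
    selected = cand_all %in% selected,
    step = if (nrow(enter)) enter$step[match(cand_all, enter$factor_id)] else NA_integer_,
    p_enter = if (nrow(enter)) enter$p[match(cand_all, enter$factor_id)] else NA_real_,
    conditional_r2 = cond_r2
  ) |>
    arrange(.data$step)
  attr(out, "joint_r2") <- joint_r2
  class(out) <- c("dm_partition", class(out))
  out
}

#' Explained variance per factor group
#'
#' @param partition Result of [dbrda_forward()].
#' @return Tibble of summed conditional R-squared per factor group over the
#'   selected factors.
#' @export
partition_by_group <- function(partition) {
  partition |>
    filter(.data$selected) |>
    group_by(.data$factor_group) |>
    summarise(conditional_r2 = sum(.data$conditional_r2),
              n_factors = dplyr::n(), .groups = "drop")
}
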