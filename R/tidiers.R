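#' Tidiers for fitted result objects
#'
#' `tidy()` returns one row per estimated quantity; `glance()` returns a
#' one-row model summary.
#'
#' @param x A fitted result object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy dm_permanova
#' @export
tidy.dm_permanova <- function(x, ...) {
  tibble(
    term = c("model", "residual"),
    df = c(x$df[1], x$df[2]),
    r_squared = c(x$r_squared, 1 - x$r_squared),
    statistic = c(x$f_statistic, NA_real_),
    p_value = c(x$p_value, NA_real_)
  )
}

#' @rdname tidiers
#' @method glance dm_permanova
#' @export
glance.dm_permanova <- function(x, ...) {
  tibble(r_squared = x$r_squared, statistic = x$f_statistic,
         p_value = x$p_value, n = x$n, n_permutations = x$n_permutations)
}

#' @rdname tidiers
#' @method tidy dm_transfer
#' @export
tidy.dm_transfer <- function(x, ...) {
  x$repeats |>
    select("repeat_id", "auroc", "auroc_self", "n_test", "n_target_cases")
}

#' @rdname tidiers
#' @method glance dm_transfer
#' @export
glance.dm_transfer <- function(x, ...) {
  tibble(auroc = x$auroc, n_repeats = x$n_repeats,
         auroc_sd = sd(x$repeats$auroc, na.rm = TRUE))
}

#' @rdname tidiers
#' @method tidy dm_abx_model
#' @export
tidy.dm_abx_model <- function(x, ...) {
  cf <- as.matrix(coef(x$fit, s = x$lambda))
  tibble(term = rownames(cf), estimate = cf[, 1]) |>
    filter(.data$estimate != 0)
}

#' @rdname tidiers
#' @method glance dm_abx_model
#' @export
glance.dm_abx_model <- function(x, ...) {
  tibble(alpha = x$alpha, lambda = x$lambda, cv_auroc = x$cv_auc,
         auroc_self = x$auroc_self,
         n_train = length(x$train_ids), n_test = length(x$test_ids))
}

#' @rdname tidiers
#' @method tidy dm_partition
#' @export
tidy.dm_partition <- function(x, ...) {
  as_tibble(x) |>
    filter(.data$selected) |>
    select("factor_id", "factor_group", "step", "p_enter", "conditional_r2")
}

#' @rdname tidiers
#' @method glance dm_partition
#' @export
glance.dm_partition <- function(x, ...) {
  tibble(joint_r2 = attr(x, "joint_r2"), n_selected = sum(x$selected),
         n_candidates = nrow(x))
}
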