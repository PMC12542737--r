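#' Two-timepoint (T1/T2) delta analysis
#'
#' Within-subject change in CLR-transformed abundance between two sampling
#' time points is the response for drug initiation, post-initiation
#' carryover and discontinuation models. Each time point's CLR matrix is
#' computed with its own pseudocount; the delta is the aligned difference
#' CLR(T2) - CLR(T1) over the subjects present at both time points.
#'
#' @name longitudinal
NULL

#' Build the CLR change matrix between two time points
#'
#' @param clr_t1,clr_t2 CLR matrices from [clr_transform()], sharing the
#'   same taxon columns (any column order).
#' @return Matrix of CLR(T2) - CLR(T1), rows restricted to the common
#'   subjects; subjects present at only one time point are dropped with a
#'   message.
#' @export
build_delta <- function(clr_t1, clr_t2) {
  if (!setequal(colnames(clr_t1), colnames(clr_t2))) {
    abort("The two CLR matrices must share the same taxon columns.")
  }
  common <- intersect(rownames(clr_t1), rownames(clr_t2))
  if (length(common) == 0) abort("No subjects are present at both time points.")
  dropped <- (nrow(clr_t1) - length(common)) + (nrow(clr_t2) - length(common))
  if (dropped > 0) {
    inform(sprintf("Dropping %d subject row(s) present at only one time point.", dropped))
  }
  out <- clr_t2[common, colnames(clr_t1), drop = FALSE] -
    clr_t1[common, , drop = FALSE]
  if (any(!is.finite(out))) abort("Delta profile contains non-finite values.")
  out
}

#' Fit a covariate-adjusted model on one delta-response
#'
#' Same estimator contract as [fit_abundance_model()] with the
#' within-subject CLR change as the response: the effect size is the
#' partial Pearson correlation of the change with the group indicator
#' given age, gender and BMI (age taken at T1).
#'
#' @inheritParams fit_abundance_model
#' @export
fit_delta_model <- function(data, response, indicator,
                            covariates = c("age", "gender", "bmi")) {
  fit_abundance_model(data, response, indicator, covariates)
}

#' Q4 association testing on CLR changes
#'
#' Runs the delta models for every drug in a Q4 case/control grouping
#' (initiation, post-initiation carryover, or discontinuation) across the
#' taxon columns of the delta matrix.
#'
#' @param groups Q4 case/control tibble from [build_q_groups()].
#' @param delta Matrix from [build_delta()].
#' @param subjects Subject covariate tibble.
#' @param covariates Adjustment covariates.
#' @param taxa Optional named list restricting the taxa tested per drug.
#' @return Association records (partial r effect sizes) as from
#'   [associate()].
#' @export
associate_delta <- function(groups, delta, subjects,
                            covariates = c("age", "gender", "bmi"),
                            taxa = NULL) {
  associate(groups, delta, subjects, response_kind = "abundance",
            covariates = covariates, taxa = taxa)
}
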