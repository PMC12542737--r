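#' Nested-model confounder analysis
#'
#' A naive drug-taxon association is interrogated against a panel of
#' candidate confounders (other drugs, prevalent diseases, lifestyle,
#' dietary and anthropometric factors). For each candidate, two nested
#' model comparisons are run on the same subjects, both adjusted for the
#' base covariates (age, gender, BMI):
#' * test A — does the drug add signal on top of the candidate?
#'   full (base + candidate + drug) vs reduced (base + candidate);
#' * test B — does the candidate add signal on top of the drug?
#'   full vs (base + drug).
#'
#' The association is *confounded* when at least one candidate adds signal
#' while the drug does not (given that candidate); otherwise it is
#' *confidently deconfounded*. Gaussian responses use the partial F-test,
#' binary responses the likelihood-ratio test.
#'
#' @name deconfound
NULL

#' Paired nested-model test for one candidate confounder
#'
#' @param data Data frame holding the response, drug indicator, candidate
#'   and base covariates; complete cases are used.
#' @param response Response column name.
#' @param drug Name of the 0/1 drug-usage column.
#' @param candidate Name of the candidate-confounder column.
#' @param base_covariates Always-adjusted covariates.
#' @param alpha Significance level for both nested tests.
#' @param response_kind `"abundance"` (Gaussian, partial F) or
#'   `"presence"` (logistic, LRT).
#' @return One-row tibble: `covariate_id`, `drug_adds_signal`,
#'   `covariate_adds_signal`, `p_drug_given_cov`, `p_cov_given_drug`,
#'   `alpha`, `indeterminate` (TRUE when the candidate is collinear with
#'   the drug indicator).
#' @export
nested_pair_test <- function(data, response, drug, candidate,
                             base_covariates = c("age", "gender", "bmi"),
                             alpha = 0.05,
                             response_kind = c("abundance", "presence")) {
  response_kind <- rlang::arg_match(response_kind)
  cols <- c(response, drug, candidate, base_covariates)
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  if (response_kind == "presence") d[[response]] <- as.numeric(d[[response]] > 0)

  out_shell <- tibble(
    covariate_id = candidate,
    drug_adds_signal = NA, covariate_adds_signal = NA,
    p_drug_given_cov = NA_real_, p_cov_given_drug = NA_real_,
    alpha = alpha, indeterminate = TRUE
  )
  # collinearity guard: a candidate carrying the same information as the
  # drug indicator can never arbitrate between the two
  cand_num <- as.numeric(factor(d[[candidate]]))
  drug_num <- as.numeric(d[[drug]])
  if (var(cand_num) < 1e-12 || var(drug_num) < 1e-12 ||
      abs(cor(cand_num, drug_num)) > 1 - 1e-10) {
    return(out_shell)
  }

  base <- if (length(base_covariates)) paste(base_covariates, collapse = " + ") else "1"
  fit <- function(rhs) {
    f <- stats::as.formula(paste(response, "~", rhs))
    if (response_kind == "abundance") lm(f, data = d) else
      suppressWarnings(glm(f, data = d, family = binomial()))
  }
  full <- fit(paste(base, "+", candidate, "+", drug))
  red_drug <- fit(paste(base, "+", candidate))   # drops the drug
  red_cand <- fit(paste(base, "+", drug))        # drops the candidate
  if (any(is.na(coef(full)))) return(out_shell)  # aliased design

  nested_p <- function(reduced) {
    if (response_kind == "abundance") {
      anova(reduced, full)[2, "Pr(>F)"]
    } else {
      anova(reduced, full, test = "LRT")[2, "Pr(>Chi)"]
    }
  }
  p_drug <- nested_p(red_drug)
  p_cand <- nested_p(red_cand)
  tibble(
    covariate_id = candidate,
    drug_adds_signal = p_drug < alpha,
    covariate_adds_signal = p_cand < alpha,
    p_drug_given_cov = p_drug, p_cov_given_drug = p_cand,
    alpha = alpha, indeterminate = FALSE
  )
}

#' Aggregate per-candidate verdicts into a deconfounding status
#'
#' @param verdicts Tibble of [nested_pair_test()] rows for one drug-taxon
#'   pair across the covariate panel.
#' @return One-row tibble: `status` (`"confidently_deconfounded"` or
#'   `"confounded"`), `blocking_covariates` (list column of the candidates
#'   that explain the association away), `n_candidates`.
#' @export
assign_status <- function(verdicts) {
  if (nrow(verdicts) == 0) {
    warn("Empty covariate panel: association is trivially deconfounded.")
    return(tibble(status = "confidently_deconfounded",
                  blocking_covariates = list(character()),
                  n_candidates = 0L))
  }
  usable <- filter(verdicts, !.data$indeterminate)
  blocking <- usable$covariate_id[usable$covariate_adds_signal &
                                    !usable$drug_adds_signal]
  tibble(
    status = if (length(blocking) > 0) "confounded" else "confidently_deconfounded",
    blocking_covariates = list(blocking),
    n_candidates = nrow(verdicts)
  )
}

#' Deconfound naive drug-taxon associations against a covariate panel
#'
#' Runs the paired nested-model tests for every Q1-significant association
#' and every panel covariate, on the same case/control subjects as the
#' naive model.
#'
#' @param q1_records Q1 association records with `fdr_q`.
#' @param groups Case/control tibble used for the naive associations.
#' @param response_matrix CLR matrix (abundance) or raw profile (presence).
#' @param subjects Subject tibble with the base covariates.
#' @param panel Tibble: `subject_id` plus one column per candidate
#'   confounder (numeric or binary).
#' @param alpha Significance level of the nested tests.
#' @param fdr_threshold Q1 cut defining which pairs are interrogated.
#' @param response_kind `"abundance"` or `"presence"`.
#' @param base_covariates Always-adjusted covariates.
#' @return Tibble with one row per interrogated pair: `drug_code`,
#'   `taxon_id`, `status`, `blocking_covariates`, `n_candidates`. Pairs not
#'   significant at the Q1 cut are reported as `"no_naive_association"`.
#' @export
deconfound <- function(q1_records, groups, response_matrix, subjects, panel,
                       alpha = 0.05, fdr_threshold = 0.1,
                       response_kind = c("abundance", "presence"),
                       base_covariates = c("age", "gender", "bmi")) {
  response_kind <- rlang::arg_match(response_kind)
  candidates <- setdiff(names(panel), "subject_id")
  rec <- mutate(q1_records,
                significant = .data$fdr_q <= fdr_threshold & !is.na(.data$effect))

  purrr::pmap(
    list(rec$drug_code, rec$taxon_id, rec$significant),
    function(drug, taxon, significant) {
      base_row <- tibble(drug_code = drug, taxon_id = taxon)
      if (!significant) {
        return(mutate(base_row, status = "no_naive_association",
                      blocking_covariates = list(character()),
                      n_candidates = 0L))
      }
      g <- filter(groups, .data$drug_code == drug,
                  .data$subject_id %in% rownames(response_matrix))
      d <- g |>
        inner_join(subjects[, c("subject_id", base_covariates)],
                   by = "subject_id") |>
        inner_join(panel, by = "subject_id") |>
        mutate(.drug = as.numeric(.data$role == "case"))
      d$.resp <- response_matrix[d$subject_id, taxon]
      verdicts <- purrr::map(candidates, function(cand) {
        nested_pair_test(d, ".resp", ".drug", cand,
                         base_covariates = base_covariates, alpha = alpha,
                         response_kind = response_kind)
      }) |>
        bind_rows()
      dplyr::bind_cols(base_row, assign_status(verdicts))
    }
  ) |>
    bind_rows()
}
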