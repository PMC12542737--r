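#' Competing additive-effect models (M1/M2/M3) compared by AIC
#'
#' Cumulative drug effects are probed with three nested-in-spirit models of
#' increasing complexity, all adjusted for age, gender and BMI:
#' * M1 — active usage only (binary),
#' * M2 — active usage + any past usage in the 5-year lookback (binary),
#' * M3 — active usage + number of past prescriptions (count, with the
#'   active-defining prescriptions excluded).
#'
#' A more complex model beats the simpler one only when its AIC is lower by
#' more than 2. M2 and M3 are not nested in each other; when both clear the
#' threshold the lower AIC wins and an exact tie falls to M2 (the model with
#' fewer assumptions about dose-response). The analysis population is all
#' subjects — active, former and never users — since M2/M3 need variation in
#' past usage among the non-active.
#'
#' @name model_selection
NULL

#' The AIC decision rule for the M1/M2/M3 race
#'
#' A complex model (M2 or M3) is eligible only when `aic_m1 - aic_complex >
#' delta`; among eligible models the lower AIC wins and an exact tie falls
#' to M2. `NA` entries (non-identifiable models) are out of the race.
#'
#' @param aic_m1,aic_m2,aic_m3 AIC values of the three fits.
#' @param delta Margin a complex model must clear (default 2).
#' @return `"M1"`, `"M2"` or `"M3"`.
#' @export
aic_decision <- function(aic_m1, aic_m2, aic_m3, delta = 2) {
  cand <- c(M2 = aic_m2, M3 = aic_m3)
  eligible <- names(cand)[!is.na(cand) & (aic_m1 - cand) > delta]
  if (length(eligible) == 0) return("M1")
  if (length(eligible) == 1) return(eligible)
  if (cand["M3"] < cand["M2"]) "M3" else "M2"
}

#' Fit the three competing models for one drug-taxon pair
#'
#' @param data Data frame with the response, exposure and covariate
#'   columns; complete cases are used.
#' @param response Response column: CLR abundance (`response_kind =
#'   "abundance"`) or an abundance/presence column dichotomized at > 0
#'   (`"presence"`).
#' @param response_kind `"abundance"` (Gaussian OLS) or `"presence"`
#'   (logistic; the AIC uses the binomial log-likelihood).
#' @param active Name of the 0/1 active-usage column.
#' @param past Name of the 0/1 any-past-usage column.
#' @param n_prescriptions Name of the past-prescription-count column.
#' @param covariates Adjustment covariates.
#' @param delta AIC margin a complex model must clear (default 2).
#' @return One-row tibble: `aic_m1`, `aic_m2`, `aic_m3`, `best_model`,
#'   `coefficients` (list column with the winning model's coefficients),
#'   `n`.
#' @export
fit_competing <- function(data, response,
                          response_kind = c("abundance", "presence"),
                          active = "active", past = "past_binary",
                          n_prescriptions = "n_past_prescriptions",
                          covariates = c("age", "gender", "bmi"),
                          delta = 2) {
  response_kind <- rlang::arg_match(response_kind)
  cols <- c(response, active, past, n_prescriptions, covariates)
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  if (response_kind == "presence") d[[response]] <- as.numeric(d[[response]] > 0)

  base <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  forms <- list(
    M1 = paste(response, "~", base, "+", active),
    M2 = paste(response, "~", base, "+", active, "+", past),
    M3 = paste(response, "~", base, "+", active, "+", n_prescriptions)
  )
  fit1 <- function(f) {
    if (response_kind == "abundance") {
      lm(stats::as.formula(f), data = d)
    } else {
      glm(stats::as.formula(f), data = d, family = binomial())
    }
  }

  # a constant added term makes the model non-identifiable: drop it from
  # the race rather than fitting an aliased coefficient
  ok_m2 <- length(unique(d[[past]])) > 1
  ok_m3 <- length(unique(d[[n_prescriptions]])) > 1
  fits <- list(M1 = fit1(forms$M1),
               M2 = if (ok_m2) fit1(forms$M2) else NULL,
               M3 = if (ok_m3) fit1(forms$M3) else NULL)
  aics <- purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else AIC(.x))
  best <- aic_decision(aics[["M1"]], aics[["M2"]], aics[["M3"]], delta = delta)
  tibble(
    aic_m1 = aics[["M1"]], aic_m2 = aics[["M2"]], aic_m3 = aics[["M3"]],
    best_model = best,
    coefficients = list(coef(fits[[best]])),
    n = nrow(d)
  )
}

#' Additive-effect model race over Q1-significant pairs
#'
#' For every drug-taxon pair significant for active usage, fits M1/M2/M3 on
#' the whole cohort and records the AIC winner.
#'
#' @param q1_records Q1 association records with `fdr_q`.
#' @param exposures T1 exposure tibble (provides active state, past-usage
#'   indicator and prescription counts).
#' @param response_matrix CLR matrix (abundance) or raw profile (presence).
#' @param subjects Subject covariate tibble.
#' @param response_kind `"abundance"` or `"presence"`.
#' @param fdr_threshold Q1 significance cut.
#' @param covariates Adjustment covariates.
#' @param delta AIC margin.
#' @return Tibble of [fit_competing()] rows keyed by `drug_code` and
#'   `taxon_id`; class `"dm_competing"`.
#' @export
additive_scan <- function(q1_records, exposures, response_matrix, subjects,
                          response_kind = c("abundance", "presence"),
                          fdr_threshold = 0.1,
                          covariates = c("age", "gender", "bmi"),
                          delta = 2) {
  response_kind <- rlang::arg_match(response_kind)
  sig <- filter(q1_records, .data$fdr_q <= fdr_threshold, !is.na(.data$effect))
  if (nrow(sig) == 0) {
    out <- tibble()
    class(out) <- c("dm_competing", class(out))
    return(out)
  }
  out <- purrr::pmap(
    list(sig$drug_code, sig$taxon_id),
    function(drug, taxon) {
      ex <- filter(exposures, .data$drug_code == drug)
      d <- ex |>
        inner_join(subjects, by = "subject_id") |>
        filter(.data$subject_id %in% rownames(response_matrix)) |>
        mutate(
          active = as.numeric(.data$state == "active"),
          past_binary = as.numeric(.data$n_past_prescriptions > 0)
        )
      d$.resp <- response_matrix[d$subject_id, taxon]
      fit_competing(d, ".resp", response_kind = response_kind,
                    covariates = covariates, delta = delta) |>
        mutate(drug_code = drug, taxon_id = taxon)
    }
  ) |>
    bind_rows() |>
    relocate("drug_code", "taxon_id")
  class(out) <- c("dm_competing", class(out))
  out
}

#' Per-drug proportions of winning models
#'
#' @param fits Tibble from [additive_scan()] (or any tibble with
#'   `drug_code` and `best_model`).
#' @return Tidy tibble: `drug_code`, `best_model`, `n`, `proportion`
#'   (summing to 1 within each drug). Empty input gives an empty tibble.
#' @export
summarize_best_models <- function(fits) {
  if (nrow(fits) == 0) {
    return(tibble(drug_code = character(), best_model = character(),
                  n = integer(), proportion = numeric()))
  }
  fits |>
    count(.data$drug_code, best_model = factor(.data$best_model,
                                               levels = c("M1", "M2", "M3"))) |>
    tidyr::complete(.data$drug_code, .data$best_model, fill = list(n = 0L)) |>
    group_by(.data$drug_code) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(best_model = as.character(.data$best_model))
}
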