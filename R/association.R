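#' Covariate-adjusted drug-taxon association models
#'
#' Abundance associations are ordinary least squares of the CLR-transformed
#' taxon on age, gender, BMI and a case/control indicator; the reported
#' effect size is the partial Pearson correlation between response and
#' indicator given the covariates (the correlation of the two residual
#' vectors after projecting out covariates and intercept), which equals the
#' sign-consistent transform t/sqrt(t^2 + df) of the indicator's
#' t-statistic. Presence-absence associations use logistic regression with a
#' two-sided Wald test on the indicator.
#'
#' @name association
NULL

# Batch partial-correlation fit: Y (n x m) responses, g indicator, X covariates.
# Returns a tibble with one row per column of Y.
partial_r_many <- function(Y, g, X = NULL) {
  n <- length(g)
  Z <- cbind(`(Intercept)` = rep(1, n), X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    return(tibble(taxon_id = colnames(Y) %||% as.character(seq_len(ncol(Y))),
                  effect = NA_real_, p_value = NA_real_, df = NA_integer_,
                  note = "rank-deficient covariates"))
  }
  Q <- qr.Q(qz)
  ry <- Y - Q %*% crossprod(Q, Y)
  rg <- as.numeric(g - Q %*% crossprod(Q, g))
  ss_g <- sum(rg^2)
  ss_y <- colSums(ry^2)
  df <- n - ncol(Z) - 1L
  if (ss_g < 1e-12 || df < 1) {
    return(tibble(taxon_id = colnames(Y) %||% as.character(seq_len(ncol(Y))),
                  effect = NA_real_, p_value = NA_real_, df = df,
                  note = "indicator collinear with covariates"))
  }
  r <- as.numeric(crossprod(ry, rg)) / unname(sqrt(ss_y * ss_g))
  r[ss_y < 1e-12] <- NA_real_
  # guard rounding at |r| = 1
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  tibble(taxon_id = colnames(Y) %||% as.character(seq_len(ncol(Y))),
         effect = r, p_value = p, df = as.integer(df), note = NA_character_)
}

#' Fit one covariate-adjusted abundance model
#'
#' @param data Data frame with the response, indicator and covariate
#'   columns; complete cases are used.
#' @param response Name of the (CLR abundance or diversity) response column.
#' @param indicator Name of the 0/1 case indicator column.
#' @param covariates Character vector of adjustment covariates (possibly
#'   empty, in which case the partial correlation reduces to the plain
#'   Pearson correlation).
#' @return One-row tibble: `effect` (partial Pearson r), `p_value`, `df`,
#'   `n`, `note`.
#' @export
fit_abundance_model <- function(data, response, indicator,
                                covariates = c("age", "gender", "bmi")) {
  cols <- c(response, indicator, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  Y <- matrix(as.numeric(d[[response]]), ncol = 1,
              dimnames = list(NULL, response))
  X <- if (length(covariates)) as.matrix(d[covariates]) else NULL
  fit <- partial_r_many(Y, as.numeric(d[[indicator]]), X)
  mutate(fit, n = nrow(d)) |> select(-"taxon_id")
}

#' Fit one covariate-adjusted presence-absence model
#'
#' Maximum-likelihood logistic regression of taxon presence on covariates
#' and the case indicator; the effect is the indicator's log-odds
#' coefficient with a two-sided Wald p-value. Perfect separation or a
#' response with a single class yields a flagged `NA` row, never an error.
#'
#' @inheritParams fit_abundance_model
#' @return One-row tibble: `effect` (log-odds), `p_value`, `n`, `note`.
#' @export
fit_presence_model <- function(data, response, indicator,
                               covariates = c("age", "gender", "bmi")) {
  cols <- c(response, indicator, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  y <- as.numeric(d[[response]] > 0)
  if (length(unique(y)) < 2 || length(unique(d[[indicator]])) < 2) {
    return(tibble(effect = NA_real_, p_value = NA_real_, n = nrow(d),
                  note = "constant response or indicator"))
  }
  # events-per-variable reliability floor: the minority presence class must
  # supply ~10 events per estimated parameter or the Wald test degenerates
  n_params <- length(covariates) + 2L
  if (min(table(y)) < 10 * n_params) {
    return(tibble(effect = NA_real_, p_value = NA_real_, n = nrow(d),
                  note = "minority presence class below the EPV floor"))
  }
  rhs <- paste(c(covariates, indicator), collapse = " + ")
  d$.y <- y
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(stats::as.formula(paste(".y ~", rhs)), data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  # glm does not always warn on (quasi-)separation: an essentially infinite
  # log-odds estimate or boundary fitted probabilities are the giveaway
  separated <- separated ||
    any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) ||
    abs(sm[indicator, "Estimate"]) > 30
  if (separated || !fit$converged) {
    return(tibble(effect = NA_real_, p_value = NA_real_, n = nrow(d),
                  note = "separation or non-convergence"))
  }
  tibble(effect = unname(sm[indicator, "Estimate"]),
         p_value = unname(sm[indicator, "Pr(>|z|)"]),
         n = nrow(d), note = NA_character_)
}

#' Drug-taxon association testing across a cohort
#'
#' Runs, for each drug in `groups` and each taxon column of the response
#' matrix, the covariate-adjusted abundance model (on CLR values) or
#' presence-absence model (on the raw profile), restricted to that drug's
#' case/control subjects.
#'
#' @param groups Case/control tibble from [build_q_groups()].
#' @param response_matrix Subjects x taxa matrix: CLR values for
#'   `response_kind = "abundance"`, raw (count or relative) abundances for
#'   `"presence"`.
#' @param subjects Subject tibble with `age`, `gender`, `bmi`.
#' @param response_kind `"abundance"` or `"presence"`.
#' @param covariates Adjustment covariates.
#' @param taxa Optional named list mapping drug codes to the taxon ids to
#'   test for that drug (used when re-testing only previously significant
#'   pairs); default: all columns for every drug.
#' @return Tibble of association records: `drug_code`, `taxon_id`,
#'   `response_kind`, `question`, `effect`, `p_value`, `n_cases`,
#'   `n_controls`, `note`, ordered by (drug, taxon).
#' @export
associate <- function(groups, response_matrix, subjects,
                      response_kind = c("abundance", "presence"),
                      covariates = c("age", "gender", "bmi"),
                      taxa = NULL) {
  response_kind <- rlang::arg_match(response_kind)
  covar_tab <- subjects[, c("subject_id", covariates), drop = FALSE]

  purrr::map(split(groups, groups$drug_code), function(g) {
    ids <- g$subject_id[g$subject_id %in% rownames(response_matrix)]
    g <- filter(g, .data$subject_id %in% ids)
    cov_g <- covar_tab[match(g$subject_id, covar_tab$subject_id), , drop = FALSE]
    keep <- complete.cases(cov_g)
    g <- g[keep, , drop = FALSE]
    cov_g <- cov_g[keep, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    drug <- g$drug_code[1]
    want <- if (is.null(taxa)) colnames(response_matrix) else taxa[[drug]]
    want <- intersect(want, colnames(response_matrix))
    if (length(want) == 0) return(NULL)
    Y <- response_matrix[g$subject_id, want, drop = FALSE]
    ind <- as.numeric(g$role == "case")
    X <- if (length(covariates)) as.matrix(cov_g[covariates]) else NULL
    res <- if (response_kind == "abundance") {
      partial_r_many(Y, ind, X) |> select(-"df")
    } else {
      purrr::map(want, function(tx) {
        d <- as.data.frame(cov_g[covariates])
        d$.abund <- Y[, tx]
        d$.case <- ind
        fit_presence_model(d, ".abund", ".case", covariates) |>
          mutate(taxon_id = tx) |> select(-"n")
      }) |> bind_rows()
    }
    res |>
      mutate(drug_code = drug,
             response_kind = response_kind,
             question = g$question[1],
             n_cases = sum(ind == 1),
             n_controls = sum(ind == 0))
  }) |>
    bind_rows() |>
    relocate("drug_code", "taxon_id", "response_kind", "question") |>
    arrange(.data$drug_code, .data$taxon_id)
}

#' Alpha-diversity association models
#'
#' Same linear-model contract as the abundance models, with observed
#' richness and the Shannon index as responses.
#'
#' @inheritParams associate
#' @param alpha Tibble from [alpha_diversity()].
#' @return Association records with `response_kind` `"richness"` and
#'   `"shannon"` and `taxon_id = NA`.
#' @export
associate_alpha <- function(groups, alpha, subjects,
                            covariates = c("age", "gender", "bmi")) {
  m <- as.matrix(alpha[c("richness", "shannon")])
  rownames(m) <- alpha$subject_id
  associate(groups, m, subjects, response_kind = "abundance",
            covariates = covariates) |>
    mutate(response_kind = .data$taxon_id, taxon_id = NA_character_)
}

#' Benjamini-Hochberg q-values within association families
#'
#' Applies the BH step-up procedure (via [stats::p.adjust()]) within each
#' family of tests; by default one family per (drug, response kind,
#' question), matching per-drug reporting. Set `by = NULL` to pool all
#' records into one family.
#'
#' @param records Association records with a `p_value` column.
#' @param by Character vector of grouping columns, or `NULL` to pool.
#' @return `records` with an `fdr_q` column; input order preserved.
#' @export
add_fdr <- function(records, by = c("drug_code", "response_kind", "question")) {
  if (is.null(by)) {
    return(mutate(records, fdr_q = p.adjust(.data$p_value, method = "BH")))
  }
  records |>
    group_by(across(dplyr::all_of(by))) |>
    mutate(fdr_q = p.adjust(.data$p_value, method = "BH")) |>
    ungroup()
}

#' Carryover-window scan for long-term drug effects
#'
#' Re-tests drug-taxon pairs that were significant for active usage
#' (FDR at or below `fdr_threshold` in the supplied Q1 records) in four
#' carryover scenarios: former users whose last use lies more than 1, 2, 3
#' or 4 years before sampling versus never-users. Windows whose case or
#' control arm falls below `min_group` subjects are skipped with a message.
#'
#' @param q1_records Q1 association records carrying `fdr_q` (from
#'   [associate()] + [add_fdr()]).
#' @param exposures T1 exposure tibble.
#' @param response_matrix CLR matrix (abundance) or raw profile (presence).
#' @param subjects Subject covariate tibble.
#' @param windows Carryover windows in years (cases have
#'   `years_since_last > window`).
#' @param fdr_threshold Q1 significance cut defining the pairs to re-test.
#' @param min_group Minimum subjects per arm within a window.
#' @param response_kind `"abundance"` or `"presence"`.
#' @param exclude_subjects Recent antibiotic users excluded from
#'   human-targeted comparisons.
#' @param covariates Adjustment covariates.
#' @return Association records across windows, with `fdr_q` computed within
#'   each (drug, window) family; class `"dm_carryover"` for plotting.
#' @export
carryover_scan <- function(q1_records, exposures, response_matrix, subjects,
                           windows = c(1, 2, 3, 4),
                           fdr_threshold = 0.1,
                           min_group = 10,
                           response_kind = c("abundance", "presence"),
                           exclude_subjects = NULL,
                           covariates = c("age", "gender", "bmi")) {
  response_kind <- rlang::arg_match(response_kind)
  sig <- filter(q1_records, .data$fdr_q <= fdr_threshold, !is.na(.data$effect))
  if (nrow(sig) == 0) {
    inform("No Q1-significant pairs to scan.")
    return(tibble())
  }
  taxa_by_drug <- split(sig$taxon_id, sig$drug_code)

  out <- purrr::map(windows, function(w) {
    grp <- build_q_groups(
      filter(exposures, .data$drug_code %in% names(taxa_by_drug)),
      question = "Q2", window_years = w,
      exclude_subjects = exclude_subjects, min_cases = min_group
    )
    if (nrow(grp) == 0) return(NULL)
    sizes <- grp |>
      group_by(.data$drug_code) |>
      summarise(ok = sum(.data$role == "case") >= min_group &
                  sum(.data$role == "control") >= min_group,
                .groups = "drop")
    small <- sizes$drug_code[!sizes$ok]
    if (length(small) > 0) {
      inform(sprintf("Window >%gy: skipping %d drug(s) below the group-size floor.",
                     w, length(small)))
    }
    grp <- filter(grp, .data$drug_code %in% sizes$drug_code[sizes$ok])
    if (nrow(grp) == 0) return(NULL)
    associate(grp, response_matrix, subjects, response_kind = response_kind,
              covariates = covariates, taxa = taxa_by_drug) |>
      mutate(window_years = w)
  }) |>
    bind_rows()
  if (nrow(out) > 0) {
    out <- add_fdr(out, by = c("drug_code", "response_kind", "question"))
  }
  class(out) <- c("dm_carryover", class(out))
  out
}

#' Per-window carryover hit counts
#'
#' @param scan Records from [carryover_scan()].
#' @param fdr_threshold Significance cut on the within-window q-values.
#' @return Tibble of hit counts per drug and window.
#' @export
carryover_hits <- function(scan, fdr_threshold = 0.1) {
  if (nrow(scan) == 0) return(tibble())
  scan |>
    group_by(.data$drug_code, .data$window_years) |>
    summarise(n_tested = dplyr::n(),
              n_hits = sum(.data$fdr_q <= fdr_threshold, na.rm = TRUE),
              .groups = "drop")
}

#' Likelihood-ratio test for a dosage effect
#'
#' Compares the covariate-adjusted linear model with dosage entered as an
#' unordered factor against the covariate-only model; the statistic is
#' 2 x the log-likelihood difference on `levels - 1` degrees of freedom.
#'
#' @param data Data frame holding response, covariates and dosage columns.
#' @param response Name of the CLR response column.
#' @param dosage Name of the dosage-class column (factor or coercible).
#' @param covariates Adjustment covariates.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @export
dosage_lrt <- function(data, response, dosage,
                       covariates = c("age", "gender", "bmi")) {
  cols <- c(response, dosage, covariates)
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  d[[dosage]] <- droplevels(factor(d[[dosage]]))
  k <- nlevels(d[[dosage]])
  if (k < 2) abort("Dosage LRT needs at least two dosage levels.")
  if (min(table(d[[dosage]])) < 2) {
    abort("Each dosage level needs at least two subjects.")
  }
  if (var(d[[response]]) < 1e-12) {
    return(tibble(statistic = 0, df = k - 1L, p_value = 1, n = nrow(d)))
  }
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f0 <- lm(stats::as.formula(paste(response, "~", rhs0)), data = d)
  f1 <- lm(stats::as.formula(paste(response, "~", rhs0, "+", dosage)), data = d)
  stat <- as.numeric(2 * (logLik(f1) - logLik(f0)))
  tibble(statistic = stat, df = k - 1L,
         p_value = pchisq(stat, df = k - 1L, lower.tail = FALSE),
         n = nrow(d))
}
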