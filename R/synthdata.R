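#' Synthetic cohort generator with planted drug effects
#'
#' Generates seeded prescription registries, subject tables and paired
#' T1/T2 taxon count matrices in which drug effects are planted on a latent
#' log-abundance scale:
#' * an *active* shift `beta_active` for subjects actively using the drug,
#' * a *carryover* effect `beta_carry * decay(years_since_last)` for former
#'   users, with exponential (half-life `tau`), step or linear decay,
#' * an *additive* slope `beta_add` per past prescription,
#' * an optional presence *elimination* probability for exposed subjects,
#' * confounding-by-indication: a latent disease tilts both drug usage odds
#'   and taxon abundances.
#'
#' Latent log-abundances (taxon baselines, covariate effects, planted
#' effects, Gaussian noise) are closed to relative abundances and sampled
#' to counts by per-subject multinomial draws at a configurable depth, so
#' every downstream stage sees realistic compositional count data. Exposure
#' states used to apply the effects are computed from the generated
#' registry by [classify_exposure()] itself, closing the loop between the
#' generator and the pipeline. All randomness flows from one top-level
#' seed.
#'
#' Drug usage streams follow per-drug regimes — PRN ("as needed") drugs
#' emit sporadic Poisson-process purchases, continuous-regime drugs emit
#' regular refills — and per-user archetypes (ongoing user, past-only user
#' and, when a second time point is simulated, initiator, initiator with
#' carryover, discontinuer) whose weights are part of the configuration, so
#' every study-question arm has a controllable size.
#'
#' @name synthdata
NULL

default_drugs <- function() {
  tibble(
    atc5 = c("J01FA01", "J01FA02", "J01FA09", "J01FA10",
             "N05BA01", "N05BA02", "N05BA06", "N05BA12",
             "A02BC01", "A02BC02", "A02BC03", "A02BC05"),
    regime = rep(c("prn", "prn", "continuous"), each = 4),
    prevalence = 0.25
  )
}

#' Construct a synthetic-truth configuration
#'
#' @param drugs Tibble with columns `atc5`, `regime` (`"prn"` or
#'   `"continuous"`), `prevalence` (5-year ever-user fraction, in (0,1));
#'   default: 12 drugs across 3 ATC4 classes (macrolide-like
#'   antimicrobials, benzodiazepine-like and PPI-like human-targeted
#'   drugs).
#' @param edges Tibble of planted drug-taxon effects with columns
#'   `drug_code` (any ATC level; prefix-matched), `taxon` (index or name),
#'   and any of `beta_active`, `beta_carry`, `tau`, `beta_add`,
#'   `p_eliminate`. Default: none (a global-null cohort).
#' @param n_taxa Number of taxa.
#' @param disease_prevalence Prevalence of the latent indication.
#' @param disease_drug_logodds Log-odds shift of drug usage for diseased
#'   subjects (scalar, or named by drug code).
#' @param disease_taxon_effects Named numeric vector (by taxon) of latent
#'   disease effects on abundance.
#' @param covariate_effect_sd SD of per-taxon age/gender/BMI nuisance
#'   coefficients (on standardized covariates).
#' @param noise_sd Residual SD of latent log-abundance.
#' @param depth Sequencing depth per subject (multinomial size).
#' @param baseline_log_sd SD of taxon baseline log-abundances.
#' @param decay Carryover decay form: `"exponential"` (2^(-y/tau)),
#'   `"step"` (1 while y <= tau), `"linear"` (1 - y/tau, floored at 0).
#' @param prn_rate PRN purchase rate, purchases/year while in use.
#' @param refill_days Refill interval for continuous-regime drugs.
#' @param archetype_weights Named weights for user archetypes; defaults to
#'   `c(ongoing = .4, past_only = .6)` cross-sectionally and
#'   `c(ongoing = .25, past_only = .25, initiator = .2,
#'   initiator_carryover = .15, discontinuer = .15)` with a second time
#'   point.
#' @param follow_up_years T1-to-T2 follow-up (study median 4.4 years).
#' @param t2 Simulate a second time point?
#' @param dosage_levels Optional character vector; when set, each
#'   prescription gets a dosage class sampled uniformly.
#' @return A list of class `"dm_truth"` with the validated configuration.
#' @export
sim_truth <- function(drugs = default_drugs(),
                      edges = NULL,
                      n_taxa = 150,
                      disease_prevalence = 0.2,
                      disease_drug_logodds = 0,
                      disease_taxon_effects = NULL,
                      covariate_effect_sd = 0.05,
                      noise_sd = 1,
                      depth = 1e4,
                      baseline_log_sd = 2,
                      decay = c("exponential", "step", "linear"),
                      prn_rate = 2,
                      refill_days = 30,
                      archetype_weights = NULL,
                      follow_up_years = 4.4,
                      t2 = FALSE,
                      dosage_levels = NULL) {
  decay <- rlang::arg_match(decay)
  validate_atc5(drugs$atc5)
  if (any(drugs$prevalence <= 0 & nrow(edges %||% tibble()) > 0)) {
    abort("A drug with prevalence 0 cannot carry planted effects.")
  }
  if (any(drugs$prevalence < 0 | drugs$prevalence >= 1)) {
    abort("Drug prevalences must lie in [0, 1).")
  }
  taxa_ids <- sprintf("tx%03d", seq_len(n_taxa))
  edges <- edges %||% tibble(drug_code = character(), taxon = character())
  edges <- as_tibble(edges)
  for (col in c("beta_active", "beta_carry", "beta_add")) {
    if (!col %in% names(edges)) edges[[col]] <- 0
  }
  if (!"tau" %in% names(edges)) edges$tau <- 1
  if (!"p_eliminate" %in% names(edges)) edges$p_eliminate <- 0
  if (is.numeric(edges$taxon)) edges$taxon <- taxa_ids[edges$taxon]
  if (any(!edges$taxon %in% taxa_ids)) abort("Edge taxon outside the taxon set.")
  if (any(edges$tau <= 0)) abort("Carryover half-life tau must be positive.")

  if (is.null(archetype_weights)) {
    archetype_weights <- if (t2) {
      c(ongoing = 0.25, past_only = 0.25, initiator = 0.2,
        initiator_carryover = 0.15, discontinuer = 0.15)
    } else {
      c(ongoing = 0.4, past_only = 0.6)
    }
  }
  archetype_weights <- archetype_weights / sum(archetype_weights)

  logodds <- disease_drug_logodds
  if (is.null(names(logodds))) {
    logodds <- setNames(rep(logodds[1], nrow(drugs)), drugs$atc5)
  }
  dte <- setNames(numeric(n_taxa), taxa_ids)
  if (!is.null(disease_taxon_effects)) {
    if (is.numeric(disease_taxon_effects) && is.null(names(disease_taxon_effects))) {
      abort("disease_taxon_effects must be named by taxon id or index.")
    }
    nm <- names(disease_taxon_effects)
    if (all(grepl("^[0-9]+$", nm))) nm <- taxa_ids[as.integer(nm)]
    dte[nm] <- as.numeric(disease_taxon_effects)
  }

  structure(
    list(drugs = drugs, edges = edges, n_taxa = n_taxa, taxa_ids = taxa_ids,
         disease_prevalence = disease_prevalence,
         disease_drug_logodds = logodds,
         disease_taxon_effects = dte,
         covariate_effect_sd = covariate_effect_sd,
         noise_sd = noise_sd, depth = depth,
         baseline_log_sd = baseline_log_sd, decay = decay,
         prn_rate = prn_rate, refill_days = refill_days,
         archetype_weights = archetype_weights,
         follow_up_years = follow_up_years, t2 = t2,
         dosage_levels = dosage_levels),
    class = "dm_truth"
  )
}

decay_factor <- function(years, tau, decay) {
  switch(decay,
    exponential = 2^(-years / tau),
    step = as.numeric(years <= tau),
    linear = pmax(0, 1 - years / tau)
  )
}

# purchase dates for one user x drug given the archetype (days are Dates)
archetype_purchases <- function(archetype, regime, t1, t2_date, window, rate,
                                refill_days, fu_years) {
  yr <- DAYS_PER_YEAR
  prn_span <- function(a, b) { # Poisson purchases over (a, b]
    span_years <- max(as.numeric(b - a) / yr, 0)
    k <- rpois(1, rate * span_years)
    if (k == 0) return(as.Date(character()))
    a + sort(runif(k, 1e-9, as.numeric(b - a)))
  }
  refills <- function(a, b) {
    if (b < a) return(as.Date(character()))
    seq(a, b, by = refill_days)
  }
  anchor <- function(ref) ref - runif(1, 0, window * 0.9) # inside active window

  switch(archetype,
    ongoing = {
      onset <- t1 - runif(1, 1, 4.5) * yr
      end <- if (is.null(t2_date)) t1 else t2_date
      if (regime == "continuous") refills(onset, end)
      else c(prn_span(onset, end), anchor(t1),
             if (!is.null(t2_date)) anchor(t2_date))
    },
    past_only = {
      last <- t1 - runif(1, 0.35, 4.9) * yr
      onset <- max(t1 - 4.99 * yr, last - runif(1, 0.2, 2) * yr)
      if (regime == "continuous") c(refills(onset, last - refill_days), last)
      else c(prn_span(onset, last - 1), last)
    },
    initiator = {
      onset <- t1 + runif(1, 0.3, max(0.4, fu_years - 0.4)) * yr
      if (regime == "continuous") refills(onset, t2_date)
      else c(prn_span(onset, t2_date), anchor(t2_date))
    },
    initiator_carryover = {
      hi <- max(1.3, fu_years - 0.3)
      last <- t2_date - runif(1, 1.1, hi) * yr
      onset <- max(t1 + 2, last - runif(1, 0.1, 0.8) * yr)
      if (regime == "continuous") c(refills(onset, last - refill_days), last)
      else c(prn_span(onset, last - 1), last)
    },
    discontinuer = {
      onset <- t1 - runif(1, 1, 4.5) * yr
      if (regime == "continuous") c(refills(onset, t1 - window * 0.5), anchor(t1))
      else c(prn_span(onset, t1 - window), anchor(t1))
    }
  )
}

#' Generate a synthetic prescription registry and subject table
#'
#' @param truth Configuration from [sim_truth()].
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @return List: `prescriptions` (tibble, one row per dispensing),
#'   `subjects` (tibble incl. the latent `disease` indicator),
#'   `assignments` (tibble of the generator's internal user archetypes,
#'   for round-trip checks).
#' @export
generate_prescriptions <- function(truth, n_subjects = 500, seed = 1) {
  withr::with_seed(seed, {
    t1 <- as.Date("2018-06-01")
    t2_date <- if (truth$t2) t1 + round(truth$follow_up_years * DAYS_PER_YEAR) else NULL
    subjects <- tibble(
      subject_id = sprintf("S%05d", seq_len(n_subjects)),
      age = round(pmin(pmax(rnorm(n_subjects, 50.1, 14.9), 23), 89)),
      gender = rbinom(n_subjects, 1, 0.7),
      bmi = round(pmin(pmax(rnorm(n_subjects, 26.5, 5.3), 15.1), 54), 1),
      disease = rbinom(n_subjects, 1, truth$disease_prevalence),
      t1_date = t1
    )
    if (truth$t2) subjects$t2_date <- t2_date

    arch_names <- names(truth$archetype_weights)
    rows <- list()
    assign <- list()
    for (k in seq_len(nrow(truth$drugs))) {
      drug <- truth$drugs$atc5[k]
      regime <- truth$drugs$regime[k]
      p_use <- stats::plogis(stats::qlogis(pmax(truth$drugs$prevalence[k], 1e-9)) +
                               truth$disease_drug_logodds[[drug]] * subjects$disease)
      users <- which(runif(n_subjects) < p_use)
      if (length(users) == 0) next
      arche <- sample(arch_names, length(users), replace = TRUE,
                      prob = truth$archetype_weights)
      dates <- purrr::map(seq_along(users), function(i) {
        archetype_purchases(arche[i], regime, t1, t2_date, 90,
                            truth$prn_rate, truth$refill_days,
                            truth$follow_up_years)
      })
      n_per <- lengths(dates)
      rows[[drug]] <- tibble(
        subject_id = rep(subjects$subject_id[users], n_per),
        atc5 = drug,
        # dispensing dates are whole calendar days
        date = as.Date(floor(as.numeric(unlist(dates))), origin = "1970-01-01")
      )
      assign[[drug]] <- tibble(subject_id = subjects$subject_id[users],
                               drug_code = drug, archetype = arche)
    }
    prescriptions <- if (length(rows) == 0) {
      tibble(subject_id = character(), atc5 = character(),
             date = as.Date(character()))
    } else {
      arrange(bind_rows(rows), .data$subject_id, .data$atc5, .data$date)
    }
    if (!is.null(truth$dosage_levels) && nrow(prescriptions) > 0) {
      prescriptions$dosage_class <- sample(truth$dosage_levels,
                                           nrow(prescriptions), replace = TRUE)
    }
    list(prescriptions = prescriptions, subjects = subjects,
         assignments = bind_rows(assign))
  })
}

#' Generate a taxon count matrix from exposures and planted effects
#'
#' @param truth Configuration from [sim_truth()].
#' @param exposures Exposure tibble from [classify_exposure()] at the
#'   relevant time point, covering the edge drug codes.
#' @param subjects Subject tibble from [generate_prescriptions()].
#' @param seed Integer seed.
#' @return Subjects x taxa count matrix.
#' @export
generate_taxa <- function(truth, exposures, subjects, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(subjects)
    taxa <- truth$taxa_ids
    # taxon baselines and nuisance covariate loadings
    mu <- rnorm(truth$n_taxa, 0, truth$baseline_log_sd)
    B <- matrix(rnorm(3 * truth$n_taxa, 0, truth$covariate_effect_sd),
                nrow = 3)
    Z <- cbind((subjects$age - 50) / 15, subjects$gender,
               (subjects$bmi - 26.5) / 5.3)
    L <- matrix(mu, n, truth$n_taxa, byrow = TRUE) + Z %*% B +
      outer(as.numeric(subjects$disease), truth$disease_taxon_effects)

    if (nrow(truth$edges) > 0) {
      ex <- exposures
      for (e in seq_len(nrow(truth$edges))) {
        ed <- truth$edges[e, ]
        st <- filter(ex, .data$drug_code == ed$drug_code)
        st <- st[match(subjects$subject_id, st$subject_id), ]
        j <- match(ed$taxon, taxa)
        active <- !is.na(st$state) & st$state == "active"
        former <- !is.na(st$state) & st$state == "former"
        shift <- ed$beta_active * active
        if (ed$beta_carry != 0) {
          dk <- decay_factor(st$years_since_last[former], ed$tau, truth$decay)
          shift[former] <- shift[former] + ed$beta_carry * dk
        }
        if (ed$beta_add != 0) {
          shift <- shift + ed$beta_add * dplyr::coalesce(st$n_past_prescriptions, 0L)
        }
        L[, j] <- L[, j] + shift
      }
    }
    L <- L + matrix(rnorm(n * truth$n_taxa, 0, truth$noise_sd), n)

    rel <- exp(L - apply(L, 1, max))
    rel <- rel / rowSums(rel)
    counts <- t(vapply(seq_len(n), function(i) {
      rmultinom(1, truth$depth, rel[i, ])[, 1]
    }, integer(truth$n_taxa)))
    dimnames(counts) <- list(subjects$subject_id, taxa)

    # presence elimination: exposed subjects lose the taxon outright
    elim <- filter(truth$edges, .data$p_eliminate > 0)
    for (e in seq_len(nrow(elim))) {
      ed <- elim[e, ]
      st <- filter(exposures, .data$drug_code == ed$drug_code)
      exposed <- st$subject_id[st$state == "active"]
      hit <- exposed[runif(length(exposed)) < ed$p_eliminate]
      counts[hit, ed$taxon] <- 0L
    }
    counts
  })
}

#' Simulate a full cohort: registry, subjects and taxon matrices
#'
#' @param truth Configuration from [sim_truth()].
#' @param n_subjects Cohort size.
#' @param seed Top-level integer seed; all stages derive from it.
#' @return List of class `"dm_cohort"`: `prescriptions`, `subjects`,
#'   `taxa_t1` (+ `taxa_t2` when configured), `exposures_t1`
#'   (+ `exposures_t2`), `assignments`, `truth`, `seed`.
#' @export
simulate_cohort <- function(truth, n_subjects = 500, seed = 1) {
  gen <- generate_prescriptions(truth, n_subjects, seed = seed)
  drug_codes <- sort(unique(c(truth$drugs$atc5, truth$edges$drug_code)))
  # purchases between T1 and T2 are legitimately invisible at T1
  exp_t1 <- suppressWarnings(
    classify_exposure(gen$prescriptions, gen$subjects,
                      drugs = drug_codes, ref = "t1")
  )
  out <- list(
    prescriptions = gen$prescriptions,
    subjects = gen$subjects,
    exposures_t1 = exp_t1,
    taxa_t1 = generate_taxa(truth, exp_t1, gen$subjects, seed = seed + 1L),
    assignments = gen$assignments,
    truth = truth, seed = seed
  )
  if (truth$t2) {
    exp_t2 <- classify_exposure(gen$prescriptions, gen$subjects,
                                drugs = drug_codes, ref = "t2")
    out$exposures_t2 <- exp_t2
    out$taxa_t2 <- generate_taxa(truth, exp_t2, gen$subjects, seed = seed + 2L)
  }
  class(out) <- "dm_cohort"
  out
}

#' @export
print.dm_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d taxa, %d drugs, %d prescriptions%s (seed %d)\n",
    nrow(x$subjects), x$truth$n_taxa, nrow(x$truth$drugs),
    nrow(x$prescriptions), if (x$truth$t2) ", two time points" else "", x$seed
  ))
  invisible(x)
}

#' Serialize a truth configuration to JSON
#'
#' @param truth A `"dm_truth"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Score pipeline outputs against the planted truth
#'
#' @param truth A `"dm_truth"` with planted edges.
#' @param q1_records Q1 association records with `fdr_q` (and `effect`).
#' @param fits Optional [additive_scan()] result for best-model scoring.
#' @param statuses Optional [deconfound()] result.
#' @param fdr_threshold Detection cut.
#' @return List: `edges` (per planted edge: detected, sign agreement,
#'   best-model match), `null_fdp` (false-discovery proportion among
#'   unplanted drug-taxon pairs), `detection_rate`, `sign_concordance`.
#' @export
score_recovery <- function(truth, q1_records, fits = NULL, statuses = NULL,
                           fdr_threshold = 0.1) {
  need <- c("drug_code", "taxon_id", "effect", "p_value", "fdr_q")
  missing_cols <- setdiff(need, names(q1_records))
  if (length(missing_cols) > 0) {
    abort(paste0("Pipeline output lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  planted <- truth$edges |>
    mutate(
      planted_sign = sign(.data$beta_active + .data$beta_carry + .data$beta_add),
      mechanism = dplyr::case_when(
        .data$beta_add != 0 ~ "M3",
        .data$beta_carry != 0 ~ "M2",
        TRUE ~ "M1"
      )
    ) |>
    rename(taxon_id = "taxon")

  edges <- planted |>
    left_join(q1_records, by = c("drug_code", "taxon_id")) |>
    mutate(
      detected = !is.na(.data$fdr_q) & .data$fdr_q <= fdr_threshold,
      sign_match = .data$detected & sign(.data$effect) == .data$planted_sign
    )
  if (!is.null(fits) && nrow(fits) > 0) {
    edges <- edges |>
      left_join(select(fits, "drug_code", "taxon_id", "best_model"),
                by = c("drug_code", "taxon_id")) |>
      mutate(model_match = .data$best_model == .data$mechanism)
  }
  if (!is.null(statuses) && nrow(statuses) > 0) {
    edges <- left_join(edges,
                       select(statuses, "drug_code", "taxon_id", "status"),
                       by = c("drug_code", "taxon_id"))
  }

  null_rec <- anti_join(q1_records, planted, by = c("drug_code", "taxon_id"))
  null_disc <- sum(null_rec$fdr_q <= fdr_threshold, na.rm = TRUE)
  all_disc <- sum(q1_records$fdr_q <= fdr_threshold, na.rm = TRUE)

  list(
    edges = edges,
    detection_rate = mean(edges$detected),
    sign_concordance = if (any(edges$detected))
      mean(edges$sign_match[edges$detected]) else NA_real_,
    null_fdp = if (all_disc > 0) null_disc / all_disc else 0
  )
}
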