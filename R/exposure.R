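#' Classify per-subject drug exposure at a reference date
#'
#' Turns raw dispensing records into one exposure state per subject x drug:
#' `active` (a purchase inside the activity window before the reference
#' date), `former` (a purchase inside the lookback but none inside the
#' activity window; `years_since_last` records the gap) or `never` (no
#' purchase inside the lookback). Antimicrobials use a 90-day activity
#' window; for human-targeted drugs the window is configurable (default also
#' 90 days). `n_past_prescriptions` counts lookback purchases with the
#' active-defining ones (those inside the activity window) excluded, so for
#' a `former` subject it is the full lookback count and for `never` it is 0.
#'
#' Purchases dated on the reference date itself count as before sampling
#' (dispensing precedes stool collection); purchases dated after the
#' reference date are dropped with a warning reporting how many. Duplicate
#' records (same subject, code, date) each count toward the prescription
#' count: same-day refills are distinct purchases.
#'
#' @param prescriptions Tibble from [read_prescriptions()].
#' @param subjects Tibble from [read_subjects()].
#' @param level ATC level (3, 4 or 5) at which codes are rolled up when
#'   `drugs` is not given.
#' @param drugs Optional character vector of drug codes (any mix of levels);
#'   membership is by code-prefix match. Default: every code observed in the
#'   registry, rolled up to `level`.
#' @param ref Which sampling date anchors the windows: `"t1"` or `"t2"`.
#'   Subjects without a `t2_date` are dropped when `ref = "t2"`.
#' @param lookback_years Length of the lookback window (years of 365.25
#'   days).
#' @param active_window_days Activity window for human-targeted drugs, days.
#' @param antimicrobial_window_days Activity window for antimicrobials, days.
#' @param antimicrobial Predicate mapping drug codes to TRUE when the
#'   antimicrobial window applies.
#' @return A tibble with columns `subject_id`, `drug_code`, `state`
#'   (factor: never < former < active), `years_since_last`,
#'   `n_past_prescriptions`, `n_active_defining`, `ref_date`; one row per
#'   subject x drug, including explicit `never` rows.
#' @export
classify_exposure <- function(prescriptions, subjects,
                              level = 4,
                              drugs = NULL,
                              ref = c("t1", "t2"),
                              lookback_years = 5,
                              active_window_days = 90,
                              antimicrobial_window_days = 90,
                              antimicrobial = is_antimicrobial) {
  ref <- rlang::arg_match(ref)
  subs <- subjects
  if (ref == "t2") {
    if (!"t2_date" %in% names(subs)) abort("`ref = \"t2\"` needs a t2_date column.")
    subs <- filter(subs, !is.na(.data$t2_date))
  }
  subs <- mutate(subs, ref_date = if (ref == "t1") .data$t1_date else .data$t2_date)

  if (is.null(drugs)) {
    drugs <- sort(unique(atc_rollup(prescriptions$atc5, level)))
  }
  validate_atc5(prescriptions$atc5)

  px <- inner_join(prescriptions, select(subs, "subject_id", "ref_date"),
                   by = "subject_id")
  n_future <- sum(px$date > px$ref_date)
  if (n_future > 0) {
    warn(sprintf("Ignoring %d prescription(s) dated after the reference date.", n_future))
    px <- filter(px, .data$date <= .data$ref_date)
  }
  px <- filter(px, .data$date > .data$ref_date - lookback_years * DAYS_PER_YEAR)

  per_drug <- purrr::map(drugs, function(d) {
    window <- if (isTRUE(antimicrobial(d)[1])) antimicrobial_window_days else active_window_days
    hits <- filter(px, stringr::str_starts(.data$atc5, d))
    if (nrow(hits) == 0) {
      return(tibble(subject_id = character(), drug_code = character(),
                    n_total = integer(), n_active_defining = integer(),
                    last_date = as.Date(character())))
    }
    hits |>
      group_by(.data$subject_id) |>
      summarise(
        n_total = dplyr::n(),
        n_active_defining = sum(.data$date > .data$ref_date - window),
        last_date = max(.data$date),
        ref_date = .data$ref_date[1],
        .groups = "drop"
      ) |>
      mutate(drug_code = d)
  })

  grid <- tidyr::expand_grid(
    subject_id = subs$subject_id,
    drug_code = drugs
  )
  out <- grid |>
    left_join(select(subs, "subject_id", "ref_date"), by = "subject_id") |>
    left_join(
      bind_rows(per_drug) |> select(-"ref_date"),
      by = c("subject_id", "drug_code")
    ) |>
    mutate(
      n_total = tidyr::replace_na(.data$n_total, 0L),
      n_active_defining = tidyr::replace_na(.data$n_active_defining, 0L),
      state = dplyr::case_when(
        .data$n_active_defining > 0 ~ "active",
        .data$n_total > 0 ~ "former",
        TRUE ~ "never"
      ),
      state = factor(.data$state, levels = c("never", "former", "active"), ordered = TRUE),
      years_since_last = if_else(
        .data$state == "former",
        as.numeric(.data$ref_date - .data$last_date) / DAYS_PER_YEAR,
        NA_real_
      ),
      n_past_prescriptions = .data$n_total - .data$n_active_defining
    ) |>
    select("subject_id", "drug_code", "state", "years_since_last",
           "n_past_prescriptions", "n_active_defining", "ref_date") |>
    arrange(.data$drug_code, .data$subject_id)
  out
}

#' Drugs with enough active users for analysis
#'
#' Keeps drugs whose count of distinct active users at the reference time
#' point reaches the threshold (default 20 active users).
#'
#' @param exposures Tibble from [classify_exposure()].
#' @param min_active_users Minimum number of distinct active users.
#' @return Tibble with `drug_code`, `n_active`, sorted by decreasing
#'   `n_active`; only retained drugs.
#' @export
select_drugs <- function(exposures, min_active_users = 20) {
  exposures |>
    filter(.data$state == "active") |>
    distinct(.data$drug_code, .data$subject_id) |>
    count(.data$drug_code, name = "n_active") |>
    filter(.data$n_active >= min_active_users) |>
    arrange(dplyr::desc(.data$n_active), .data$drug_code)
}

#' Subjects with recent antibiotic use
#'
#' Used to exclude antibiotic-perturbed microbiomes from case and control
#' arms when testing human-targeted drugs.
#'
#' @param prescriptions Prescription registry tibble.
#' @param subjects Subject tibble.
#' @param days Window before the reference date, days.
#' @param pattern Regular expression defining antibiotic codes (default
#'   ATC J01, antibacterials for systemic use).
#' @param ref `"t1"` or `"t2"`.
#' @return Character vector of subject ids.
#' @export
recent_antibiotic_users <- function(prescriptions, subjects, days = 90,
                                    pattern = "^J01", ref = c("t1", "t2")) {
  ref <- rlang::arg_match(ref)
  subs <- mutate(subjects,
                 ref_date = if (ref == "t1") .data$t1_date else .data$t2_date)
  prescriptions |>
    filter(stringr::str_detect(.data$atc5, pattern)) |>
    inner_join(select(subs, "subject_id", "ref_date"), by = "subject_id") |>
    filter(.data$date <= .data$ref_date, .data$date > .data$ref_date - days) |>
    pull(.data$subject_id) |>
    unique()
}

#' Assemble case/control groups for the study questions
#'
#' Builds, per drug, the case and control subject sets for:
#' * `Q1` (active usage): cases active at T1, controls with no use in the
#'   5-year lookback; for human-targeted drugs, subjects with antibiotic use
#'   within 90 days of T1 are excluded from both arms.
#' * `Q2` (carryover): cases are former users whose last use lies more than
#'   `window_years` before T1 (strict inequality), controls as in Q1.
#' * `Q4` (two-timepoint): `initiation` — no use in the 5 years before T1,
#'   first use between T1 and T2, active at T2; `carryover` — initiated
#'   between the time points but last used more than 1 year before T2;
#'   `discontinuation` — active at T1 with no use between T1 and T2.
#'   Controls for all Q4 variants are drug-naive across the whole recorded
#'   span. Q4 requires the raw registry and a subject table with `t2_date`.
#'
#' Drugs with an empty case or control arm, or with fewer than `min_cases`
#' cases, are skipped with a message rather than an error.
#'
#' @param exposures T1 exposure tibble from [classify_exposure()].
#' @param question `"Q1"`, `"Q2"` or `"Q4"`.
#' @param window_years Carryover window for Q2 (cases have
#'   `years_since_last > window_years`).
#' @param q4 Q4 variant: `"initiation"`, `"carryover"` or
#'   `"discontinuation"`.
#' @param prescriptions,subjects Needed for Q4 and for the Q1/Q2 antibiotic
#'   exclusion (when `exclude_subjects` is not supplied directly).
#' @param exclude_subjects Optional character vector of subject ids excluded
#'   from both arms of human-targeted drugs (recent antibiotic users).
#' @param antimicrobial Predicate identifying antimicrobial drug codes.
#' @param min_cases Minimum case-arm size (default 1 for Q1/Q2; 10 for Q4
#'   unless overridden).
#' @param lookback_years,active_window_days,antimicrobial_window_days Window
#'   parameters forwarded to [classify_exposure()] for the T2 state in Q4.
#' @return Tibble with columns `drug_code`, `subject_id`, `role`
#'   (`"case"`/`"control"`) and `question`.
#' @export
build_q_groups <- function(exposures,
                           question = c("Q1", "Q2", "Q4"),
                           window_years = NULL,
                           q4 = c("initiation", "carryover", "discontinuation"),
                           prescriptions = NULL,
                           subjects = NULL,
                           exclude_subjects = NULL,
                           antimicrobial = is_antimicrobial,
                           min_cases = NULL,
                           lookback_years = 5,
                           active_window_days = 90,
                           antimicrobial_window_days = 90) {
  question <- rlang::arg_match(question)
  if (question == "Q2" && is.null(window_years)) {
    abort("Q2 needs `window_years`.")
  }
  if (question == "Q4") {
    q4 <- rlang::arg_match(q4)
    min_cases <- min_cases %||% 10L
    return(q4_groups(exposures, q4, prescriptions, subjects,
                     antimicrobial = antimicrobial, min_cases = min_cases,
                     lookback_years = lookback_years,
                     active_window_days = active_window_days,
                     antimicrobial_window_days = antimicrobial_window_days))
  }
  min_cases <- min_cases %||% 1L

  if (is.null(exclude_subjects) && !is.null(prescriptions) && !is.null(subjects)) {
    exclude_subjects <- recent_antibiotic_users(prescriptions, subjects)
  }
  exclude_subjects <- exclude_subjects %||% character()

  tag <- if (question == "Q1") "Q1" else sprintf("Q2>%gy", window_years)
  is_case <- if (question == "Q1") {
    exposures$state == "active"
  } else {
    exposures$state == "former" &
      !is.na(exposures$years_since_last) &
      exposures$years_since_last > window_years
  }
  groups <- exposures |>
    mutate(role = dplyr::case_when(
      is_case ~ "case",
      .data$state == "never" ~ "control",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$role)) |>
    # the antibiotic exclusion protects human-targeted comparisons only
    filter(antimicrobial(.data$drug_code) |
             !(.data$subject_id %in% exclude_subjects)) |>
    select("drug_code", "subject_id", "role") |>
    mutate(question = tag)
  drop_empty_arms(groups, min_cases)
}

q4_groups <- function(exposures, q4, prescriptions, subjects,
                      antimicrobial, min_cases,
                      lookback_years, active_window_days,
                      antimicrobial_window_days) {
  if (is.null(prescriptions) || is.null(subjects)) {
    abort("Q4 group construction needs `prescriptions` and `subjects`.")
  }
  if (!"t2_date" %in% names(subjects)) abort("Q4 needs subjects with t2_date.")
  subs <- filter(subjects, !is.na(.data$t2_date))
  drugs <- unique(exposures$drug_code)

  # purchase summaries per subject x drug over the full recorded span
  spans <- purrr::map(drugs, function(d) {
    prescriptions |>
      filter(stringr::str_starts(.data$atc5, d)) |>
      inner_join(select(subs, "subject_id", "t1_date", "t2_date"),
                 by = "subject_id") |>
      group_by(.data$subject_id) |>
      summarise(
        any_ever = dplyr::n() > 0,
        any_between = any(.data$date > .data$t1_date & .data$date <= .data$t2_date),
        .groups = "drop"
      ) |>
      mutate(drug_code = d)
  }) |>
    bind_rows()

  exp_t2 <- classify_exposure(prescriptions, subs, drugs = drugs, ref = "t2",
                              lookback_years = lookback_years,
                              active_window_days = active_window_days,
                              antimicrobial_window_days = antimicrobial_window_days,
                              antimicrobial = antimicrobial)

  tab <- tidyr::expand_grid(subject_id = subs$subject_id, drug_code = drugs) |>
    left_join(spans, by = c("subject_id", "drug_code")) |>
    mutate(
      any_ever = tidyr::replace_na(.data$any_ever, FALSE),
      any_between = tidyr::replace_na(.data$any_between, FALSE)
    ) |>
    left_join(
      exposures |>
        select("subject_id", "drug_code", state_t1 = "state"),
      by = c("subject_id", "drug_code")
    ) |>
    left_join(
      exp_t2 |>
        select("subject_id", "drug_code", state_t2 = "state",
               ysl_t2 = "years_since_last"),
      by = c("subject_id", "drug_code")
    ) |>
    filter(!is.na(.data$state_t1), !is.na(.data$state_t2))

  tab <- mutate(tab, role = dplyr::case_when(
    q4 == "initiation" & .data$state_t1 == "never" & .data$any_between &
      .data$state_t2 == "active" ~ "case",
    q4 == "carryover" & .data$state_t1 == "never" & .data$any_between &
      .data$state_t2 == "former" & .data$ysl_t2 > 1 ~ "case",
    q4 == "discontinuation" & .data$state_t1 == "active" &
      !.data$any_between ~ "case",
    !.data$any_ever ~ "control",
    TRUE ~ NA_character_
  ))

  groups <- tab |>
    filter(!is.na(.data$role)) |>
    select("drug_code", "subject_id", "role") |>
    mutate(question = paste0("Q4-", q4))
  drop_empty_arms(groups, min_cases)
}

drop_empty_arms <- function(groups, min_cases) {
  keep <- groups |>
    group_by(.data$drug_code) |>
    summarise(
      n_case = sum(.data$role == "case"),
      n_control = sum(.data$role == "control"),
      .groups = "drop"
    ) |>
    filter(.data$n_case >= min_cases, .data$n_control >= 1)
  dropped <- setdiff(unique(groups$drug_code), keep$drug_code)
  if (length(dropped) > 0) {
    inform(sprintf("Skipping %d drug(s) with an undersized case or control arm: %s",
                   length(dropped), paste(head(dropped, 8), collapse = ", ")))
  }
  semi_join(groups, keep, by = "drug_code")
}
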