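test_that("generation is reproducible from one seed and seeds differ", {
  tr <- sim_truth(n_taxa = 10)
  a <- simulate_cohort(tr, n_subjects = 80, seed = 80)
  b <- simulate_cohort(tr, n_subjects = 80, seed = 80)
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$taxa_t1, b$taxa_t1)
  c2 <- simulate_cohort(tr, n_subjects = 80, seed = 81)
  expect_false(identical(a$taxa_t1, c2$taxa_t1))
})

test_that("zero prevalence yields an empty registry; invalid configs fail", {
  tr <- sim_truth(drugs = tibble::tibble(atc5 = "N05BA01", regime = "prn",
                                         prevalence = 0),
                  n_taxa = 5)
  gen <- generate_prescriptions(tr, n_subjects = 50, seed = 82)
  expect_equal(nrow(gen$prescriptions), 0L)

  expect_error(
    sim_truth(drugs = tibble::tibble(atc5 = "N05BA01", regime = "prn",
                                     prevalence = 0),
              edges = tibble::tibble(drug_code = "N05BA01", taxon = 1,
                                     beta_active = 1),
              n_taxa = 5),
    "prevalence 0"
  )
  expect_error(sim_truth(drugs = tibble::tibble(atc5 = "N05BA01",
                                                regime = "prn",
                                                prevalence = 1.2)),
               "prevalence")
  expect_error(sim_truth(n_taxa = 5,
                         edges = tibble::tibble(drug_code = "J01FA09",
                                                taxon = 1, tau = -1)),
               "tau")
  expect_error(sim_truth(n_taxa = 5,
                         edges = tibble::tibble(drug_code = "J01FA09",
                                                taxon = 99)),
               "taxon")
})

test_that("continuous-regime ongoing users refill on schedule", {
  tr <- sim_truth(
    drugs = tibble::tibble(atc5 = "A02BC01", regime = "continuous",
                           prevalence = 0.6),
    n_taxa = 5, archetype_weights = c(ongoing = 1), refill_days = 30
  )
  gen <- generate_prescriptions(tr, n_subjects = 60, seed = 83)
  per_user <- dplyr::count(gen$prescriptions, subject_id)
  spans <- gen$prescriptions |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(span = as.numeric(max(date) - min(date)), n = dplyr::n())
  # monthly refills: count tracks span/30, up to ~55 purchases over 4.5 years
  expect_true(all(abs(spans$n - (spans$span / 30 + 1)) <= 1))
  expect_true(all(per_user$n >= 12 & per_user$n <= 56))
})

test_that("exposure states recomputed from the registry match the archetypes", {
  tr <- sim_truth(n_taxa = 5, t2 = TRUE)
  co <- simulate_cohort(tr, n_subjects = 250, seed = 84)
  chk <- co$assignments |>
    dplyr::left_join(co$exposures_t1, by = c("subject_id", "drug_code")) |>
    dplyr::left_join(co$exposures_t2, by = c("subject_id", "drug_code"),
                     suffix = c("_t1", "_t2"))
  ongoing <- dplyr::filter(chk, archetype == "ongoing")
  expect_true(all(ongoing$state_t1 == "active"))
  expect_true(all(ongoing$state_t2 == "active"))
  past <- dplyr::filter(chk, archetype == "past_only")
  expect_true(all(past$state_t1 == "former"))
  expect_true(all(past$years_since_last_t1 > 90 / 365.25))
  init <- dplyr::filter(chk, archetype == "initiator")
  expect_true(all(init$state_t1 == "never"))
  expect_true(all(init$state_t2 == "active"))
  ic <- dplyr::filter(chk, archetype == "initiator_carryover")
  expect_true(all(ic$state_t1 == "never"))
  expect_true(all(ic$state_t2 == "former"))
  expect_true(all(ic$years_since_last_t2 > 1))
  disc <- dplyr::filter(chk, archetype == "discontinuer")
  expect_true(all(disc$state_t1 == "active"))
  expect_true(all(disc$state_t2 != "active"))
})

test_that("carryover decay forms scale the planted effect as configured", {
  expect_equal(drugmem:::decay_factor(10, 10, "exponential"), 0.5)
  expect_equal(drugmem:::decay_factor(0, 3, "exponential"), 1)
  expect_equal(drugmem:::decay_factor(c(2, 4), 3, "step"), c(1, 0))
  expect_equal(drugmem:::decay_factor(c(1, 5), 4, "linear"), c(0.75, 0))
})

test_that("planted active shifts are recovered on the CLR scale", {
  tr <- sim_truth(
    n_taxa = 50,
    drugs = tibble::tibble(atc5 = "N05BA01", regime = "prn", prevalence = 0.3),
    edges = tibble::tibble(drug_code = "N05BA01", taxon = 1, beta_active = 1)
  )
  co <- simulate_cohort(tr, n_subjects = 3000, seed = 85)
  clr <- clr_transform(co$taxa_t1)
  ex <- co$exposures_t1
  active <- ex$subject_id[ex$state == "active"]
  never <- ex$subject_id[ex$state == "never"]
  diff <- mean(clr[active, "tx001"]) - mean(clr[never, "tx001"])
  expect_equal(diff, 1, tolerance = 0.15)
})

test_that("truth serialization and recovery scoring round-trip", {
  edges <- tibble::tibble(drug_code = "J01FA09", taxon = 1:3,
                          beta_active = c(1, -1, 0), beta_carry = c(0, 0, 0.5),
                          tau = 5)
  tr <- sim_truth(n_taxa = 5, edges = edges)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(tr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_taxa, 5)
  expect_equal(nrow(back$edges), 3)
  expect_equal(back$edges$beta_active, c(1, -1, 0))

  # perfect-knowledge synthetic pipeline output: full recovery
  rec <- tibble::tibble(
    drug_code = "J01FA09", taxon_id = sprintf("tx%03d", 1:5),
    response_kind = "abundance", question = "Q1",
    effect = c(0.5, -0.5, 0.3, 0.01, -0.01),
    p_value = c(1e-6, 1e-6, 1e-6, 0.9, 0.8),
    fdr_q = c(1e-5, 1e-5, 1e-5, 0.9, 0.9)
  )
  sc <- score_recovery(tr, rec)
  expect_equal(sc$detection_rate, 1)
  expect_equal(sc$sign_concordance, 1)
  expect_equal(sc$null_fdp, 0)

  expect_error(score_recovery(tr, dplyr::select(rec, -fdr_q)), "fdr_q")
})

test_that("presence elimination knocks exposed subjects' taxa to zero", {
  tr <- sim_truth(
    n_taxa = 8,
    drugs = tibble::tibble(atc5 = "J01FA09", regime = "prn", prevalence = 0.5),
    edges = tibble::tibble(drug_code = "J01FA09", taxon = 1, p_eliminate = 1),
    baseline_log_sd = 0.2
  )
  co <- simulate_cohort(tr, n_subjects = 200, seed = 86)
  ex <- co$exposures_t1
  active <- ex$subject_id[ex$state == "active"]
  never <- ex$subject_id[ex$state == "never"]
  expect_true(all(co$taxa_t1[active, "tx001"] == 0))
  expect_gt(mean(co$taxa_t1[never, "tx001"] > 0), 0.9)
})
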