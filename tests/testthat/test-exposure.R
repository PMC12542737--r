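test_that("exposure states follow the activity and lookback windows", {
  subs <- tiny_subjects(4)
  px <- dplyr::bind_rows(
    rx("S1", "J01FA09", 30),                 # antibiotic inside 90-day window
    rx("S2", "J01FA09", years_days(3.6)),    # single old purchase
    rx("S3", "J01FA09", years_days(6))       # outside the 5-year lookback
  )
  ex <- classify_exposure(px, subs, drugs = "J01FA09")

  s1 <- dplyr::filter(ex, subject_id == "S1")
  expect_equal(as.character(s1$state), "active")
  expect_true(is.na(s1$years_since_last))

  s2 <- dplyr::filter(ex, subject_id == "S2")
  expect_equal(as.character(s2$state), "former")
  expect_equal(s2$years_since_last, 3.6, tolerance = 0.01)
  expect_equal(s2$n_past_prescriptions, 1L)

  # old purchase invisible; no purchases at all
  for (id in c("S3", "S4")) {
    row <- dplyr::filter(ex, subject_id == id)
    expect_equal(as.character(row$state), "never")
    expect_equal(row$n_past_prescriptions, 0L)
    expect_true(is.na(row$years_since_last))
  }
})

test_that("active-defining prescriptions are excluded from the past count", {
  subs <- tiny_subjects(1)
  px <- dplyr::bind_rows(
    rx("S1", "J01FA09", c(10, 40, 200, 700)),
    rx("S1", "J01FA09", 700)  # same-day duplicate: counts once more
  )
  ex <- classify_exposure(px, subs, drugs = "J01FA09")
  expect_equal(as.character(ex$state), "active")
  expect_equal(ex$n_active_defining, 2L)   # purchases at 10 and 40 days
  expect_equal(ex$n_past_prescriptions, 3L) # 200 + 700 + duplicate 700
  # count conservation
  expect_equal(ex$n_past_prescriptions + ex$n_active_defining, 5L)
})

test_that("purchases on the sampling date count; later ones warn and drop", {
  subs <- tiny_subjects(1)
  px <- dplyr::bind_rows(rx("S1", "N05BA12", 0), rx("S1", "N05BA12", -30))
  expect_warning(
    ex <- classify_exposure(px, subs, drugs = "N05BA12"),
    "1 prescription"
  )
  expect_equal(as.character(ex$state), "active")
  expect_equal(ex$n_active_defining, 1L)
})

test_that("human-targeted activity window is configurable", {
  subs <- tiny_subjects(1)
  px <- rx("S1", "N05BA12", 120)
  ex90 <- classify_exposure(px, subs, drugs = "N05BA12")
  ex180 <- classify_exposure(px, subs, drugs = "N05BA12",
                             active_window_days = 180)
  expect_equal(as.character(ex90$state), "former")
  expect_equal(as.character(ex180$state), "active")
  # the antimicrobial window is independent of the human-targeted one
  exab <- classify_exposure(rx("S1", "J01FA09", 120), subs,
                            drugs = "J01FA09", active_window_days = 180)
  expect_equal(as.character(exab$state), "former")
})

test_that("drug selection thresholds on distinct active users and rolls up", {
  subs <- tiny_subjects(44)
  # drug A: 25 active users, drug B: 19
  px <- dplyr::bind_rows(
    rx(paste0("S", 1:25), "C07AB02", 10),
    rx(paste0("S", 20:38), "C09AA02", 10)
  )
  ex <- classify_exposure(px, subs, level = 5)
  kept <- select_drugs(ex, min_active_users = 20)
  expect_equal(kept$drug_code, "C07AB02")
  expect_equal(kept$n_active, 25L)
  expect_equal(nrow(select_drugs(ex, min_active_users = 1)), 2L)

  # two ATC5 siblings with 12 users each: parent retained at ATC4 only
  px2 <- dplyr::bind_rows(
    rx(paste0("S", 1:12), "N05BA01", 10),
    rx(paste0("S", 13:24), "N05BA12", 10)
  )
  ex5 <- classify_exposure(px2, subs, level = 5)
  ex4 <- classify_exposure(px2, subs, level = 4)
  expect_equal(nrow(select_drugs(ex5, 20)), 0L)
  expect_equal(select_drugs(ex4, 20)$drug_code, "N05BA")
  expect_equal(select_drugs(ex4, 20)$n_active, 24L)
})

test_that("Q1/Q2 groups partition correctly and exclude recent antibiotic users", {
  subs <- tiny_subjects(6)
  px <- dplyr::bind_rows(
    rx("S1", "N05BA12", 10),               # active human-targeted
    rx("S2", "N05BA12", years_days(2.5)),  # former
    rx("S3", "N05BA12", years_days(1.2)),  # former, recent-ish
    rx("S4", "J01FA09", 20)                # recent antibiotic user, no N05BA
  )
  ex <- classify_exposure(px, subs, drugs = c("N05BA12", "J01FA09"))
  q1 <- build_q_groups(ex, "Q1", prescriptions = px, subjects = subs)
  n05 <- dplyr::filter(q1, drug_code == "N05BA12")
  expect_setequal(n05$subject_id[n05$role == "case"], "S1")
  # S4 is excluded from the human-targeted control arm; S5, S6 remain
  expect_setequal(n05$subject_id[n05$role == "control"], c("S5", "S6"))
  expect_length(intersect(n05$subject_id[n05$role == "case"],
                          n05$subject_id[n05$role == "control"]), 0)

  # window monotonicity: cases for >2y are a subset of cases for >1y
  q2_1 <- build_q_groups(ex, "Q2", window_years = 1, exclude_subjects = "S4")
  q2_2 <- build_q_groups(ex, "Q2", window_years = 2, exclude_subjects = "S4")
  c1 <- dplyr::filter(q2_1, drug_code == "N05BA12", role == "case")$subject_id
  c2 <- dplyr::filter(q2_2, drug_code == "N05BA12", role == "case")$subject_id
  expect_setequal(c1, c("S2", "S3"))
  expect_setequal(c2, "S2")
  expect_true(all(c2 %in% c1))

  # a subject with zero prescriptions is a control everywhere
  expect_true(all(c("S5", "S6") %in% n05$subject_id[n05$role == "control"]))
})

test_that("Q4 interval logic classifies initiators, carryover and discontinuers", {
  subs <- tiny_subjects(6, t2 = TRUE)   # t1 2020-01-01, t2 2024-06-01
  t1 <- as.Date("2020-01-01")
  px <- dplyr::bind_rows(
    # S1: first purchase 2y after T1, last 14 months before T2 -> Q4-carryover
    tibble::tibble(subject_id = "S1", atc5 = "A02BC01",
                   date = c(t1 + years_days(2), as.Date("2024-06-01") - years_days(14 / 12))),
    # S2: initiates 3y after T1 and keeps purchasing until T2 -> initiation
    tibble::tibble(subject_id = "S2", atc5 = "A02BC01",
                   date = c(t1 + years_days(3), as.Date("2024-06-01") - 30)),
    # S3: active at T1, nothing afterwards -> discontinuation
    tibble::tibble(subject_id = "S3", atc5 = "A02BC01", date = t1 - 30),
    # S4: drug-naive for A02BC01 but uses something else
    tibble::tibble(subject_id = "S4", atc5 = "N05BA12", date = t1 - 10)
  )
  ex <- suppressWarnings(classify_exposure(px, subs, drugs = "A02BC01"))
  args <- list(exposures = ex, question = "Q4", prescriptions = px,
               subjects = subs, min_cases = 1)
  init <- do.call(build_q_groups, c(args, q4 = "initiation"))
  carry <- do.call(build_q_groups, c(args, q4 = "carryover"))
  disc <- do.call(build_q_groups, c(args, q4 = "discontinuation"))
  expect_equal(init$subject_id[init$role == "case"], "S2")
  expect_equal(carry$subject_id[carry$role == "case"], "S1")
  expect_equal(disc$subject_id[disc$role == "case"], "S3")
  # drug-naive controls include users of unrelated drugs
  expect_true(all(c("S4", "S5", "S6") %in%
                    init$subject_id[init$role == "control"]))
})

test_that("drugs with an empty arm are skipped with a message, not an error", {
  subs <- tiny_subjects(3)
  px <- rx(c("S1", "S2", "S3"), "N05BA12", 10) # everyone active: no controls
  ex <- classify_exposure(px, subs, drugs = "N05BA12")
  expect_message(g <- build_q_groups(ex, "Q1", exclude_subjects = character()),
                 "undersized")
  expect_equal(nrow(g), 0L)
})

test_that("roll-up consistency: an active ATC5 child implies active ancestors", {
  tr <- sim_truth(n_taxa = 5)
  co <- simulate_cohort(tr, n_subjects = 150, seed = 3)
  ex5 <- classify_exposure(co$prescriptions, co$subjects, level = 5)
  ex4 <- classify_exposure(co$prescriptions, co$subjects, level = 4)
  ex3 <- classify_exposure(co$prescriptions, co$subjects, level = 3)
  act5 <- dplyr::filter(ex5, state == "active")
  for (lvl in list(list(ex = ex4, w = 5), list(ex = ex3, w = 4))) {
    up <- dplyr::mutate(act5, drug_code = substr(drug_code, 1, lvl$w)) |>
      dplyr::distinct(subject_id, drug_code) |>
      dplyr::left_join(lvl$ex, by = c("subject_id", "drug_code"))
    expect_true(all(up$state == "active"))
  }
  # count conservation across the whole synthetic registry
  expect_true(all(ex5$n_past_prescriptions + ex5$n_active_defining >=
                    ex5$n_past_prescriptions))
  act <- dplyr::filter(ex5, state == "active")
  tot <- co$prescriptions |>
    dplyr::inner_join(dplyr::select(co$subjects, subject_id, t1_date),
                      by = "subject_id") |>
    dplyr::filter(date <= t1_date, date > t1_date - 5 * 365.25) |>
    dplyr::count(subject_id, atc5)
  joined <- dplyr::inner_join(act, tot,
                              by = c("subject_id", drug_code = "atc5"))
  expect_equal(joined$n_past_prescriptions + joined$n_active_defining,
               joined$n)
})
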