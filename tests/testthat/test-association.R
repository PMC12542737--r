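test_that("partial r matches the residual correlation and the t transform", {
  d <- model_fixture(80, seed = 2)
  withr::with_seed(3, {
    d$g <- rbinom(80, 1, 0.4)
    d$y <- 0.1 * d$age + 0.5 * d$g + rnorm(80)
  })
  got <- fit_abundance_model(d, "y", "g")

  # oracle 1: correlation of the two residual vectors
  ry <- resid(lm(y ~ age + gender + bmi, data = d))
  rg <- resid(lm(g ~ age + gender + bmi, data = d))
  expect_equal(got$effect, cor(ry, rg), tolerance = 1e-12)

  # oracle 2: sign-consistent transform of the OLS t statistic
  fit <- lm(y ~ age + gender + bmi + g, data = d)
  tg <- summary(fit)$coefficients["g", "t value"]
  df <- fit$df.residual
  expect_equal(got$effect, tg / sqrt(tg^2 + df), tolerance = 1e-12)
  expect_equal(got$p_value, summary(fit)$coefficients["g", "Pr(>|t|)"],
               tolerance = 1e-12)
})

test_that("OLS on a 12-row fixture matches an independent normal-equations solve", {
  d <- model_fixture(12, seed = 5)
  withr::with_seed(6, {
    d$g <- rep(c(0, 1), 6)
    d$y <- rnorm(12)
  })
  X <- cbind(1, d$age, d$gender, d$bmi, d$g)
  beta <- solve(t(X) %*% X, t(X) %*% d$y) # independent solve
  res <- d$y - X %*% beta
  s2 <- sum(res^2) / (12 - 5)
  se <- sqrt(s2 * solve(t(X) %*% X)[5, 5])
  tstat <- beta[5] / se
  expected_r <- tstat / sqrt(tstat^2 + 7)
  got <- fit_abundance_model(d, "y", "g")
  expect_equal(got$effect, as.numeric(expected_r), tolerance = 1e-8)
  expect_equal(got$p_value, 2 * pt(-abs(tstat), 7), tolerance = 1e-8)
})

test_that("with no covariates the partial r reduces to plain Pearson", {
  withr::with_seed(7, {
    d <- tibble::tibble(g = rbinom(40, 1, 0.5), y = rnorm(40))
  })
  got <- fit_abundance_model(d, "y", "g", covariates = character())
  expect_equal(got$effect, cor(d$y, d$g), tolerance = 1e-12)
})

test_that("rank-deficient covariates yield a flagged NA, not an error", {
  d <- model_fixture(20, seed = 8)
  d$dup <- d$age
  d$g <- rep(c(0, 1), 10)
  d$y <- rnorm(20)
  got <- fit_abundance_model(d, "y", "g", covariates = c("age", "dup"))
  expect_true(is.na(got$effect))
  expect_match(got$note, "rank")
})

test_that("presence model recovers the contingency-table log odds", {
  # cases: 30 present / 10 absent; controls: 15 present / 25 absent
  d <- tibble::tibble(
    present = c(rep(1, 30), rep(0, 10), rep(1, 15), rep(0, 25)),
    g = c(rep(1, 40), rep(0, 40))
  )
  got <- fit_presence_model(d, "present", "g", covariates = character())
  expect_equal(got$effect, log(5), tolerance = 1e-6)

  # balanced table with odds ratio 1
  d2 <- tibble::tibble(present = rep(c(1, 0), 40), g = rep(c(1, 1, 0, 0), 20))
  got2 <- fit_presence_model(d2, "present", "g", covariates = character())
  expect_equal(got2$effect, 0, tolerance = 1e-8)
})

test_that("perfect separation and constant responses are flagged, never thrown", {
  d <- tibble::tibble(present = c(rep(1, 30), rep(0, 30)),
                      g = c(rep(1, 30), rep(0, 30)))
  got <- fit_presence_model(d, "present", "g", covariates = character())
  expect_true(is.na(got$effect))
  expect_match(got$note, "separation")

  d2 <- tibble::tibble(present = rep(1, 20), g = rep(c(0, 1), 10))
  got2 <- fit_presence_model(d2, "present", "g", covariates = character())
  expect_true(is.na(got2$effect))

  # a near-saturated taxon cannot support the fit: flagged, not tested
  d3 <- tibble::tibble(present = c(rep(1, 95), rep(0, 5)),
                       g = rep(c(0, 1), 50))
  got3 <- fit_presence_model(d3, "present", "g", covariates = character())
  expect_true(is.na(got3$effect))
  expect_match(got3$note, "EPV")
})

test_that("BH q-values match the step-up procedure and preserve order", {
  expect_equal(add_fdr(tibble::tibble(p_value = 0.03), by = NULL)$fdr_q, 0.03)
  got <- add_fdr(tibble::tibble(p_value = c(0.01, 0.02, 0.03, 0.04)),
                 by = NULL)$fdr_q
  expect_equal(got, rep(0.04, 4))
  expect_equal(add_fdr(tibble::tibble(p_value = rep(1, 5)), by = NULL)$fdr_q,
               rep(1, 5))

  # invariant to input permutation; monotone in sorted order
  withr::with_seed(9, p <- runif(20))
  q <- add_fdr(tibble::tibble(p_value = p), by = NULL)$fdr_q
  perm <- sample(20)
  q2 <- add_fdr(tibble::tibble(p_value = p[perm]), by = NULL)$fdr_q
  expect_equal(q2, q[perm])
  expect_true(all(diff(q[order(p)]) >= -1e-15))

  # family-wise grouping adjusts within each drug separately
  rec <- tibble::tibble(
    drug_code = rep(c("A", "B"), each = 2),
    response_kind = "abundance", question = "Q1",
    p_value = c(0.01, 0.04, 0.5, 0.9)
  )
  byq <- add_fdr(rec)
  expect_equal(byq$fdr_q[1:2], p.adjust(c(0.01, 0.04), "BH"))
  expect_equal(byq$fdr_q[3:4], p.adjust(c(0.5, 0.9), "BH"))
})

test_that("dosage LRT behaves at its edge cases and matches the nested lm", {
  d <- model_fixture(60, seed = 10)
  withr::with_seed(11, {
    d$dose <- sample(c("low", "mid", "high"), 60, replace = TRUE)
    d$y <- rnorm(60) + (d$dose == "high")
  })
  got <- dosage_lrt(d, "y", "dose")
  f0 <- lm(y ~ age + gender + bmi, data = d)
  f1 <- lm(y ~ age + gender + bmi + factor(dose), data = d)
  expect_equal(got$statistic, as.numeric(2 * (logLik(f1) - logLik(f0))),
               tolerance = 1e-10)
  expect_equal(got$df, 2L)

  dz <- d
  dz$y <- 1
  expect_equal(dosage_lrt(dz, "y", "dose")$p_value, 1)
  d1 <- d
  d1$dose <- "low"
  expect_error(dosage_lrt(d1, "y", "dose"), "two dosage levels")
})

test_that("null dosage permutations give approximately uniform LRT p-values", {
  d <- model_fixture(80, seed = 12)
  ps <- withr::with_seed(13, vapply(seq_len(300), function(i) {
    d$dose <- sample(rep(c("a", "b"), 40))
    d$y <- rnorm(80)
    dosage_lrt(d, "y", "dose")$p_value
  }, numeric(1)))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("association pipeline returns deterministic long-format records", {
  tr <- sim_truth(
    n_taxa = 12,
    drugs = tibble::tibble(atc5 = c("J01FA09", "N05BA12"),
                           regime = "prn", prevalence = 0.4),
    edges = tibble::tibble(drug_code = "J01FA09", taxon = 1, beta_active = 1.5)
  )
  co <- simulate_cohort(tr, n_subjects = 250, seed = 14)
  g <- build_q_groups(co$exposures_t1, "Q1",
                      prescriptions = co$prescriptions,
                      subjects = co$subjects)
  clr <- clr_transform(co$taxa_t1)
  rec <- add_fdr(associate(g, clr, co$subjects))
  expect_setequal(unique(rec$drug_code), c("J01FA09", "N05BA12"))
  expect_equal(nrow(rec), 24L)
  expect_true(all(rec$p_value >= 0 & rec$p_value <= 1, na.rm = TRUE))
  expect_true(all(abs(rec$effect) <= 1, na.rm = TRUE))
  expect_true(all(rec$fdr_q >= rec$p_value - 1e-12, na.rm = TRUE))
  hit <- dplyr::filter(rec, drug_code == "J01FA09", taxon_id == "tx001")
  expect_lt(hit$fdr_q, 0.1)
  expect_gt(hit$effect, 0)
  # rows are ordered by (drug, taxon)
  expect_equal(rec, dplyr::arrange(rec, drug_code, taxon_id))

  # alpha-diversity models run through the same estimator
  al <- associate_alpha(g, alpha_diversity(co$taxa_t1), co$subjects)
  expect_setequal(unique(al$response_kind), c("richness", "shannon"))
  expect_equal(nrow(al), 4L)
})
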