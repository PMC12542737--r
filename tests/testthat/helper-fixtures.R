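# Hand-built micro-registry used across exposure tests.
# Reference date (t1) is 2020-01-01 for everyone.
tiny_subjects <- function(n = 6, t2 = FALSE) {
  s <- tibble::tibble(
    subject_id = paste0("S", seq_len(n)),
    age = seq(30, 30 + 5 * (n - 1), by = 5),
    gender = rep_len(c(0, 1), n),
    bmi = seq(22, 22 + n - 1),
    t1_date = as.Date("2020-01-01")
  )
  if (t2) s$t2_date <- as.Date("2024-06-01")
  s
}

rx <- function(subject_id, atc5, days_before_t1,
               t1 = as.Date("2020-01-01")) {
  tibble::tibble(subject_id = subject_id, atc5 = atc5,
                 date = t1 - days_before_t1)
}

years_days <- function(y) round(y * 365.25)

# every permutation of 1..n (tiny n), for exhaustive permutation oracles
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# independent single-shot pseudo-F for the enumeration oracle
permanova_f_once <- function(d, g) {
  g <- factor(g)
  n <- nrow(d)
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  X <- stats::model.matrix(~g)
  H <- X %*% solve(crossprod(X), t(X))
  ssb <- sum(diag(H %*% G))
  sst <- sum(diag(G))
  (ssb / (nlevels(g) - 1)) / ((sst - ssb) / (n - nlevels(g)))
}

# deterministic covariate table for model fixtures
model_fixture <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = paste0("S", seq_len(n)),
    age = round(runif(n, 25, 80)),
    gender = rbinom(n, 1, 0.5),
    bmi = round(runif(n, 18, 40), 1)
  ))
}
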