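#' Antibiotic-usage classifiers and their transfer to other drugs
#'
#' Elastic-net logistic models are trained on CLR-transformed microbiome
#' profiles to recognize active usage of an antibiotic subclass, then
#' evaluated for their ability to recognize usage of *other* (non-
#' antibiotic) drugs in held-out data — a transfer signal indicating that
#' the two drugs perturb overlapping parts of the community. The protocol:
#' a 75:25 label-stratified train/test split; hyperparameters (mixing
#' parameter x penalty strength, 50 combinations) tuned by fivefold
#' cross-validation repeated 4 times on the training split; transfer AUROC
#' computed on the test split with all users of the source antibiotic
#' removed; the whole procedure repeated on 5 random splits and averaged.
#'
#' @name transfer
NULL

# Mann-Whitney AUROC via pROC; NA when either class has < 2 members
auroc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) return(NA_real_)
  as.numeric(pROC::auc(response = labels, predictor = as.numeric(scores),
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

# label-stratified fold assignment (1..k), seeded by the caller
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train an elastic-net classifier for antibiotic usage
#'
#' @param clr CLR matrix (subjects x taxa), predictors.
#' @param labels Named 0/1 vector of active usage of the source antibiotic,
#'   names matching `rownames(clr)`.
#' @param seed Integer seed controlling the split, folds and fit.
#' @param train_prop Training fraction of the stratified split.
#' @param folds,cv_repeats Cross-validation geometry.
#' @param n_mixing Number of mixing-parameter (alpha) values, uniform on
#'   \[0, 1\]; each contributes a log-spaced penalty path so that
#'   `n_mixing * path_length` hyperparameter combinations are searched
#'   (defaults give 50).
#' @param path_length Penalty path length per mixing value.
#' @param min_users Minimum active users required (study rule: 50).
#' @return Class `"dm_abx_model"`: the refit glmnet model, chosen
#'   hyperparameters, train/test ids and the held-out AUROC on the source
#'   antibiotic's own labels.
#' @export
train_antibiotic_model <- function(clr, labels, seed = 1,
                                   train_prop = 0.75,
                                   folds = 5, cv_repeats = 4,
                                   n_mixing = 5, path_length = 10,
                                   min_users = 50) {
  stopifnot(!is.null(names(labels)))
  ids <- intersect(rownames(clr), names(labels))
  x <- clr[ids, , drop = FALSE]
  y <- as.integer(labels[ids] > 0)
  if (sum(y) < min_users) {
    abort(sprintf("Antibiotic class has %d active users; %d required.",
                  sum(y), min_users))
  }

  withr::with_seed(seed, {
    # stratified 75:25 split
    train_idx <- unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, round(train_prop * length(idx)))
    }))
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_along(y), train_idx)
    xt <- x[train_idx, , drop = FALSE]
    yt <- y[train_idx]

    alphas <- seq(0, 1, length.out = n_mixing)
    # one shared log-spaced penalty path per mixing value, anchored at the
    # smallest penalty that zeroes the lasso solution
    lam_max <- max(abs(crossprod(scale(xt), yt - mean(yt)))) / length(yt)
    lam_path <- exp(seq(log(lam_max * 2), log(lam_max * 1e-3),
                        length.out = path_length))

    grid_scores <- array(0, dim = c(n_mixing, path_length))
    grid_counts <- array(0, dim = c(n_mixing, path_length))
    for (rep in seq_len(cv_repeats)) {
      fold <- stratified_folds(yt, folds)
      for (f in seq_len(folds)) {
        in_tr <- fold != f
        if (length(unique(yt[!in_tr])) < 2 || length(unique(yt[in_tr])) < 2) next
        for (a in seq_along(alphas)) {
          fit <- glmnet::glmnet(xt[in_tr, , drop = FALSE], yt[in_tr],
                                family = "binomial", alpha = alphas[a],
                                lambda = lam_path)
          pr <- predict(fit, xt[!in_tr, , drop = FALSE], s = lam_path,
                        type = "response")
          for (l in seq_len(path_length)) {
            au <- auroc(pr[, l], yt[!in_tr])
            if (!is.na(au)) {
              grid_scores[a, l] <- grid_scores[a, l] + au
              grid_counts[a, l] <- grid_counts[a, l] + 1
            }
          }
        }
      }
    }
    mean_auc <- grid_scores / pmax(grid_counts, 1)
    best <- which(mean_auc == max(mean_auc), arr.ind = TRUE)
    # deterministic tie-break: strongest penalty, then smallest mixing value
    best <- best[order(-best[, 2], best[, 1]), , drop = FALSE][1, ]
    alpha_star <- alphas[best[1]]
    lambda_star <- lam_path[best[2]]

    final <- glmnet::glmnet(xt, yt, family = "binomial",
                            alpha = alpha_star, lambda = lam_path)
    test_scores <- as.numeric(predict(final, x[test_idx, , drop = FALSE],
                                      s = lambda_star, type = "response"))
    structure(
      list(fit = final, alpha = alpha_star, lambda = lambda_star,
           cv_auc = max(mean_auc),
           train_ids = ids[train_idx], test_ids = ids[test_idx],
           auroc_self = auroc(test_scores, y[test_idx]),
           seed = seed),
      class = "dm_abx_model"
    )
  })
}

#' @export
print.dm_abx_model <- function(x, ...) {
  cat(sprintf(
    "Elastic-net antibiotic-usage model: mixing = %.2f, penalty = %.4g\n  CV AUROC = %.3f, held-out AUROC (own labels) = %.3f, n_train = %d\n",
    x$alpha, x$lambda, x$cv_auc, x$auroc_self, length(x$train_ids)
  ))
  invisible(x)
}

#' Score subjects with a trained antibiotic model
#'
#' @param object A `"dm_abx_model"`.
#' @param newdata CLR matrix of subjects to score.
#' @param ... Unused.
#' @return Named numeric vector of usage probabilities.
#' @export
predict.dm_abx_model <- function(object, newdata, ...) {
  p <- as.numeric(predict(object$fit, newdata, s = object$lambda,
                          type = "response"))
  setNames(p, rownames(newdata))
}

#' Evaluate transfer of an antibiotic model to a target drug
#'
#' @param model A `"dm_abx_model"` from [train_antibiotic_model()].
#' @param clr CLR matrix covering the model's test subjects.
#' @param target_labels Named 0/1 vector of the target drug's active usage.
#' @param antibiotic_users Subject ids removed from the test set before
#'   scoring (the source antibiotic's users).
#' @return One-row tibble: `auroc`, `n_test`, `n_target_cases`.
#' @export
transfer_evaluate <- function(model, clr, target_labels, antibiotic_users) {
  ids <- setdiff(intersect(model$test_ids, names(target_labels)),
                 antibiotic_users)
  if (length(ids) < 4) {
    return(tibble(auroc = NA_real_, n_test = length(ids), n_target_cases = NA_integer_))
  }
  scores <- predict(model, clr[ids, , drop = FALSE])
  y <- as.integer(target_labels[ids] > 0)
  tibble(auroc = auroc(scores, y), n_test = length(ids),
         n_target_cases = sum(y))
}

#' Repeated-split transfer AUROC
#'
#' Full protocol: for each of `n_repeats` seeded random splits, tune and
#' train the source-antibiotic model on the training split, then compute
#' the transfer AUROC on the test split with antibiotic users excluded;
#' report the per-repeat values and their mean.
#'
#' @param clr CLR matrix.
#' @param abx_labels Named 0/1 active-usage vector for the source
#'   antibiotic.
#' @param target_labels Named 0/1 active-usage vector for the target drug.
#' @param n_repeats Number of random splits (study default 5).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param ... Passed to [train_antibiotic_model()].
#' @return Class `"dm_transfer"`: list with `auroc` (mean over repeats) and
#'   `repeats` (per-repeat tibble).
#' @export
transfer_auroc <- function(clr, abx_labels, target_labels,
                           n_repeats = 5, seed = 1, ...) {
  abx_users <- names(abx_labels)[abx_labels > 0]
  reps <- purrr::map(seq_len(n_repeats), function(r) {
    model <- train_antibiotic_model(clr, abx_labels, seed = seed + r, ...)
    transfer_evaluate(model, clr, target_labels, abx_users) |>
      mutate(repeat_id = r, auroc_self = model$auroc_self)
  }) |>
    bind_rows()
  structure(
    list(auroc = mean(reps$auroc, na.rm = TRUE), repeats = reps,
         n_repeats = n_repeats),
    class = "dm_transfer"
  )
}

#' @export
print.dm_transfer <- function(x, ...) {
  cat(sprintf("Transfer AUROC = %.3f (mean of %d repeats)\n",
              x$auroc, x$n_repeats))
  invisible(x)
}
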