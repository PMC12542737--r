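#' Compositional transforms and diversity metrics
#'
#' Shotgun-metagenomic taxon profiles are compositional: only relative
#' information is meaningful. The centered log-ratio (CLR) transform maps
#' each sample's composition into unconstrained real space by taking natural
#' logs and centering by the sample's mean log abundance; Euclidean distance
#' on CLR rows is the Aitchison distance. Zeros are imputed with a single
#' global pseudocount equal to half of the smallest non-zero relative
#' abundance in the matrix, so the imputation is deterministic across
#' subjects.
#'
#' @name composition
NULL

validate_profile <- function(profile) {
  if (!is.matrix(profile) || !is.numeric(profile)) {
    abort("Taxon profile must be a numeric matrix (subjects x taxa).")
  }
  if (any(profile < 0)) abort("Taxon profile contains negative abundances.")
  if (anyDuplicated(rownames(profile))) abort("Duplicate subject ids in profile.")
  if (anyDuplicated(colnames(profile))) abort("Duplicate taxon ids in profile.")
  invisible(profile)
}

#' Convert counts to relative abundances
#'
#' @param profile Subjects x taxa numeric matrix.
#' @return Matrix of the same shape with rows summing to 1; the zero
#'   pattern is preserved. Idempotent on already-relative data.
#' @export
to_relative <- function(profile) {
  validate_profile(profile)
  rs <- rowSums(profile)
  if (any(rs == 0)) {
    abort(paste0("All-zero subject row(s): ",
                 paste(head(rownames(profile)[rs == 0], 5), collapse = ", ")))
  }
  profile / rs
}

#' Centered log-ratio transform with global half-minimum pseudocount
#'
#' @param profile Subjects x taxa matrix of counts or relative abundances
#'   (converted internally with [to_relative()]).
#' @param pseudocount Optional; by default half the smallest non-zero
#'   relative abundance of the whole matrix.
#' @return A subjects x taxa matrix of CLR values, rows summing to 0, with
#'   attribute `"pseudocount"`.
#' @export
#' @examples
#' clr_transform(matrix(c(0.2, 0.8), 1, 2, dimnames = list("s1", c("a", "b"))))
clr_transform <- function(profile, pseudocount = NULL) {
  rel <- to_relative(profile)
  if (ncol(rel) < 2) abort("CLR is undefined for a single-taxon profile.")
  if (is.null(pseudocount)) {
    nz <- rel[rel > 0]
    pseudocount <- min(nz) / 2
  }
  rel[rel == 0] <- pseudocount
  lg <- log(rel)
  out <- lg - rowMeans(lg)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Aitchison distances between samples
#'
#' Euclidean distance on CLR-transformed rows.
#'
#' @param clr CLR matrix from [clr_transform()].
#' @return A [stats::dist] object.
#' @export
aitchison_distance <- function(clr) {
  if (any(!is.finite(clr))) abort("CLR matrix contains non-finite values.")
  dist(clr, method = "euclidean")
}

#' Alpha diversity: observed richness and Shannon index
#'
#' Richness counts strictly positive taxa; the Shannon index is
#' \eqn{-\sum_i p_i \ln p_i} over the positive relative abundances
#' (natural log, via [vegan::diversity()]).
#'
#' @param profile Subjects x taxa matrix of counts or relative abundances.
#' @return Tibble with `subject_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(profile) {
  rel <- to_relative(profile)
  tibble(
    subject_id = rownames(rel) %||% as.character(seq_len(nrow(rel))),
    richness = as.integer(rowSums(rel > 0)),
    shannon = unname(vegan::diversity(rel, index = "shannon"))
  )
}

#' Keep taxa present in at least a fraction of subjects
#'
#' @param profile Subjects x taxa matrix.
#' @param min_prevalence Minimum fraction of subjects with abundance > 0
#'   (inclusive: a taxon at exactly the threshold is kept).
#' @return The profile restricted to prevalent taxa; subjects unchanged.
#' @export
prevalence_filter <- function(profile, min_prevalence = 0.10) {
  validate_profile(profile)
  prev <- colMeans(profile > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) warn("No taxon passes the prevalence filter.")
  profile[, keep, drop = FALSE]
}
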