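#' Read a prescription registry table
#'
#' Expects delimited text (TSV or CSV, autodetected) with columns
#' `subject_id`, `atc5`, `date` and optionally `dosage_class`; dates must be
#' ISO-8601. Every code is validated against the ATC level-5 pattern.
#'
#' @param path Path to the file.
#' @return A tibble with columns `subject_id` (character), `atc5`
#'   (character), `date` (Date) and, when present, `dosage_class`.
#' @export
read_prescriptions <- function(path) {
  x <- read_delim_auto(path)
  need <- c("subject_id", "atc5", "date")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Prescription table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- mutate(x,
    subject_id = as.character(.data$subject_id),
    atc5 = as.character(.data$atc5),
    date = as.Date(.data$date)
  )
  validate_atc5(x$atc5)
  if (anyNA(x$date)) abort("Prescription table contains unparseable dates.")
  x
}

#' Read a subject table
#'
#' Columns `subject_id`, `age`, `gender`, `bmi`, `t1_date` and optionally
#' `t2_date` (ISO-8601). `gender` is a 0/1 indicator; which level is coded 1
#' is irrelevant to the adjusted models.
#'
#' @param path Path to the file.
#' @return A tibble, one row per subject.
#' @export
read_subjects <- function(path) {
  x <- read_delim_auto(path)
  need <- c("subject_id", "age", "gender", "bmi", "t1_date")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Subject table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- mutate(x,
    subject_id = as.character(.data$subject_id),
    t1_date = as.Date(.data$t1_date)
  )
  if ("t2_date" %in% names(x)) x$t2_date <- as.Date(x$t2_date)
  validate_subjects(x)
  x
}

validate_subjects <- function(x) {
  if (anyDuplicated(x$subject_id)) abort("Duplicate subject ids in subject table.")
  if (any(x$age <= 0, na.rm = TRUE)) abort("Subject ages must be positive.")
  if (any(x$bmi <= 0, na.rm = TRUE)) abort("Subject BMI values must be positive.")
  if ("t2_date" %in% names(x)) {
    bad <- !is.na(x$t2_date) & x$t2_date <= x$t1_date
    if (any(bad)) {
      abort(paste0("t2_date must be strictly after t1_date; offending subject(s): ",
                   paste(head(x$subject_id[bad], 5), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Read a taxon abundance matrix
#'
#' Delimited text with subjects in rows (first column = subject id) and taxa
#' in columns (header row of taxon ids). Values may be counts or relative
#' abundances; downstream transforms handle either.
#'
#' @param path Path to the file.
#' @return A numeric matrix, subjects x taxa, with dimnames.
#' @export
read_taxa <- function(path) {
  x <- read_delim_auto(path)
  ids <- as.character(x[[1]])
  m <- as.matrix(x[-1])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_profile(m)
  m
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Write a taxon matrix as TSV
#'
#' @param profile Subjects x taxa numeric matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_taxa <- function(profile, path) {
  out <- tibble::as_tibble(profile, rownames = "subject_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
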