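#' ATC code utilities
#'
#' The Anatomical Therapeutic Chemical (ATC) classification is hierarchical
#' and prefix-coded: level 1 is one letter (anatomical main group), level 3 a
#' 4-character pharmacological subgroup, level 4 a 5-character chemical
#' subgroup and level 5 the full 7-character chemical substance
#' (e.g. `"N05BA12"`, alprazolam, rolls up to `"N05BA"` at level 4 and
#' `"N05B"` at level 3). Because the coding is prefix-based, membership of a
#' substance in a higher-level class is a string-prefix test and no external
#' dictionary is required.
#'
#' @name atc
NULL

ATC5_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

# prefix length of an ATC code at a given level
atc_level_width <- function(level) {
  widths <- c(`1` = 1L, `2` = 3L, `3` = 4L, `4` = 5L, `5` = 7L)
  key <- as.character(level)
  if (any(!key %in% names(widths))) {
    abort("`level` must be one of 1, 2, 3, 4, 5.")
  }
  unname(widths[key])
}

#' Validate ATC level-5 codes
#'
#' @param atc5 Character vector of candidate codes.
#' @return Invisibly, `atc5`; malformed codes raise an error naming the
#'   offending values.
#' @export
#' @examples
#' validate_atc5("N05BA12")
validate_atc5 <- function(atc5) {
  bad <- unique(atc5[is.na(atc5) | !stringr::str_detect(atc5, ATC5_PATTERN)])
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed ATC level-5 code(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "",
      ". Expected pattern: letter, 2 digits, 2 letters, 2 digits."
    ))
  }
  invisible(atc5)
}

#' Roll an ATC level-5 code up to a coarser level
#'
#' @param atc5 Character vector of 7-character ATC level-5 codes.
#' @param level Target level: 3 (pharmacological subgroup, 4 characters),
#'   4 (chemical subgroup, 5 characters) or 5 (identity).
#' @return Character vector of codes truncated to the target level.
#' @export
#' @examples
#' atc_rollup("N05BA12", 4) # "N05BA"
#' atc_rollup("J01FA10", 3) # "J01F"
atc_rollup <- function(atc5, level = 5) {
  validate_atc5(atc5)
  substr(atc5, 1L, atc_level_width(level))
}

#' Is a drug code an antimicrobial?
#'
#' Antimicrobials and other anti-infectives get the stricter 90-day activity
#' window. The default rule flags ATC main group J (antiinfectives for
#' systemic use) and the antiprotozoal/anthelmintic group P; it can be
#' replaced by any predicate or regular expression where a registry uses
#' bespoke grouping.
#'
#' @param code Character vector of ATC codes at any level.
#' @param pattern Regular expression defining the antimicrobial classes.
#' @return Logical vector.
#' @export
is_antimicrobial <- function(code, pattern = "^(J|P0)") {
  stringr::str_detect(code, pattern)
}
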