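# Column dictionary for the cohort CSV: name -> storage type.
cohort_columns <- function() {
  c(id = "character", diagnosis = "character", sex = "character",
    age = "numeric",
    hads_anxiety = "numeric", hads_depression = "numeric",
    hads_total = "numeric",
    dhi_physical = "numeric", dhi_emotional = "numeric",
    dhi_functional = "numeric", dhi_total = "numeric",
    npq_upright = "numeric", npq_movement = "numeric",
    npq_visual = "numeric", npq_total = "numeric",
    caloric_right_warm = "numeric", caloric_right_cool = "numeric",
    caloric_left_warm = "numeric", caloric_left_cool = "numeric",
    cp_percent = "numeric", cp_weaker_side = "character",
    dp_percent = "numeric",
    cvemp_iaar = "numeric", ovemp_iaar = "numeric",
    foam_ratio = "numeric", romberg_ratio_foam = "numeric",
    vor_dp_percent = "numeric",
    vhit_gain_better = "numeric", vhit_gain_worse = "numeric",
    vhit_ar = "numeric", cus_present = "logical",
    complete_case = "logical")
}

#' Write a cohort table to CSV
#'
#' RFC-4180 CSV, UTF-8, "." decimal separator; missing values are empty
#' cells.
#'
#' @param cohort Cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

# rows violating questionnaire structure (range, granularity or additivity)
invalid_score_rows <- function(cohort) {
  bad <- rep(FALSE, nrow(cohort))
  for (block in questionnaire_spec()) {
    parts <- intersect(names(block$parts), names(cohort))
    for (p in parts) {
      v <- cohort[[p]]
      bad <- bad | (!is.na(v) &
                      (v < 0 | v > block$parts[[p]] | v %% block$step != 0))
    }
    if (block$total %in% names(cohort) &&
        all(names(block$parts) %in% names(cohort))) {
      sums <- Reduce(`+`, cohort[names(block$parts)])
      tot <- cohort[[block$total]]
      bad <- bad | (!is.na(sums) & (is.na(tot) | tot != sums))
    }
  }
  which(bad)
}

#' Read a cohort table from CSV
#'
#' Parses and types the cohort columns (empty cells become missing values,
#' never zero) and validates questionnaire score structure. In strict mode
#' unknown columns or any invalid row abort with the offending field and
#' record; in lenient mode unknown columns are kept with a warning and
#' invalid rows are dropped with a warning naming them.
#'
#' @param path CSV file path.
#' @param strict Abort on problems (default) instead of warn-and-skip.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dict <- cohort_columns()
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  unknown <- setdiff(header, names(dict))
  if (length(unknown)) {
    msg <- paste("unknown cohort columns:", paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  classes <- ifelse(header %in% names(dict), dict[header], NA)
  cohort <- utils::read.csv(path, colClasses = classes, check.names = FALSE,
                            na.strings = "", fileEncoding = "UTF-8")
  bad <- invalid_score_rows(cohort)
  if (length(bad)) {
    ids <- if (!is.null(cohort$id)) cohort$id[bad] else bad
    if (strict) {
      validate_scores(cohort)  # produces the field-specific error message
      stop("invalid questionnaire rows: ", paste(ids, collapse = ", "),
           call. = FALSE)
    }
    warning("dropping rows with invalid questionnaire scores: ",
            paste(ids, collapse = ", "), call. = FALSE)
    cohort <- cohort[-bad, ]
    rownames(cohort) <- NULL
  }
  cohort
}
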