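#' Read a cohort CSV
#'
#' Reads per-subject records in the package's cohort dialect: demographic
#' columns (`age`, `sex`, `menstrual_status`), raw epistaxis answers
#' (`ess_frequency`, `ess_duration`, `ess_gushing` with the documented
#' token spellings), intakes (`diet_intake_mg`, `supplement_elemental_mg`)
#' and any hematinic columns present. Categorical tokens are validated.
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("age", "sex", "menstrual_status", "ess_frequency",
              "ess_duration", "ess_gushing", "diet_intake_mg",
              "supplement_elemental_mg")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("cohort CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_f <- setdiff(unique(df$ess_frequency), ess_frequency_levels)
  bad_d <- setdiff(unique(df$ess_duration), ess_duration_levels)
  if (length(bad_f) || length(bad_d)) {
    stop("unknown epistaxis category token(s): ",
         paste(c(bad_f, bad_d), collapse = ", "), call. = FALSE)
  }
  df$ess_gushing <- as.logical(df$ess_gushing)
  df
}

#' Write a cohort CSV
#'
#' @param cohort a cohort tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
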