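#' Supported volume units for timed-bleed records
#' @export
volume_units <- c("mL", "cup_imperial", "cup_us", "hb_drop_g_dl",
                  "container_mL")

# mL per unit of volume_value; hb_drop_g_dl uses the survey back-calculation
# convention (750 mL of blood per 1 g/dl hemoglobin fall over hours), which
# deliberately differs from the 470 mL one-transfusion-unit rule used in the
# clinical-settings table (see hb_fall_to_volume).
unit_to_ml_factor <- c(mL = 1, cup_imperial = 284.131, cup_us = 236.59,
                       hb_drop_g_dl = 750, container_mL = 1)

#' Convert a reported bleed volume to millilitres
#'
#' Linear conversion per unit: imperial cup 284.131 mL, US cup 236.59 mL,
#' hemoglobin drop 750 mL per g/dl (acute back-calculation convention),
#' `container_mL` and `mL` identity.
#'
#' @param value positive numeric (vectorised).
#' @param unit one of [volume_units] (vectorised).
#' @return mL.
#' @examples
#' convert_volume_to_ml(2, "hb_drop_g_dl") # 1500
#' @export
convert_volume_to_ml <- function(value, unit) {
  bad <- setdiff(unique(unit), volume_units)
  if (length(bad)) {
    stop("unknown volume unit: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(value <= 0)) {
    stop("volume values must be positive", call. = FALSE)
  }
  value * unname(unit_to_ml_factor[unit])
}

#' Construct a timed-bleed record
#'
#' One survey record of a nosebleed with both duration and measured volume.
#'
#' @param duration minutes, positive.
#' @param volume_value positive volume in `volume_unit`.
#' @param volume_unit one of [volume_units].
#' @param corroborated logical; whether independent evidence (hemodynamic
#'   consequence, hemoglobin fall, transfusion/admission) supported the
#'   record.
#' @return an object of class `timed_bleed`.
#' @export
timed_bleed <- function(duration, volume_value, volume_unit = "mL",
                        corroborated = FALSE) {
  volume_unit <- match.arg(volume_unit, volume_units)
  stopifnot(is.numeric(duration), length(duration) == 1L,
            is.numeric(volume_value), length(volume_value) == 1L,
            is.logical(corroborated), length(corroborated) == 1L)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (volume_value <= 0) stop("volume_value must be positive", call. = FALSE)
  structure(list(duration = as.numeric(duration),
                 volume_value = as.numeric(volume_value),
                 volume_unit = volume_unit,
                 corroborated = corroborated),
            class = "timed_bleed")
}

#' Bleed rate of a timed-bleed record
#'
#' Converted volume divided by duration.
#'
#' @param bleed a [timed_bleed()], or a data frame with columns
#'   `duration_min`, `volume_value`, `volume_unit`.
#' @return mL/min.
#' @examples
#' bleed_rate(timed_bleed(30, 270)) # 9
#' @export
bleed_rate <- function(bleed) {
  if (inherits(bleed, "timed_bleed")) {
    if (bleed$duration <= 0) stop("duration must be positive", call. = FALSE)
    return(convert_volume_to_ml(bleed$volume_value, bleed$volume_unit) /
             bleed$duration)
  }
  if (is.data.frame(bleed)) {
    if (any(bleed$duration_min <= 0)) {
      stop("duration must be positive", call. = FALSE)
    }
    return(convert_volume_to_ml(bleed$volume_value, bleed$volume_unit) /
             bleed$duration_min)
  }
  stop("bleed must be a timed_bleed or a data frame", call. = FALSE)
}

#' Bleed-rate percentiles with outlier exclusion
#'
#' Computes the per-record rates (mL/min), excludes implausible
#' uncorroborated records, and summarises the retained rates: median,
#' interquartile range, 20th and 5th percentiles. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7). The
#' default exclusion rule drops uncorroborated records whose rate exceeds
#' `max_uncorroborated_rate` mL/min or whose converted volume exceeds
#' `max_uncorroborated_volume` mL, mirroring the corroboration criterion
#' used to exclude extreme survey records.
#'
#' @param bleeds a data frame with columns `duration_min`, `volume_value`,
#'   `volume_unit`, `corroborated` (as read by [read_timed_bleeds()] or made
#'   by [generate_timed_bleeds()]), or a list of [timed_bleed()] objects.
#' @param max_uncorroborated_rate mL/min threshold (default 50); `Inf`
#'   disables.
#' @param max_uncorroborated_volume mL threshold (default 5000); `Inf`
#'   disables.
#' @return an object of class `rate_summary`: list with `median`, `iqr_low`,
#'   `iqr_high`, `p20`, `p5`, `n_used`, `n_excluded`.
#' @export
rate_percentiles <- function(bleeds, max_uncorroborated_rate = 50,
                             max_uncorroborated_volume = 5000) {
  if (is.list(bleeds) && !is.data.frame(bleeds) &&
      all(vapply(bleeds, inherits, logical(1), "timed_bleed"))) {
    bleeds <- tibble::tibble(
      duration_min = vapply(bleeds, `[[`, numeric(1), "duration"),
      volume_value = vapply(bleeds, `[[`, numeric(1), "volume_value"),
      volume_unit = vapply(bleeds, `[[`, character(1), "volume_unit"),
      corroborated = vapply(bleeds, `[[`, logical(1), "corroborated")
    )
  }
  stopifnot(is.data.frame(bleeds))
  if (nrow(bleeds) == 0L) {
    stop("no timed-bleed records supplied", call. = FALSE)
  }
  volume_ml <- convert_volume_to_ml(bleeds$volume_value, bleeds$volume_unit)
  rate <- volume_ml / bleeds$duration_min
  exclude <- !bleeds$corroborated &
    (rate > max_uncorroborated_rate | volume_ml > max_uncorroborated_volume)
  used <- rate[!exclude]
  if (length(used) == 0L) {
    stop("all records excluded; no rates left to summarise", call. = FALSE)
  }
  q <- unname(quantile(used, c(0.05, 0.20, 0.25, 0.50, 0.75), type = 7))
  structure(list(median = q[4], iqr_low = q[3], iqr_high = q[5],
                 p20 = q[2], p5 = q[1],
                 n_used = length(used), n_excluded = sum(exclude)),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf(paste0("<rate_summary> median %.1f [IQR %.1f, %.1f] mL/min; ",
                     "p20 %.1f; p5 %.1f (n = %d used, %d excluded)\n"),
              x$median, x$iqr_low, x$iqr_high, x$p20, x$p5,
              x$n_used, x$n_excluded))
  invisible(x)
}

#' Published default bleed-rate constants
#'
#' The shipped defaults used when no timed-bleed calibration data are
#' available: median 7.9 mL/min (gushing), 20th percentile 2.3 mL/min (not
#' gushing), 5th percentile 0.3 mL/min (sensitivity floor).
#'
#' @return named numeric vector.
#' @export
default_rate_constants <- function() {
  c(median = 7.9, p20 = 2.3, p5 = 0.3)
}

#' Read a timed-bleed survey CSV
#'
#' Expects columns `duration_min`, `volume_value`, `volume_unit`,
#' `corroborated`.
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_timed_bleeds <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("duration_min", "volume_value", "volume_unit", "corroborated")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("timed-bleed CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$corroborated <- as.logical(df$corroborated)
  df
}
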