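#' Epistaxis severity-score category levels
#'
#' The fixed tick-box categories for typical nosebleed frequency and
#' duration, in increasing order of severity.
#'
#' @format `ess_frequency_levels`: character vector of 6 frequency tokens.
#' @export
ess_frequency_levels <- c("lt_monthly", "monthly", "weekly",
                          "several_per_week", "daily", "several_per_day")

#' @rdname ess_frequency_levels
#' @format `ess_duration_levels`: character vector of 5 duration tokens
#'   (minutes bands: <1, 1-5, 6-15, 16-30, >30).
#' @export
ess_duration_levels <- c("lt_1", "1_5", "6_15", "16_30", "gt_30")

#' Construct one subject's raw epistaxis report
#'
#' Raw tick-box answers from the epistaxis severity score instrument:
#' typical nosebleed frequency, typical duration, and whether bleeds are
#' "typically pouring or gushing" (a proxy for arterial bleeding).
#'
#' @param frequency_category one of [ess_frequency_levels].
#' @param duration_category one of [ess_duration_levels].
#' @param gushing logical; typically pouring/gushing.
#' @return an object of class `epistaxis_report`.
#' @export
epistaxis_report <- function(frequency_category, duration_category, gushing) {
  frequency_category <- match.arg(frequency_category, ess_frequency_levels)
  duration_category <- match.arg(duration_category, ess_duration_levels)
  stopifnot(is.logical(gushing), length(gushing) == 1L, !is.na(gushing))
  structure(list(frequency_category = frequency_category,
                 duration_category = duration_category,
                 gushing = gushing),
            class = "epistaxis_report")
}

#' Construct category-to-number maps for epistaxis quantification
#'
#' Maps the frequency and duration tick-box categories to bleeds/month and
#' minutes, and fixes the two bleed rates (mL/min) assigned to gushing and
#' non-gushing bleeds. Defaults: frequency map `(0, 1, 3.5, 17.7, 30, 70)`
#' whose endpoints and middle values are anchored to the validation cohort's
#' published order statistics; duration map `(0.5, 2.5, 10, 23, 30)` minutes;
#' rates 7.9 (gushing; timed-bleed survey median) and 2.3 (not gushing; 20th
#' percentile) mL/min.
#'
#' @param frequency_map named or unnamed numeric vector of length 6, one
#'   bleeds/month value per frequency category in increasing order;
#'   non-negative and strictly increasing.
#' @param duration_map numeric vector of length 5, minutes per duration
#'   category; positive and strictly increasing.
#' @param rate_gushing,rate_not_gushing mL/min; must satisfy
#'   `rate_gushing > rate_not_gushing > 0`.
#' @return an object of class `category_maps`.
#' @export
category_maps <- function(frequency_map = c(lt_monthly = 0, monthly = 1,
                                            weekly = 3.5,
                                            several_per_week = 17.7,
                                            daily = 30, several_per_day = 70),
                          duration_map = c(lt_1 = 0.5, `1_5` = 2.5,
                                           `6_15` = 10, `16_30` = 23,
                                           gt_30 = 30),
                          rate_gushing = 7.9, rate_not_gushing = 2.3) {
  stopifnot(is.numeric(frequency_map), length(frequency_map) == 6L,
            is.numeric(duration_map), length(duration_map) == 5L)
  frequency_map <- setNames(as.numeric(frequency_map), ess_frequency_levels)
  duration_map <- setNames(as.numeric(duration_map), ess_duration_levels)
  if (any(frequency_map < 0) || any(diff(frequency_map) <= 0)) {
    stop("frequency_map must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (any(duration_map <= 0) || any(diff(duration_map) <= 0)) {
    stop("duration_map must be positive and strictly increasing",
         call. = FALSE)
  }
  if (!(rate_gushing > rate_not_gushing && rate_not_gushing > 0)) {
    stop("rates must satisfy rate_gushing > rate_not_gushing > 0",
         call. = FALSE)
  }
  structure(list(frequency_map = frequency_map, duration_map = duration_map,
                 rate_gushing = as.numeric(rate_gushing),
                 rate_not_gushing = as.numeric(rate_not_gushing)),
            class = "category_maps")
}

#' Map a frequency category to bleeds per month
#'
#' @param category one of [ess_frequency_levels] (vectorised).
#' @param maps a [category_maps()].
#' @return bleeds/month.
#' @export
frequency_to_monthly_count <- function(category, maps = category_maps()) {
  stopifnot(inherits(maps, "category_maps"))
  bad <- setdiff(unique(category), ess_frequency_levels)
  if (length(bad)) {
    stop("unknown frequency category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(maps$frequency_map[category])
}

#' Map a duration category to minutes
#'
#' @param category one of [ess_duration_levels] (vectorised).
#' @inheritParams frequency_to_monthly_count
#' @return minutes.
#' @export
duration_to_minutes <- function(category, maps = category_maps()) {
  stopifnot(inherits(maps, "category_maps"))
  bad <- setdiff(unique(category), ess_duration_levels)
  if (length(bad)) {
    stop("unknown duration category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(maps$duration_map[category])
}

#' Estimated monthly nosebleed blood volume
#'
#' Bleeds/month times typical duration (minutes) times the bleed rate
#' appropriate to the reported intensity (gushing vs not). Zero when the
#' frequency category maps to zero bleeds.
#'
#' @param report an [epistaxis_report()], or a data frame with columns
#'   `ess_frequency`, `ess_duration`, `ess_gushing` (vectorised use).
#' @param maps a [category_maps()].
#' @return mL/month (scalar or vector).
#' @examples
#' monthly_nosebleed_volume(
#'   epistaxis_report("several_per_day", "16_30", gushing = TRUE)
#' ) # 70 * 23 * 7.9 = 12719
#' @export
monthly_nosebleed_volume <- function(report, maps = category_maps()) {
  stopifnot(inherits(maps, "category_maps"))
  if (inherits(report, "epistaxis_report")) {
    freq <- report$frequency_category
    dur <- report$duration_category
    gush <- report$gushing
  } else if (is.data.frame(report)) {
    freq <- report$ess_frequency
    dur <- report$ess_duration
    gush <- report$ess_gushing
  } else {
    stop("report must be an epistaxis_report or a data frame", call. = FALSE)
  }
  rate <- ifelse(gush, maps$rate_gushing, maps$rate_not_gushing)
  frequency_to_monthly_count(freq, maps) * duration_to_minutes(dur, maps) * rate
}
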