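#' Construct a three-month loss window
#'
#' Blood losses (mL) assigned to each month of a 3-month rectification
#' window. A single acute loss occupies month 1 with zeros elsewhere; a
#' chronic recurring loss fills all three months equally (see
#' [loss_window_single()] / [loss_window_recurring()]).
#'
#' @param monthly_losses numeric vector of length 3, each >= 0 (mL).
#' @return an object of class `loss_window`.
#' @export
loss_window <- function(monthly_losses) {
  stopifnot(is.numeric(monthly_losses), length(monthly_losses) == 3L)
  if (any(monthly_losses < 0)) {
    stop("monthly losses must be non-negative", call. = FALSE)
  }
  structure(list(monthly_losses = as.numeric(monthly_losses)),
            class = "loss_window")
}

#' @rdname loss_window
#' @param volume_ml mL lost in a single event (month 1).
#' @export
loss_window_single <- function(volume_ml) {
  loss_window(c(volume_ml, 0, 0))
}

#' @rdname loss_window
#' @param ml_per_month mL lost every month (chronic recurring loss).
#' @export
loss_window_recurring <- function(ml_per_month) {
  loss_window(rep(ml_per_month, 3))
}

#' Extra daily iron requirement for a loss window
#'
#' The mean monthly loss across the 3-month window, expressed as a multiple
#' of the scheme's menstrual reference volume (80 mL/month by default), times
#' the scheme's effective increment (mg/day). This is the daily dietary iron
#' needed, on top of the base allowance, to replace the window's losses.
#'
#' @param window a [loss_window()].
#' @param scheme an [intake_scheme()].
#' @return mg/day (unrounded).
#' @examples
#' extra_requirement(loss_window_single(470), default_schemes()$us_rda)
#' # (470/3)/80 * 10 = 19.58...
#' @export
extra_requirement <- function(window, scheme) {
  stopifnot(inherits(window, "loss_window"), inherits(scheme, "intake_scheme"))
  mean_monthly <- mean(window$monthly_losses)
  (mean_monthly / scheme$menstrual_reference_volume) *
    effective_increment(scheme)
}

#' Compute the hemorrhage-adjusted iron requirement
#'
#' HAIR = base allowance (from the subject's class under the scheme) +
#' extra requirement for the loss window. `log_hair` is the natural
#' logarithm of HAIR.
#'
#' @param subject a [subject_profile()].
#' @param window a [loss_window()].
#' @param scheme an [intake_scheme()].
#' @return an object of class `hair_result`: list with `base`, `extra`,
#'   `hair`, `log_hair` (all mg/day except `log_hair`), unrounded.
#' @examples
#' res <- compute_hair(subject_profile(40, "male"), loss_window_single(470),
#'                     default_schemes()$us_rda)
#' round_half_up(res$hair, 1) # 27.6
#' @export
compute_hair <- function(subject, window, scheme) {
  base <- resolve_base(scheme, subject)
  extra <- extra_requirement(window, scheme)
  hair <- base + extra
  structure(list(base = base, extra = extra, hair = hair,
                 log_hair = log(hair)),
            class = "hair_result")
}

#' @export
print.hair_result <- function(x, ...) {
  cat(sprintf("<hair_result> HAIR %.1f mg/day (base %.1f + extra %.1f); log(HAIR) %.2f\n",
              round_half_up(x$hair, 1), x$base, round_half_up(x$extra, 1),
              x$log_hair))
  invisible(x)
}

#' Convert a hemorrhagic hemoglobin fall to blood volume
#'
#' Uses the clinical rule of thumb that one unit of blood (470 mL) raises
#' the hemoglobin by 1 g/dl in a non-bleeding adult; a fall of `delta_hb`
#' g/dl therefore corresponds to `delta_hb * 470` mL lost. (The timed-bleed
#' survey conversion in [convert_volume_to_ml()] uses the distinct 750
#' mL/g/dl acute back-calculation convention.)
#'
#' @param delta_hb hemoglobin fall in g/dl, >= 0 (vectorised).
#' @return mL.
#' @examples
#' hb_fall_to_volume(4) # 1880
#' @export
hb_fall_to_volume <- function(delta_hb) {
  if (any(delta_hb < 0)) {
    stop("hemoglobin fall must be non-negative", call. = FALSE)
  }
  delta_hb * 470
}

#' Assess dietary intake against RDA and HAIR
#'
#' @param hair a [hair_result()] from [compute_hair()].
#' @param diet dietary iron intake, mg/day.
#' @param supplement_mg daily elemental iron from supplements, mg/day.
#' @param subject a [subject_profile()].
#' @param scheme an [intake_scheme()].
#' @return a list of class `intake_assessment` with `diet_intake`,
#'   `supplement_elemental`, `total_intake`, `shortfall` (HAIR minus total
#'   intake; negative when intake exceeds HAIR), `meets_rda`, `meets_hair`.
#' @export
assess_intake <- function(hair, diet, supplement_mg, subject, scheme) {
  stopifnot(inherits(hair, "hair_result"), diet >= 0, supplement_mg >= 0)
  total <- diet + supplement_mg
  structure(list(diet_intake = diet, supplement_elemental = supplement_mg,
                 total_intake = total, shortfall = hair$hair - total,
                 meets_rda = total >= resolve_base(scheme, subject),
                 meets_hair = total >= hair$hair),
            class = "intake_assessment")
}

#' Default clinical-settings pack
#'
#' Typical clinical blood-loss settings and their approximate volumes:
#' no additional losses; three-monthly blood donation (470 mL); hemorrhagic
#' hemoglobin falls of 1-4 g/dl at 470 mL per g/dl (peri-partum loss, TURP /
#' colectomy / minor post-partum hemorrhage, moderate post-partum
#' hemorrhage, nephrectomy); femoral head fracture (611 mL). All are single
#' events within the 3-month window.
#'
#' @return a tibble with columns `setting`, `volume_ml`, `recurring`.
#' @export
default_clinical_settings <- function() {
  tibble::tibble(
    setting = c("No additional losses",
                "Blood donation every 3 months",
                "Hemorrhagic hemoglobin fall of 1 g/dl",
                "Hemorrhagic hemoglobin fall of 2 g/dl",
                "Hemorrhagic hemoglobin fall of 3 g/dl",
                "Hemorrhagic hemoglobin fall of 4 g/dl",
                "Femoral head fracture"),
    volume_ml = c(0, 470, hb_fall_to_volume(1:4), 611),
    recurring = FALSE
  )
}

#' HAIR values for clinical settings under one or more schemes
#'
#' One row per setting; one column per scheme x subject-class combination
#' (default allowance class and pre-menopausal class), each value rounded
#' half-up to 1 decimal place. The default pack with the US and UK schemes
#' regenerates the published clinical-settings reference table.
#'
#' @param schemes a named list of [intake_scheme()] objects (default: the
#'   `us_rda` and `uk_rni` presets).
#' @param settings a tibble as returned by [default_clinical_settings()]:
#'   columns `setting`, `volume_ml`, and `recurring` (`TRUE` = the volume
#'   recurs every month; `FALSE` = single event in the window).
#' @return a tibble: `setting`, `volume_ml`, then one numeric column
#'   `<scheme_id>_default` and `<scheme_id>_premenopausal` per scheme.
#' @export
clinical_settings_table <- function(schemes = default_schemes()[c("us_rda",
                                                                  "uk_rni")],
                                    settings = default_clinical_settings()) {
  stopifnot(is.data.frame(settings),
            all(c("setting", "volume_ml", "recurring") %in% names(settings)))
  out <- tibble::tibble(setting = settings$setting,
                        volume_ml = settings$volume_ml)
  for (sc in schemes) {
    vals_def <- numeric(nrow(settings))
    vals_pre <- numeric(nrow(settings))
    for (i in seq_len(nrow(settings))) {
      w <- if (settings$recurring[i]) {
        loss_window_recurring(settings$volume_ml[i])
      } else {
        loss_window_single(settings$volume_ml[i])
      }
      extra <- extra_requirement(w, sc)
      vals_def[i] <- round_half_up(sc$base_default + extra, 1)
      vals_pre[i] <- round_half_up(sc$base_premenopausal + extra, 1)
    }
    out[[paste0(sc$scheme_id, "_default")]] <- vals_def
    out[[paste0(sc$scheme_id, "_premenopausal")]] <- vals_pre
  }
  out
}
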