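#' Construct a reference-intake scheme
#'
#' A scheme encodes a national set of recommended daily iron intakes: the
#' default allowance (males and post-menopausal females), the higher
#' allowance for non-pregnant pre-menopausal females, and optionally a
#' pregnancy allowance. The difference between the pre-menopausal and the
#' default allowance -- the "pre-menopausal increment" -- is interpreted as
#' the daily iron needed to replace `menstrual_reference_volume` mL of blood
#' loss per month (80 mL, the menorrhagia threshold, by convention).
#'
#' `increment_override`, when supplied, replaces the base difference as the
#' mg/day-per-reference-volume conversion factor while leaving the base
#' allowances untouched. This supports hybrid rulesets that pair one
#' country's allowances with another's increment.
#'
#' @param scheme_id short label, e.g. `"us_rda"`.
#' @param base_default mg/day for males and post-menopausal females.
#' @param base_premenopausal mg/day for non-pregnant pre-menopausal females.
#' @param base_pregnant mg/day during pregnancy, or `NA` if the scheme does
#'   not define one.
#' @param increment_override optional mg/day conversion increment replacing
#'   `base_premenopausal - base_default`.
#' @param menstrual_reference_volume mL/month of blood loss the increment is
#'   taken to replace (default 80).
#' @return an object of class `intake_scheme`.
#' @examples
#' us <- intake_scheme("us_rda", 8, 18, base_pregnant = 27)
#' premenopausal_increment(us) # 10
#' @export
intake_scheme <- function(scheme_id, base_default, base_premenopausal,
                          base_pregnant = NA_real_,
                          increment_override = NA_real_,
                          menstrual_reference_volume = 80) {
  stopifnot(is.character(scheme_id), length(scheme_id) == 1L, nzchar(scheme_id))
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  if (!num1(base_default) || !num1(base_premenopausal) ||
      !num1(menstrual_reference_volume)) {
    stop("intake_scheme fields must be single numeric values", call. = FALSE)
  }
  if (base_default <= 0) {
    stop("base_default must be positive", call. = FALSE)
  }
  if (base_premenopausal <= base_default) {
    stop("base_premenopausal must exceed base_default ",
         "(the pre-menopausal increment must be strictly positive)",
         call. = FALSE)
  }
  if (menstrual_reference_volume <= 0) {
    stop("menstrual_reference_volume must be positive", call. = FALSE)
  }
  if (!is.na(increment_override) && increment_override <= 0) {
    stop("increment_override must be positive when supplied", call. = FALSE)
  }
  if (!is.na(base_pregnant) && base_pregnant <= 0) {
    stop("base_pregnant must be positive when supplied", call. = FALSE)
  }
  structure(
    list(scheme_id = scheme_id,
         base_default = as.numeric(base_default),
         base_premenopausal = as.numeric(base_premenopausal),
         base_pregnant = as.numeric(base_pregnant),
         increment_override = as.numeric(increment_override),
         menstrual_reference_volume = as.numeric(menstrual_reference_volume)),
    class = "intake_scheme"
  )
}

#' @export
print.intake_scheme <- function(x, ...) {
  cat(sprintf("<intake_scheme %s>\n", x$scheme_id))
  cat(sprintf("  base (default/premenopausal): %g / %g mg/day\n",
              x$base_default, x$base_premenopausal))
  if (!is.na(x$base_pregnant)) {
    cat(sprintf("  base (pregnant): %g mg/day\n", x$base_pregnant))
  }
  cat(sprintf("  effective increment: %g mg/day per %g mL/month\n",
              effective_increment(x), x$menstrual_reference_volume))
  invisible(x)
}

#' Pre-menopausal increment of a scheme
#'
#' The excess of the pre-menopausal over the default allowance,
#' `base_premenopausal - base_default`. This is the iron cost assigned to the
#' scheme's menstrual reference volume of monthly blood loss.
#'
#' @param scheme an [intake_scheme()].
#' @return mg/day, strictly positive.
#' @export
premenopausal_increment <- function(scheme) {
  stopifnot(inherits(scheme, "intake_scheme"))
  scheme$base_premenopausal - scheme$base_default
}

#' Effective conversion increment of a scheme
#'
#' The increment actually used to convert blood volume to daily iron:
#' `increment_override` when present, otherwise the pre-menopausal increment.
#'
#' @inheritParams premenopausal_increment
#' @return mg/day.
#' @export
effective_increment <- function(scheme) {
  stopifnot(inherits(scheme, "intake_scheme"))
  if (!is.na(scheme$increment_override)) scheme$increment_override
  else premenopausal_increment(scheme)
}

#' Construct a subject profile
#'
#' @param age years.
#' @param sex `"male"` or `"female"`.
#' @param menstrual_status `"premenopausal"`, `"postmenopausal"`, or
#'   `"not_applicable"` (males).
#' @param pregnant logical; only allowed for premenopausal females.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(age, sex,
                            menstrual_status = if (sex == "male")
                              "not_applicable" else "postmenopausal",
                            pregnant = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  menstrual_status <- match.arg(
    menstrual_status, c("premenopausal", "postmenopausal", "not_applicable"))
  stopifnot(is.numeric(age), length(age) == 1L, age >= 0,
            is.logical(pregnant), length(pregnant) == 1L)
  if (sex == "male" && menstrual_status != "not_applicable") {
    stop("males must have menstrual_status = 'not_applicable'", call. = FALSE)
  }
  if (sex == "female" && menstrual_status == "not_applicable") {
    stop("females must have a menstrual_status", call. = FALSE)
  }
  if (pregnant && !(sex == "female" && menstrual_status == "premenopausal")) {
    stop("pregnant is only valid for premenopausal females", call. = FALSE)
  }
  structure(list(age = as.numeric(age), sex = sex,
                 menstrual_status = menstrual_status, pregnant = pregnant),
            class = "subject_profile")
}

#' Resolve the base allowance for a subject under a scheme
#'
#' Males and post-menopausal females receive the default allowance;
#' non-pregnant pre-menopausal females the higher pre-menopausal allowance;
#' pregnant subjects the pregnancy allowance when the scheme defines one.
#'
#' @param scheme an [intake_scheme()].
#' @param subject a [subject_profile()].
#' @return mg/day.
#' @examples
#' resolve_base(default_schemes()$us_rda, subject_profile(40, "male")) # 8
#' @export
resolve_base <- function(scheme, subject) {
  stopifnot(inherits(scheme, "intake_scheme"),
            inherits(subject, "subject_profile"))
  if (subject$pregnant) {
    if (is.na(scheme$base_pregnant)) {
      stop(sprintf("scheme '%s' defines no pregnancy allowance",
                   scheme$scheme_id), call. = FALSE)
    }
    return(scheme$base_pregnant)
  }
  if (subject$sex == "female" && subject$menstrual_status == "premenopausal") {
    scheme$base_premenopausal
  } else {
    scheme$base_default
  }
}

#' Built-in reference-intake schemes
#'
#' Three presets: `us_rda` (8 / 18 / 27 mg/day), `uk_rni` (8.7 / 14.8 mg/day,
#' no pregnancy value), and `study_hybrid` (US allowances 8 / 18 paired with
#' the UK-derived conversion increment 6.1 mg/day per 80 mL/month, the
#' combination that reproduces the validation cohort's published derived
#' values).
#'
#' @return a named list of [intake_scheme()] objects.
#' @export
default_schemes <- function() {
  list(
    us_rda = intake_scheme("us_rda", 8, 18, base_pregnant = 27),
    uk_rni = intake_scheme("uk_rni", 8.7, 14.8),
    study_hybrid = intake_scheme("study_hybrid", 8, 18, base_pregnant = 27,
                                 increment_override = 6.1)
  )
}

scheme_fields <- c("scheme_id", "base_default", "base_premenopausal",
                   "base_pregnant", "increment_override",
                   "menstrual_reference_volume")

#' Load reference-intake schemes from a YAML config
#'
#' Reads user-defined schemes and merges them with the built-in presets
#' (user definitions with a preset's id replace the preset). The config is a
#' YAML mapping `schemes:` to a list of entries with keys `scheme_id`,
#' `base_default`, `base_premenopausal`, and optionally `base_pregnant`,
#' `increment_override`, `menstrual_reference_volume`. A packaged example
#' lives at `system.file("extdata", "intake_schemes.yaml", package =
#' "hairmetric")`.
#'
#' @param path path to a YAML file, or `NULL` for the presets alone.
#' @return a named list of [intake_scheme()] objects.
#' @export
load_schemes <- function(path = NULL) {
  schemes <- default_schemes()
  if (is.null(path)) {
    return(schemes)
  }
  cfg <- yaml::read_yaml(path)
  entries <- cfg$schemes
  if (is.null(entries) && length(cfg)) {
    stop("scheme config must place entries under top-level key 'schemes'",
         call. = FALSE)
  }
  for (entry in entries) {
    unknown <- setdiff(names(entry), scheme_fields)
    if (length(unknown)) {
      stop("unknown scheme config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (req in c("scheme_id", "base_default", "base_premenopausal")) {
      if (is.null(entry[[req]])) {
        stop("scheme config entry missing required key '", req, "'",
             call. = FALSE)
      }
    }
    sc <- intake_scheme(
      scheme_id = entry$scheme_id,
      base_default = entry$base_default,
      base_premenopausal = entry$base_premenopausal,
      base_pregnant = entry$base_pregnant %||% NA_real_,
      increment_override = entry$increment_override %||% NA_real_,
      menstrual_reference_volume = entry$menstrual_reference_volume %||% 80
    )
    schemes[[sc$scheme_id]] <- sc
  }
  schemes
}

#' Write schemes to a YAML config
#'
#' Inverse of [load_schemes()]: round-tripping preserves all fields.
#'
#' @param schemes a named list of [intake_scheme()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schemes <- function(schemes, path) {
  entries <- lapply(unname(schemes), function(sc) {
    entry <- sc[scheme_fields]
    entry[!vapply(entry, function(v) is.na(v) || is.null(v), logical(1))]
  })
  yaml::write_yaml(list(schemes = entries), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
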