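#' Construct a hepcidin panel table
#'
#' Validates a table of paired hepcidin / ferritin measurements and adds
#' the hepcidin:ferritin ratio. The ratio follows the field's dimensionless
#' usage (ng/mL divided by ug/L at face value).
#'
#' @param hepcidin ng/mL, positive.
#' @param ferritin ug/L, positive.
#' @return a tibble with columns `hepcidin`, `ferritin`, `ratio`.
#' @export
hepcidin_panels <- function(hepcidin, ferritin) {
  stopifnot(is.numeric(hepcidin), is.numeric(ferritin),
            length(hepcidin) == length(ferritin))
  if (any(hepcidin <= 0)) stop("hepcidin must be positive", call. = FALSE)
  if (any(ferritin <= 0)) stop("ferritin must be positive", call. = FALSE)
  tibble::tibble(hepcidin = as.numeric(hepcidin),
                 ferritin = as.numeric(ferritin),
                 ratio = hepcidin / ferritin)
}

#' Quadratic ferritin model for log hepcidin
#'
#' Least-squares fit of `ln(hepcidin) ~ ferritin + ferritin^2`. With a
#' negative quadratic term the fitted curve rises with ferritin and
#' flattens/declines at high ferritin, the expected saturating regulatory
#' response of the iron hormone to iron stores.
#'
#' @param panels a data frame with positive columns `hepcidin` and
#'   `ferritin` (see [hepcidin_panels()]).
#' @return a list of class `hepcidin_fit`: `coefficients` (named `b0`,
#'   `ferritin`, `ferritin_sq`), `ci` (95% matrix), `r_squared_adj`,
#'   `p_values`, `n`, `model`.
#' @export
fit_hepcidin_ferritin <- function(panels) {
  stopifnot(is.data.frame(panels),
            all(c("hepcidin", "ferritin") %in% names(panels)))
  panels <- panels[stats::complete.cases(panels[c("hepcidin", "ferritin")]), ]
  if (nrow(panels) < 5L) {
    stop("need at least 5 hepcidin panels", call. = FALSE)
  }
  if (any(panels$hepcidin <= 0)) {
    stop("hepcidin must be positive for the log model", call. = FALSE)
  }
  if (sd(panels$ferritin) == 0) {
    stop("rank-deficient design: ferritin is constant", call. = FALSE)
  }
  dat <- data.frame(y = log(panels$hepcidin), f = panels$ferritin,
                    f2 = panels$ferritin^2)
  fit <- lm(y ~ f + f2, data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design: ferritin and ferritin^2 are collinear",
         call. = FALSE)
  }
  smry <- summary(fit)
  ci <- confint(fit)
  structure(list(
    coefficients = setNames(coef(fit), c("b0", "ferritin", "ferritin_sq")),
    ci = ci,
    r_squared_adj = smry$adj.r.squared,
    p_values = setNames(smry$coefficients[, 4],
                        c("b0", "ferritin", "ferritin_sq")),
    n = nrow(dat),
    model = fit
  ), class = "hepcidin_fit")
}

#' @export
print.hepcidin_fit <- function(x, ...) {
  cat(sprintf(paste0("<hepcidin_fit> ln(hepcidin) ~ ferritin + ferritin^2 ",
                     "(n = %d)\n  ferritin %.3g (95%% CI %.3g, %.3g); ",
                     "ferritin^2 %.3g; adj R^2 = %.2f\n"),
              x$n, x$coefficients["ferritin"], x$ci["f", 1], x$ci["f", 2],
              x$coefficients["ferritin_sq"], x$r_squared_adj))
  invisible(x)
}

#' Geometric mean of the hepcidin:ferritin ratio
#'
#' `exp(mean +/- 1.96 se)` of the log ratios; the screening statistic
#' compared against published control-group values.
#'
#' @param panels a data frame with a positive `ratio` column, or with
#'   `hepcidin` and `ferritin` columns from which the ratio is derived.
#' @return a list with `geometric_mean`, `ci_low`, `ci_high`, `n`.
#' @examples
#' ratio_geometric_mean(hepcidin_panels(c(1, 4), c(1, 1)))$geometric_mean # 2
#' @export
ratio_geometric_mean <- function(panels) {
  stopifnot(is.data.frame(panels))
  ratio <- if ("ratio" %in% names(panels)) panels$ratio
  else panels$hepcidin / panels$ferritin
  ratio <- ratio[!is.na(ratio)]
  if (any(ratio <= 0)) {
    stop("all ratios must be positive for a geometric mean", call. = FALSE)
  }
  lr <- log(ratio)
  n <- length(lr)
  se <- if (n > 1) sd(lr) / sqrt(n) else 0
  list(geometric_mean = exp(mean(lr)),
       ci_low = exp(mean(lr) - 1.96 * se),
       ci_high = exp(mean(lr) + 1.96 * se),
       n = n)
}

#' Probe a covariate against the ferritin-restricted hepcidin model
#'
#' Adds one covariate to the `ln(hepcidin) ~ ferritin + ferritin^2` model
#' and reports the p-value of the added term, leaving the base model
#' otherwise unchanged. Collinear covariates (e.g. ferritin itself) are
#' flagged rather than fitted.
#'
#' @param model a `hepcidin_fit` from [fit_hepcidin_ferritin()].
#' @param panels the data frame the model was fitted to.
#' @param covariate name of a column of `panels` to probe.
#' @return a list with `covariate`, `p_value`, `estimate`, and `collinear`
#'   (logical; `p_value` is `NA` when flagged).
#' @export
add_covariate_probe <- function(model, panels, covariate) {
  stopifnot(inherits(model, "hepcidin_fit"), is.data.frame(panels),
            covariate %in% names(panels))
  dat <- data.frame(y = log(panels$hepcidin), f = panels$ferritin,
                    f2 = panels$ferritin^2, cv = panels[[covariate]])
  dat <- dat[stats::complete.cases(dat), ]
  fit <- lm(y ~ f + f2 + cv, data = dat)
  if (any(is.na(coef(fit)))) {
    return(list(covariate = covariate, p_value = NA_real_,
                estimate = NA_real_, collinear = TRUE))
  }
  cf <- summary(fit)$coefficients
  list(covariate = covariate, p_value = cf["cv", 4],
       estimate = cf["cv", 1], collinear = FALSE)
}
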