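#' Derive per-subject HAIR columns for a cohort table
#'
#' Takes a cohort tibble (one row per subject) holding raw epistaxis
#' severity-score answers and intakes, and appends the derived chain:
#' monthly nosebleed volume, base allowance, extra requirement, HAIR,
#' log(HAIR), total intake, shortfall, and the RDA / HAIR attainment flags.
#' Nosebleed losses are treated as chronic recurring losses (all three
#' window months equal).
#'
#' @param cohort a tibble with columns `age`, `sex`, `menstrual_status`,
#'   `ess_frequency`, `ess_duration`, `ess_gushing`, `diet_intake_mg`,
#'   `supplement_elemental_mg`.
#' @param scheme an [intake_scheme()] (default: the `study_hybrid` preset).
#' @param maps a [category_maps()].
#' @return the cohort with columns `nosebleed_ml_month`, `base_mg_day`,
#'   `extra_mg_day`, `hair_mg_day`, `log_hair`, `total_intake_mg`,
#'   `shortfall_mg_day`, `meets_rda`, `meets_hair` appended.
#' @export
add_hair <- function(cohort, scheme = default_schemes()$study_hybrid,
                     maps = category_maps()) {
  stopifnot(is.data.frame(cohort), inherits(scheme, "intake_scheme"))
  needed <- c("age", "sex", "menstrual_status", "ess_frequency",
              "ess_duration", "ess_gushing", "diet_intake_mg",
              "supplement_elemental_mg")
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("cohort missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vol <- monthly_nosebleed_volume(cohort, maps)
  premeno <- cohort$sex == "female" & cohort$menstrual_status == "premenopausal"
  pregnant <- if ("pregnant" %in% names(cohort)) cohort$pregnant else FALSE
  base <- ifelse(premeno, scheme$base_premenopausal, scheme$base_default)
  if (any(pregnant)) {
    if (is.na(scheme$base_pregnant)) {
      stop(sprintf("scheme '%s' defines no pregnancy allowance",
                   scheme$scheme_id), call. = FALSE)
    }
    base[pregnant] <- scheme$base_pregnant
  }
  extra <- (vol / scheme$menstrual_reference_volume) *
    effective_increment(scheme)
  hair <- base + extra
  total <- cohort$diet_intake_mg + cohort$supplement_elemental_mg
  dplyr::mutate(cohort,
                nosebleed_ml_month = vol,
                base_mg_day = base,
                extra_mg_day = extra,
                hair_mg_day = hair,
                log_hair = log(hair),
                total_intake_mg = total,
                shortfall_mg_day = hair - total,
                meets_rda = total >= base,
                meets_hair = total >= hair)
}

wald_prop_ci <- function(n_yes, n, z = 1.96) {
  p <- n_yes / n
  se <- sqrt(p * (1 - p) / n)
  c(max(0, p - z * se), min(1, p + z * se)) * 100
}

#' Cohort summary table
#'
#' Binary variables are reported as n, % and a Wald 95% CI (z = 1.96);
#' continuous variables as median, range and interquartile range. Derived
#' rows (nosebleed losses, extra requirement, HAIR, shortfall, proportions
#' meeting RDA/HAIR) are included when the derived columns are present
#' (see [add_hair()]).
#'
#' @param records a cohort tibble, ideally after [add_hair()].
#' @return a tibble with columns `variable`, `type`, `n`, `n_yes`,
#'   `percent`, `ci_low`, `ci_high` (binary rows) and `median`, `min`,
#'   `max`, `iqr_low`, `iqr_high` (continuous rows).
#' @export
summarize_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  rows <- list()
  bin_row <- function(variable, flag) {
    flag <- flag[!is.na(flag)]
    n <- length(flag); k <- sum(flag)
    ci <- wald_prop_ci(k, n)
    tibble::tibble(variable = variable, type = "binary", n = n, n_yes = k,
                   percent = 100 * k / n, ci_low = ci[1], ci_high = ci[2],
                   median = NA_real_, min = NA_real_, max = NA_real_,
                   iqr_low = NA_real_, iqr_high = NA_real_)
  }
  cont_row <- function(variable, x) {
    x <- x[!is.na(x)]
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    tibble::tibble(variable = variable, type = "continuous", n = length(x),
                   n_yes = NA_integer_, percent = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   median = q[2], min = min(x), max = max(x),
                   iqr_low = q[1], iqr_high = q[3])
  }
  has <- function(col) col %in% names(records)
  if (has("sex")) {
    rows <- c(rows, list(bin_row("male", records$sex == "male")))
    if (has("menstrual_status")) {
      rows <- c(rows, list(
        bin_row("postmenopausal_female",
                records$sex == "female" &
                  records$menstrual_status == "postmenopausal"),
        bin_row("premenopausal_female",
                records$sex == "female" &
                  records$menstrual_status == "premenopausal")))
    }
  }
  if (has("ess_gushing")) rows <- c(rows, list(bin_row("gushing",
                                                       records$ess_gushing)))
  if (has("uses_supplement")) {
    rows <- c(rows, list(bin_row("uses_supplement", records$uses_supplement)))
  }
  if (has("transfused")) {
    rows <- c(rows, list(bin_row("transfused", records$transfused)))
  }
  if (has("meets_rda")) rows <- c(rows, list(bin_row("meets_rda",
                                                     records$meets_rda)))
  if (has("meets_hair")) rows <- c(rows, list(bin_row("meets_hair",
                                                      records$meets_hair)))
  if (has("age")) rows <- c(rows, list(cont_row("age", records$age)))
  if (has("diet_intake_mg")) {
    rows <- c(rows, list(cont_row("diet_intake_mg", records$diet_intake_mg)))
  }
  for (col in c("nosebleed_ml_month", "extra_mg_day", "hair_mg_day",
                "shortfall_mg_day")) {
    if (has(col)) rows <- c(rows, list(cont_row(col, records[[col]])))
  }
  dplyr::bind_rows(rows)
}

#' One-dimensional natural-breaks classification
#'
#' Splits sorted values into `k` contiguous bins by cutting at the `k - 1`
#' largest gaps between adjacent sorted values ("naturally occurring breaks
#' between clusters"). Tied gap widths are broken by preferring the
#' lower-valued (earlier) cut. Bin sizes may be unequal.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of bins (default 5, approximate quintiles).
#' @return a list with `assignments` (integer bin index, 1 = lowest, per
#'   input value), `cut_gaps` (the gap widths cut at), and `bins` (a tibble
#'   with `bin`, `n`, `lower`, `upper` — the observed range of each bin).
#' @export
natural_breaks_quintiles <- function(values, k = 5) {
  stopifnot(is.numeric(values), k >= 2)
  if (length(unique(values)) < k) {
    stop("need at least k distinct values for k natural-breaks bins",
         call. = FALSE)
  }
  ord <- order(values)
  sorted <- values[ord]
  gaps <- diff(sorted)
  # largest gaps first; ties by earliest position
  cut_pos <- sort(head(order(-gaps, seq_along(gaps)), k - 1))
  bin_sorted <- cumsum(c(1L, as.integer(seq_along(gaps) %in% cut_pos)))
  assignments <- integer(length(values))
  assignments[ord] <- bin_sorted
  bins <- tibble::tibble(
    bin = seq_len(k),
    n = as.integer(tabulate(bin_sorted, k)),
    lower = vapply(seq_len(k), function(b) min(sorted[bin_sorted == b]),
                   numeric(1)),
    upper = vapply(seq_len(k), function(b) max(sorted[bin_sorted == b]),
                   numeric(1))
  )
  list(assignments = assignments, cut_gaps = gaps[cut_pos], bins = bins)
}

#' Quadratic regression of a hematinic index on HAIR
#'
#' Fits `transform(outcome) ~ HAIR + HAIR^2 + covariates` by least squares
#' and reports the linear HAIR-term coefficient with its 95% CI, the
#' adjusted R-squared, and the HAIR-term p-value. Covariates default to age
#' and sex; supplement use can be added to test the blunting of
#' HAIR-hematinic associations among supplement users.
#'
#' @param records a cohort tibble with `hair_mg_day` (see [add_hair()]).
#' @param outcome name of the outcome column (e.g. `"hb"`).
#' @param transform `"identity"` or `"ln"` (natural log).
#' @param covariates character vector of adjustment columns (default
#'   `c("age", "sex")`); use `character(0)` for an unadjusted fit.
#' @param include_supplement add `uses_supplement` to the covariates.
#' @return an object of class `hair_regression`: list with `coefficient`
#'   (linear HAIR term), `ci` (95%), `r_squared_adj`, `p_value`, `n`,
#'   `terms` (full coefficient tibble) and `model` (the `lm` fit).
#' @export
quadratic_hair_regression <- function(records, outcome,
                                      transform = c("identity", "ln"),
                                      covariates = c("age", "sex"),
                                      include_supplement = FALSE) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(records), "hair_mg_day" %in% names(records),
            outcome %in% names(records))
  if (include_supplement) {
    covariates <- union(covariates, "uses_supplement")
  }
  cols <- c(outcome, "hair_mg_day", covariates)
  df <- records[stats::complete.cases(records[cols]), cols, drop = FALSE]
  if (nrow(df) < 10L) {
    stop("outcome '", outcome, "' present in fewer than 10 records",
         call. = FALSE)
  }
  y <- df[[outcome]]
  if (sd(y) == 0) {
    stop("outcome '", outcome, "' has zero variance", call. = FALSE)
  }
  if (transform == "ln") {
    if (any(y <= 0)) {
      stop("ln transform requires positive outcome values", call. = FALSE)
    }
    y <- log(y)
  }
  dat <- data.frame(.y = y, hair = df$hair_mg_day,
                    hair_sq = df$hair_mg_day^2)
  for (cv in covariates) dat[[cv]] <- df[[cv]]
  fml <- stats::reformulate(c("hair", "hair_sq", covariates),
                            response = ".y")
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  smry <- summary(fit)
  ci <- confint(fit)
  terms_tbl <- tibble::tibble(
    term = rownames(smry$coefficients),
    estimate = smry$coefficients[, 1],
    ci_low = ci[, 1], ci_high = ci[, 2],
    p_value = smry$coefficients[, 4]
  )
  structure(list(
    coefficient = unname(coef(fit)["hair"]),
    ci = unname(ci["hair", ]),
    r_squared_adj = smry$adj.r.squared,
    p_value = smry$coefficients["hair", 4],
    n = nrow(dat),
    outcome = outcome, transform = transform,
    terms = terms_tbl, model = fit
  ), class = "hair_regression")
}

#' @export
print.hair_regression <- function(x, ...) {
  cat(sprintf(paste0("<hair_regression> %s(%s) on HAIR + HAIR^2 (n = %d)\n",
                     "  HAIR coefficient %.3g (95%% CI %.3g, %.3g), ",
                     "p = %.3g, adj R^2 = %.2f\n"),
              if (x$transform == "ln") "ln" else "", x$outcome, x$n,
              x$coefficient, x$ci[1], x$ci[2], x$p_value, x$r_squared_adj))
  invisible(x)
}

#' Choose identity or log transform by normal quantile-quantile fit
#'
#' Compares the correlation of the sample quantiles with normal quantiles
#' for the raw and natural-log-transformed values, and returns the
#' transform with the higher correlation. Non-positive values force the
#' identity transform (flagged).
#'
#' @param values numeric vector, length >= 4.
#' @return a list with `transform` (`"identity"` or `"ln"`), `diagnostics`
#'   (named QQ correlations), and `forced` (logical: ln was barred by
#'   non-positive values).
#' @export
transform_select <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 4)
  if (sd(values) == 0) {
    stop("constant sample; no transform can normalise it", call. = FALSE)
  }
  qq_cor <- function(x) cor(sort(x), qnorm(ppoints(length(x))))
  r_id <- qq_cor(values)
  if (any(values <= 0)) {
    return(list(transform = "identity",
                diagnostics = c(identity = r_id, ln = NA_real_),
                forced = TRUE))
  }
  r_ln <- qq_cor(log(values))
  list(transform = if (r_ln > r_id) "ln" else "identity",
       diagnostics = c(identity = r_id, ln = r_ln),
       forced = FALSE)
}

#' Nonparametric two-way comparison
#'
#' Rank-sum (Mann-Whitney) comparison of two groups, or Spearman rank
#' correlation of two paired continuous vectors. Exact p-values are used
#' for small samples without ties (delegated to `stats::wilcox.test` /
#' `stats::cor.test`), normal approximation otherwise.
#'
#' @param a,b numeric vectors; independent groups for `"rank_sum"`, paired
#'   vectors of equal length for `"rank_correlation"`.
#' @param method `"rank_sum"` or `"rank_correlation"`.
#' @return a list with `statistic`, `p_value`, `method`, `estimate`
#'   (Spearman rho, `NA` for rank-sum), and `degenerate` (all-tied data).
#' @export
nonparametric_compare <- function(a, b,
                                  method = c("rank_sum",
                                             "rank_correlation")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (method == "rank_sum") {
    if (length(unique(c(a, b))) == 1L) {
      return(list(statistic = NA_real_, p_value = 1, method = method,
                  estimate = NA_real_, degenerate = TRUE))
    }
    ht <- suppressWarnings(wilcox.test(a, b))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = method, estimate = NA_real_, degenerate = FALSE)
  } else {
    stopifnot(length(a) == length(b))
    if (sd(a) == 0 || sd(b) == 0) {
      return(list(statistic = NA_real_, p_value = NA_real_, method = method,
                  estimate = NA_real_, degenerate = TRUE))
    }
    ht <- suppressWarnings(cor.test(a, b, method = "spearman"))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = method, estimate = unname(ht$estimate),
         degenerate = FALSE)
  }
}

#' Backward stepwise logistic model of persistent anemia
#'
#' Fits a logistic regression of a binary outcome on the candidate
#' variables and removes the least significant variable (largest Wald p)
#' one at a time until every remaining variable has p <= `p_threshold`
#' (default 0.10). Variables causing complete or quasi-complete separation
#' are dropped with a warning. The final model is reported as odds ratios
#' with 95% CIs, z statistics, and both likelihood-ratio and Wald p-values.
#'
#' @param records a data frame.
#' @param outcome name of the binary (logical or 0/1) outcome column.
#' @param candidate_vars character vector of candidate predictor columns.
#' @param p_threshold retention threshold on the Wald p-value.
#' @return a list with `terms` (tibble: `variable`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `z`, `p_lr`, `p_wald`), `retained`, `removed`, `n`, and
#'   `model` (the final `glm`, or `NULL` when all candidates were removed).
#' @export
stepwise_logistic_anemia <- function(records, outcome, candidate_vars,
                                     p_threshold = 0.10) {
  stopifnot(is.data.frame(records), outcome %in% names(records),
            all(candidate_vars %in% names(records)))
  cols <- c(outcome, candidate_vars)
  df <- records[stats::complete.cases(records[cols]), cols, drop = FALSE]
  y <- df[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("outcome is constant; logistic model undefined", call. = FALSE)
  }
  df[[outcome]] <- y
  vars <- candidate_vars
  removed <- character(0)
  fit <- NULL
  repeat {
    if (length(vars) == 0L) { fit <- NULL; break }
    fml <- stats::reformulate(vars, response = outcome)
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      glm(fml, data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    cf <- summary(fit)$coefficients
    slope_rows <- setdiff(rownames(cf), "(Intercept)")
    var_of <- function(rn) vars[vapply(vars, function(v) startsWith(rn, v),
                                       logical(1))][1]
    if (sep_warn || any(abs(cf[slope_rows, 1]) > 15)) {
      worst <- slope_rows[which.max(abs(cf[slope_rows, 1]))]
      drop_var <- var_of(worst)
      warning("separation detected; dropping variable '", drop_var, "'",
              call. = FALSE)
      removed <- c(removed, drop_var)
      vars <- setdiff(vars, drop_var)
      next
    }
    pvals <- cf[slope_rows, 4]
    if (max(pvals) > p_threshold) {
      worst <- slope_rows[which.max(pvals)]
      drop_var <- var_of(worst)
      removed <- c(removed, drop_var)
      vars <- setdiff(vars, drop_var)
    } else break
  }
  if (is.null(fit) || length(vars) == 0L) {
    return(list(terms = tibble::tibble(variable = character(0),
                                       odds_ratio = numeric(0),
                                       ci_low = numeric(0),
                                       ci_high = numeric(0),
                                       z = numeric(0), p_lr = numeric(0),
                                       p_wald = numeric(0)),
                retained = character(0), removed = removed,
                n = nrow(df), model = NULL))
  }
  cf <- summary(fit)$coefficients
  slope_rows <- setdiff(rownames(cf), "(Intercept)")
  ci <- suppressMessages(stats::confint.default(fit))
  lr <- stats::drop1(fit, test = "Chisq")
  p_lr <- setNames(lr[["Pr(>Chi)"]], rownames(lr))
  terms_tbl <- tibble::tibble(
    variable = slope_rows,
    odds_ratio = exp(cf[slope_rows, 1]),
    ci_low = exp(ci[slope_rows, 1]),
    ci_high = exp(ci[slope_rows, 2]),
    z = cf[slope_rows, 3],
    p_lr = vapply(slope_rows, function(rn) {
      v <- vars[vapply(vars, function(v) startsWith(rn, v), logical(1))][1]
      unname(p_lr[v])
    }, numeric(1)),
    p_wald = cf[slope_rows, 4]
  )
  list(terms = terms_tbl, retained = vars, removed = removed,
       n = nrow(df), model = fit)
}
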