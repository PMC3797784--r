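# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written from first principles, sharing no
# code with the functions they verify.

# Percentile by sorting and linear interpolation between order statistics:
# the p-th percentile sits at fractional index h = (n - 1) p + 1 of the
# sorted sample.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# Exhaustive-search natural-breaks partitioner: enumerate every set of
# k - 1 cut positions between adjacent sorted values, score each by the
# vector of cut-gap widths sorted in decreasing order (compared
# lexicographically, so the winner cuts at the largest gaps), and break
# remaining ties by the lexicographically smallest cut-position set.
oracle_natural_breaks <- function(values, k) {
  sorted <- sort(values)
  gaps <- diff(sorted)
  cut_sets <- utils::combn(seq_along(gaps), k - 1, simplify = FALSE)
  better <- function(a, b) { # is cut set a better than b?
    ga <- sort(gaps[a], decreasing = TRUE)
    gb <- sort(gaps[b], decreasing = TRUE)
    for (i in seq_along(ga)) {
      if (ga[i] != gb[i]) return(ga[i] > gb[i])
    }
    for (i in seq_along(a)) {
      if (a[i] != b[i]) return(a[i] < b[i])
    }
    FALSE
  }
  best <- cut_sets[[1]]
  for (cs in cut_sets[-1]) {
    if (better(cs, best)) best <- cs
  }
  bin_sorted <- cumsum(c(1L, as.integer(seq_along(gaps) %in% best)))
  assignments <- integer(length(values))
  assignments[order(values)] <- bin_sorted
  list(cuts = best, assignments = assignments)
}

# Exact two-sided Mann-Whitney p-value by complete enumeration of all
# assignments of the pooled ranks to group A.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(length(pooled), na, simplify = FALSE)
  w_all <- vapply(sets, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  }, numeric(1))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Small deterministic hand-built cohort used across cohort-level tests.
make_mini_cohort <- function() {
  tibble::tibble(
    subject_id = 1:6,
    age = c(44, 60, 35, 70, 52, 28),
    sex = c("male", "female", "female", "male", "female", "female"),
    menstrual_status = c("not_applicable", "postmenopausal", "premenopausal",
                         "not_applicable", "postmenopausal", "premenopausal"),
    ess_frequency = c("several_per_day", "weekly", "lt_monthly", "daily",
                      "monthly", "several_per_week"),
    ess_duration = c("16_30", "1_5", "lt_1", "6_15", "1_5", "6_15"),
    ess_gushing = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    diet_intake_mg = c(12, 10, 9, 14, 11, 8),
    supplement_elemental_mg = c(0, 40, 0, 0, 130, 0),
    uses_supplement = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    transfused = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}
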