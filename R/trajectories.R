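#' z-transform a numeric vector
#'
#' Centers to mean 0 and scales to SD 1 (denominator `n - 1`). Missing
#' values are ignored in the moments and propagate through the output.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return Standardized vector.
#' @export
z_transform <- function(x) {
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 2L) {
    stop("z_transform(): need at least 2 distinct non-missing values")
  }
  s <- sd(obs)
  if (s == 0) stop("z_transform(): zero variance")
  (x - mean(obs)) / s
}

#' Lifetime rank-trajectory components
#'
#' Summarizes each male's daily score series into six trajectory
#' components, with per-component eligibility following the study's
#' inclusion rules:
#'
#' * `entry_cardinal` — cardinal score on the hierarchy-entry date
#'   (eligible if the male entered at age 12, i.e. entry age in `[12, 13)`);
#' * `rise_slope` — cardinal change per year from entry to the first day
#'   at his lifetime-best ordinal rank (same eligibility; inapplicable for
#'   males who never improved on their entry-day ordinal rank);
#' * `peak_cardinal` — maximum cardinal achieved (eligible with rank data
#'   to at least age 26);
#' * `best_ordinal` — minimum ordinal achieved, 1 = alpha (same
#'   eligibility);
#' * `top_tenure_days` — days between first and last day at the best
#'   ordinal (eligible if best ordinal <= 3, entry before age 16, and data
#'   to at least age 26);
#' * `decline_slope` — cardinal change per year over the 2 years after the
#'   last day at the best ordinal (eligible with >= 2 years of data past
#'   that day).
#'
#' @param daily Daily series from [daily_scores()] (needs `cardinal` and
#'   `ordinal`).
#' @param roster Roster data frame (for birth dates).
#' @param min_age_peak Minimum age (years) to which rank data must extend
#'   for peak/best-ordinal/tenure eligibility (default 26).
#' @return One row per male: components, per-component `elig_*` logicals
#'   and an `ineligibility_reasons` note.
#' @export
extract_components <- function(daily, roster, min_age_peak = 26) {
  birth <- setNames(roster$birth_date, roster$male_id)
  per_male <- lapply(split(daily, daily$male_id), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    id <- d$male_id[1]
    entry_date <- d$date[1]
    last_date <- d$date[nrow(d)]
    entry_age <- age_on(birth[[id]], entry_date)
    last_age <- age_on(birth[[id]], last_date)
    entry_cardinal <- d$cardinal[1]
    peak_cardinal <- suppressWarnings(max(d$cardinal, na.rm = TRUE))
    if (!is.finite(peak_cardinal)) peak_cardinal <- NA_real_
    has_ord <- !is.na(d$ordinal)
    best_ordinal <- if (any(has_ord)) min(d$ordinal[has_ord]) else NA_integer_
    reasons <- character()

    rise_slope <- NA_real_
    top_tenure_days <- NA_real_
    decline_slope <- NA_real_
    first_best <- last_best <- as.Date(NA)
    if (!is.na(best_ordinal)) {
      at_best <- d$date[has_ord & d$ordinal == best_ordinal]
      first_best <- min(at_best)
      last_best <- max(at_best)
      top_tenure_days <- as.numeric(last_best - first_best)
      if (first_best > entry_date) {
        dt_years <- as.numeric(first_best - entry_date) / 365.25
        c_best <- d$cardinal[d$date == first_best]
        rise_slope <- (c_best - entry_cardinal) / dt_years
      } else {
        reasons <- c(reasons, "rise: never improved on entry-day ordinal rank")
      }
      horizon <- last_best + 730
      if (last_date >= horizon) {
        c_start <- d$cardinal[d$date == last_best]
        c_end <- d$cardinal[d$date == horizon]
        if (length(c_end) == 1L) {
          decline_slope <- (c_end - c_start) / 2
        }
      }
    }

    elig_entry <- entry_age >= 12 && entry_age < 13
    elig_rise <- elig_entry && !is.na(rise_slope)
    if (!elig_entry) reasons <- c(reasons, "entry/rise: did not enter at age 12")
    elig_peak <- last_age >= min_age_peak
    if (!elig_peak) {
      reasons <- c(reasons,
                   sprintf("peak/best: rank data end before age %g", min_age_peak))
    }
    elig_tenure <- elig_peak && !is.na(best_ordinal) && best_ordinal <= 3 &&
      entry_age < 16
    if (!elig_tenure) reasons <- c(reasons, "tenure: criteria not met")
    elig_decline <- !is.na(last_best) &&
      as.numeric(last_date - last_best) >= 730
    if (!elig_decline) {
      reasons <- c(reasons, "decline: < 2 years of data past last best day")
    }

    data.frame(male_id = id, entry_date = entry_date, entry_age = entry_age,
               last_age = last_age, entry_cardinal = entry_cardinal,
               rise_slope = rise_slope, peak_cardinal = peak_cardinal,
               best_ordinal = best_ordinal,
               first_best_date = first_best, last_best_date = last_best,
               top_tenure_days = top_tenure_days,
               decline_slope = decline_slope,
               elig_entry = elig_entry, elig_rise = elig_rise,
               elig_peak = elig_peak, elig_best = elig_peak,
               elig_tenure = elig_tenure, elig_decline = elig_decline,
               ineligibility_reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_male)
  rownames(out) <- NULL
  out
}

#' Bivariate validation regression of a trajectory component on a trait
#'
#' Ordinary least-squares regression of a trajectory component on a
#' z-transformed personality trait, with a normal-theory 95% confidence
#' interval on the slope. The trait is standardized over `z_sample`
#' (by default the full supplied trait vector, i.e. the full rated male
#' sample), then the regression uses the paired complete observations
#' after sensitivity exclusions.
#'
#' @param component Named numeric vector (male_id -> component value).
#' @param trait Named numeric vector of raw trait scores.
#' @param exclude Character vector of male ids to drop (sensitivity
#'   exclusions such as the injured male).
#' @param z_sample Numeric vector defining the standardization sample for
#'   the trait (default `trait`).
#' @param conf_level Confidence level (default 0.95).
#' @return A `regression_result`: `beta`, `ci_low`, `ci_high`, `n`,
#'   `excluded_ids`, `p_value`.
#' @export
validate_component <- function(component, trait, exclude = character(),
                               z_sample = trait, conf_level = 0.95) {
  trait_z <- (trait - mean(z_sample, na.rm = TRUE)) / sd(z_sample, na.rm = TRUE)
  ids <- intersect(names(component), names(trait_z))
  ids <- setdiff(ids, exclude)
  y <- component[ids]
  x <- trait_z[ids]
  keep <- !is.na(y) & !is.na(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3L) {
    stop("validate_component(): fewer than 3 paired complete observations")
  }
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, "x", level = conf_level))
  p <- suppressWarnings(summary(fit)$coefficients["x", "Pr(>|t|)"])
  structure(list(beta = unname(coef(fit)[["x"]]),
                 ci_low = ci[1], ci_high = ci[2],
                 n = length(y),
                 excluded_ids = exclude,
                 p_value = p),
            class = "regression_result")
}

#' @exportS3Method base::print
print.regression_result <- function(x, ...) {
  cat(sprintf("beta = %.4f, 95%% CI [%.4f, %.4f], n = %d\n",
              x$beta, x$ci_low, x$ci_high, x$n))
  if (length(x$excluded_ids)) {
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}
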