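#' Estimated siring date
#'
#' Conception is dated by subtracting the population mean gestation length
#' for singleton births (228 days) from the offspring's date of birth.
#'
#' @param birth_date `Date` vector of offspring birth dates.
#' @param gestation_days Mean gestation length in days (default 228).
#' @return `Date` vector of estimated siring dates.
#' @export
siring_date <- function(birth_date, gestation_days = 228) {
  as.Date(birth_date) - gestation_days
}

#' Assemble candidate-sire risk sets
#'
#' For each siring event (offspring with known sire), builds one row per
#' candidate sire: males at least `min_age` years old on the estimated
#' siring date with a cardinal score that day, trait scores, and a
#' relatedness value to the mother (dyads with missing relatedness are
#' excluded). Age and cardinal score are z-transformed across the
#' retained rows; trait z-scores are computed across the male trait
#' sample (one score per male, reused over events).
#'
#' @param paternities Paternity data frame (`offspring_id`, `birth_date`,
#'   `mother_id`, `sire_id`).
#' @param roster Roster data frame.
#' @param daily Daily series from [daily_scores()].
#' @param relatedness Data frame `mother_id`, `male_id`, `r_value`.
#' @param traits Trait-score data frame from [score_traits()].
#' @param min_age Minimum candidate age in years on the siring date
#'   (default 11).
#' @param gestation_days See [siring_date()].
#' @return Risk-set data frame: `event_id`, `male_id`, `sired`, `age`,
#'   `age_z`, `cardinal`, `elo_z`, `relatedness`, and `<trait>_z` columns.
#'   An event whose recorded sire fails the candidacy filters raises an
#'   integrity error.
#' @export
assemble_risk_sets <- function(paternities, roster, daily, relatedness,
                               traits, min_age = 11, gestation_days = 228) {
  birth <- setNames(roster$birth_date, roster$male_id)
  rel_key <- setNames(relatedness$r_value,
                      paste(relatedness$mother_id, relatedness$male_id))
  daily_key <- paste(daily$male_id, daily$date)
  rated <- traits$male_id

  rows <- lapply(seq_len(nrow(paternities)), function(i) {
    ev <- paternities[i, ]
    sdate <- siring_date(ev$birth_date, gestation_days)
    day <- daily[daily$date == sdate & !is.na(daily$cardinal), , drop = FALSE]
    cand <- day$male_id[age_on(birth[day$male_id], sdate) >= min_age]
    cand <- intersect(cand, rated)
    r <- rel_key[paste(ev$mother_id, cand)]
    cand <- cand[!is.na(r)]
    if (!ev$sire_id %in% cand) {
      stop(sprintf(
        "assemble_risk_sets(): recorded sire '%s' of offspring '%s' fails the candidacy filters",
        ev$sire_id, ev$offspring_id))
    }
    data.frame(event_id = ev$offspring_id,
               male_id = cand,
               sired = as.integer(cand == ev$sire_id),
               age = age_on(birth[cand], sdate),
               cardinal = day$cardinal[match(cand, day$male_id)],
               relatedness = unname(rel_key[paste(ev$mother_id, cand)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$age_z <- z_transform(out$age)
  out$elo_z <- z_transform(out$cardinal)
  ti <- match(out$male_id, traits$male_id)
  for (tr in intersect(trait_names(), names(traits))) {
    out[[paste0(tolower(tr), "_z")]] <- z_transform(traits[[tr]])[ti]
  }
  rownames(out) <- NULL
  out
}

#' Binomial mixed model of siring success
#'
#' Logit-link binomial GLMM with the sired indicator as outcome and a
#' random intercept for male identity, fit by maximum likelihood with the
#' Laplace approximation ([lme4::glmer()]). Reports odds ratios
#' (exponentiated coefficients) with Wald 95% confidence intervals.
#'
#' @param rows Risk-set data frame from [assemble_risk_sets()].
#' @param terms Character vector of fixed-effect terms, e.g.
#'   `c("age_z", "elo_z", "relatedness", "dominance_z",
#'   "I(dominance_z^2)")`.
#' @param random_intercept If `FALSE`, drops the random intercept and
#'   fits a plain logistic regression (the zero-variance degenerate
#'   case).
#' @return A `glmm_fit`: `model`, `fixed` (data frame of estimates, odds
#'   ratios, CI bounds, p-values), `re_variance`, `loglik`, `df`,
#'   `n_rows`, `n_events`, `converged`, `formula`.
#' @export
fit_siring_glmm <- function(rows, terms, random_intercept = TRUE) {
  if (length(unique(rows$event_id)) < 2L) {
    stop("fit_siring_glmm(): need at least 2 siring events")
  }
  rhs <- paste(terms, collapse = " + ")
  if (random_intercept) {
    fml <- as.formula(paste("sired ~", rhs, "+ (1 | male_id)"))
    model <- suppressMessages(
      lme4::glmer(fml, data = rows, family = stats::binomial()))
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(vcov(model))))
    re_var <- as.numeric(lme4::VarCorr(model)$male_id[1])
    conv <- length(model@optinfo$conv$lme4) == 0L
  } else {
    fml <- as.formula(paste("sired ~", rhs))
    model <- stats::glm(fml, data = rows, family = stats::binomial())
    est <- coef(model)
    se <- sqrt(diag(vcov(model)))
    re_var <- 0
    conv <- model$converged
  }
  z <- qnorm(0.975)
  fixed <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    odds_ratio = exp(unname(est)),
    or_ci_low = exp(unname(est) - z * unname(se)),
    or_ci_high = exp(unname(est) + z * unname(se)),
    p_value = 2 * stats::pnorm(-abs(unname(est) / unname(se))),
    stringsAsFactors = FALSE)
  ll <- logLik(model)
  structure(list(model = model, fixed = fixed, re_variance = re_var,
                 loglik = as.numeric(ll), df = attr(ll, "df"),
                 n_rows = nrow(rows),
                 n_events = length(unique(rows$event_id)),
                 converged = conv, formula = fml),
            class = "glmm_fit")
}

#' @exportS3Method base::print
print.glmm_fit <- function(x, ...) {
  cat("binomial GLMM of siring success\n")
  cat(sprintf("  %d rows, %d events; RE variance (male) = %.4f\n",
              x$n_rows, x$n_events, x$re_variance))
  df <- x$fixed
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-22s OR %6.2f [%5.2f, %5.2f]  p = %.3f\n",
                df$term[i], df$odds_ratio[i], df$or_ci_low[i],
                df$or_ci_high[i], df$p_value[i]))
  }
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 * loglik + 2p + 2p(p + 1) / (n - p - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param p Number of estimated parameters.
#' @param n Number of observations (Bernoulli candidate rows).
#' @return AICc value.
#' @export
aicc <- function(loglik, p, n) {
  -2 * loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' The 14-model siring success family
#'
#' Named list of fixed-effect term sets. The base model holds male age,
#' cardinal score on the siring date, and relatedness to the mother; the
#' other models add Dominance and/or Conscientiousness terms, their
#' squares, and interactions with age or cardinal score, plus one model
#' with all six traits.
#'
#' @return Named list of character vectors of model terms.
#' @export
siring_model_family <- function() {
  base <- c("age_z", "elo_z", "relatedness")
  all_traits <- paste0(tolower(trait_names()), "_z")
  list(
    "base" = base,
    "base + Dominance" = c(base, "dominance_z"),
    "base + Dominance + Dominance^2" =
      c(base, "dominance_z", "I(dominance_z^2)"),
    "base + Dominance x Age" = c(base, "dominance_z", "dominance_z:age_z"),
    "base + Dominance x Age + Dominance^2" =
      c(base, "dominance_z", "dominance_z:age_z", "I(dominance_z^2)"),
    "base + Dominance x Age + Dominance^2 x Age" =
      c(base, "dominance_z", "dominance_z:age_z", "I(dominance_z^2)",
        "I(dominance_z^2):age_z"),
    "base + Dominance x Elo" = c(base, "dominance_z", "dominance_z:elo_z"),
    "base + Conscientiousness" = c(base, "conscientiousness_z"),
    "base + Conscientiousness + Conscientiousness^2" =
      c(base, "conscientiousness_z", "I(conscientiousness_z^2)"),
    "base + Conscientiousness x Age" =
      c(base, "conscientiousness_z", "conscientiousness_z:age_z"),
    "base + Conscientiousness x Age + Conscientiousness^2" =
      c(base, "conscientiousness_z", "conscientiousness_z:age_z",
        "I(conscientiousness_z^2)"),
    "base + Conscientiousness x Elo" =
      c(base, "conscientiousness_z", "conscientiousness_z:elo_z"),
    "base + Dominance + Conscientiousness" =
      c(base, "dominance_z", "conscientiousness_z"),
    "base + all six traits" = c(base, all_traits)
  )
}

#' AICc model comparison with Akaike weights
#'
#' Fits every model in the family on identical rows and tabulates AICc,
#' `delta_i = AICc_i - AICc_best >= 0`, and Akaike weights
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. The sample size in
#' the small-sample correction is the number of candidate rows.
#'
#' @inheritParams fit_siring_glmm
#' @param family Named list of term sets (default
#'   [siring_model_family()]).
#' @return An `aicc_table` data frame sorted by AICc ascending: `model`,
#'   `df`, `AICc`, `delta`, `weight`; fitted models in
#'   `attr(, "fits")`.
#' @export
aicc_compare <- function(rows, family = siring_model_family(),
                         random_intercept = TRUE) {
  vars <- unique(unlist(lapply(family, function(t) all.vars(as.formula(
    paste("~", paste(t, collapse = "+")))))))
  if (anyNA(rows[, intersect(vars, names(rows))])) {
    stop("aicc_compare(): missing values would give models different row sets")
  }
  n <- nrow(rows)
  fits <- lapply(family, function(terms) {
    fit_siring_glmm(rows, terms, random_intercept = random_intercept)
  })
  tab <- data.frame(
    model = names(family),
    df = vapply(fits, function(f) as.numeric(f$df), numeric(1)),
    AICc = vapply(fits, function(f) aicc(f$loglik, f$df, n), numeric(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$delta <- tab$AICc - tab$AICc[1]
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  rownames(tab) <- NULL
  structure(tab, fits = fits[tab$model], class = c("aicc_table",
                                                   "data.frame"))
}
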