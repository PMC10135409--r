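trait_names <- function() {
  c("Dominance", "Extraversion", "Conscientiousness", "Agreeableness",
    "Neuroticism", "Openness")
}

#' Assemble the male-day modeling table
#'
#' Joins the daily cardinal score series with per-male trait scores and
#' ages, z-transforming age, traits and the cardinal outcome over the
#' table rows. Male-days without a cardinal score (singleton days) and
#' males lacking trait scores are excluded (the latter with a warning).
#'
#' @param daily Daily series from [daily_scores()].
#' @param traits Trait-score data frame from [score_traits()].
#' @param roster Roster data frame.
#' @return Data frame with `male_id` (factor), `date`, `age`, `cardinal`,
#'   `age_z`, `elo_z`, and one `<trait>_z` column per trait.
#' @export
build_rank_table <- function(daily, traits, roster) {
  daily <- daily[!is.na(daily$cardinal), , drop = FALSE]
  missing <- setdiff(unique(daily$male_id), traits$male_id)
  if (length(missing)) {
    warning("build_rank_table(): no trait scores for ",
            paste(missing, collapse = ", "), "; excluded")
    daily <- daily[!daily$male_id %in% missing, , drop = FALSE]
  }
  birth <- setNames(roster$birth_date, roster$male_id)
  tab <- data.frame(
    male_id = factor(daily$male_id),
    date = daily$date,
    age = age_on(birth[daily$male_id], daily$date),
    cardinal = daily$cardinal,
    stringsAsFactors = FALSE)
  tab$age_z <- z_transform(tab$age)
  tab$elo_z <- z_transform(tab$cardinal)
  ti <- match(as.character(tab$male_id), traits$male_id)
  for (tr in intersect(trait_names(), names(traits))) {
    tab[[paste0(tolower(tr), "_z")]] <- z_transform(traits[[tr]][ti])
  }
  rownames(tab) <- NULL
  tab
}

#' Specification of one model in the rank GAMM suite
#'
#' The suite comprises six nested models of z-transformed daily cardinal
#' score: (1) age only; (2) age + Dominance + age x Dominance; (3) age +
#' Conscientiousness + its age interaction; (4) both traits; (5) all six
#' traits; (6) model 5 plus a random effect for date. Fixed effects are
#' tensor-product interaction (`ti`) smooths with shrinkage cubic
#' regression spline bases so a term's effective degrees of freedom can
#' shrink to zero; random effects are ridge-penalized (`bs = "re"`)
#' per-male intercepts and slopes for age and each trait in the model.
#'
#' @param model Integer 1-6.
#' @param k_main Marginal basis dimension for main-effect smooths
#'   (default 5, giving reference df 4 after identifiability constraints;
#'   interactions get `k_main^2` marginals, reference df 16).
#' @return A `gamm_spec` with the model index, trait list and formula.
#' @export
gamm_spec <- function(model, k_main = 5) {
  stopifnot(model %in% 1:6)
  traits <- switch(model,
    character(0),
    "Dominance",
    "Conscientiousness",
    c("Dominance", "Conscientiousness"),
    trait_names(),
    trait_names())
  spec <- structure(list(model = model, traits = traits, k_main = k_main),
                    class = "gamm_spec")
  parts <- gamm_formula_parts(spec)
  spec$formula <- as.formula(
    paste("elo_z ~", paste(c(parts$fixed, parts$random), collapse = " + ")))
  spec$random_labels <- parts$random
  spec
}

# formula construction; when a table is supplied, marginal basis
# dimensions are clamped to the number of distinct covariate values so
# subset fits (cross-validation folds) remain well defined
gamm_formula_parts <- function(spec, table = NULL) {
  k_main <- spec$k_main
  tz <- if (length(spec$traits)) {
    paste0(tolower(spec$traits), "_z")
  } else character(0)
  k_of <- function(v) {
    if (is.null(table)) return(k_main)
    max(3L, min(k_main, length(unique(table[[v]]))))
  }
  usable <- if (is.null(table)) tz else {
    tz[vapply(tz, function(v) length(unique(table[[v]])) >= 3L, logical(1))]
  }
  k_age <- k_of("age_z")
  fixed <- c(sprintf("ti(age_z, bs = 'cs', k = %d)", k_age),
             vapply(usable, function(v) {
               sprintf("ti(%s, bs = 'cs', k = %d)", v, k_of(v))
             }, character(1)),
             vapply(usable, function(v) {
               sprintf("ti(age_z, %s, bs = c('cs', 'cs'), k = c(%d, %d))",
                       v, k_age, k_of(v))
             }, character(1)))
  random <- c("s(male_id, bs = 're')",
              "s(age_z, male_id, bs = 're')",
              if (length(tz)) sprintf("s(%s, male_id, bs = 're')", tz))
  if (spec$model == 6L) random <- c(random, "s(date_f, bs = 're')")
  list(fixed = unname(fixed), random = random)
}

#' Fit one rank GAMM
#'
#' Penalized-spline fit with smoothness selected by restricted maximum
#' likelihood (REML) via [mgcv::gam()], Gaussian likelihood on the
#' z-transformed cardinal outcome. Deterministic given data and spec.
#'
#' @param table Modeling table from [build_rank_table()].
#' @param spec A [gamm_spec()].
#' @return A `gamm_fit`: the mgcv fit plus `term_table` (per-term edf,
#'   reference df, test statistic, approximate p), `deviance`,
#'   `deviance_explained`, `adjusted_r2`, `reml`, `total_edf`, `n_obs`,
#'   `converged`. Non-convergence of smoothing-parameter selection is
#'   flagged, not raised.
#' @param engine `"gam"` (exact REML, default) or `"bam"` (fast fitting
#'   for large tables, fREML criterion with discretized covariates).
#' @export
fit_gamm <- function(table, spec, engine = c("gam", "bam")) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "gamm_spec"), nrow(table) > 0)
  if (spec$model == 6L) table$date_f <- factor(table$date)
  parts <- gamm_formula_parts(spec, table)
  fml <- as.formula(
    paste("elo_z ~", paste(c(parts$fixed, parts$random), collapse = " + ")))
  environment(fml) <- environment()
  fit <- if (engine == "bam") {
    mgcv::bam(fml, data = table, method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(fml, data = table, method = "REML")
  }
  sm <- summary(fit)
  term_table <- as.data.frame(sm$s.table)
  names(term_table) <- c("edf", "ref_df", "statistic", "p_value")
  term_table$term <- rownames(sm$s.table)
  rownames(term_table) <- NULL
  structure(list(
    spec = spec,
    fit = fit,
    term_table = term_table[, c("term", "edf", "ref_df", "statistic",
                                "p_value")],
    deviance = deviance(fit),
    deviance_explained = sm$dev.expl,
    adjusted_r2 = sm$r.sq,
    reml = as.numeric(fit$gcv.ubre),
    total_edf = sum(fit$edf) + fit$nsdf,
    n_obs = nrow(table),
    converged = isTRUE(fit$converged)
  ), class = "gamm_fit")
}

#' @exportS3Method base::print
print.gamm_fit <- function(x, ...) {
  cat(sprintf("rank GAMM (model %d): n = %d\n", x$spec$model, x$n_obs))
  cat(sprintf("  deviance explained = %.1f%%, adjusted R2 = %.1f%%\n",
              100 * x$deviance_explained, 100 * x$adjusted_r2))
  cat(sprintf("  REML = %.2f, total edf = %.2f, converged: %s\n",
              x$reml, x$total_edf, x$converged))
  invisible(x)
}

#' Compare two nested REML fits
#'
#' Chi-square test of twice the absolute difference in the minimized REML
#' criterion, on degrees of freedom equal to the difference in total
#' effective degrees of freedom. The comparison is approximate and
#' requires nested specs fit to identical data.
#'
#' @param fit_a,fit_b `gamm_fit` objects on the same rows (`fit_b` the
#'   richer model).
#' @return List: `statistic`, `df`, `p_value`.
#' @export
reml_compare <- function(fit_a, fit_b) {
  if (fit_a$n_obs != fit_b$n_obs) {
    stop("reml_compare(): fits use different numbers of observations")
  }
  statistic <- 2 * abs(fit_a$reml - fit_b$reml)
  df <- abs(fit_b$total_edf - fit_a$total_edf)
  p <- if (statistic == 0) 1 else pchisq(statistic, df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p_value = p)
}

# predict handling males unseen in training: their rows are predicted at
# the population level (all random-effect smooths excluded). Continuous
# covariates are clamped to the training support: cubic splines
# extrapolate linearly at best and tensor products can diverge, so
# out-of-support predictions are evaluated at the nearest supported value.
predict_gamm <- function(fit, spec, newdata, train) {
  train_males <- unique(as.character(train$male_id))
  for (v in grep("_z$", names(newdata), value = TRUE)) {
    if (v %in% names(train)) {
      rng <- range(train[[v]], na.rm = TRUE)
      newdata[[v]] <- pmin(pmax(newdata[[v]], rng[1]), rng[2])
    }
  }
  if (spec$model == 6L) newdata$date_f <- factor(newdata$date)
  known <- as.character(newdata$male_id) %in% train_males
  out <- numeric(nrow(newdata))
  if (any(known)) {
    out[known] <- as.numeric(predict(fit, newdata[known, , drop = FALSE],
                                     discrete = FALSE))
  }
  if (any(!known)) {
    nd <- newdata[!known, , drop = FALSE]
    nd$male_id <- factor(train_males[1], levels = levels(newdata$male_id))
    if (spec$model == 6L) nd$date_f <- factor(levels(factor(newdata$date))[1])
    labels <- vapply(fit$smooth, function(s) s$label, character(1))
    re <- labels[grepl("male_id|date_f", labels)]
    out[!known] <- as.numeric(predict(fit, nd, exclude = re,
                                      newdata.guaranteed = TRUE,
                                      discrete = FALSE))
  }
  # the outcome is a z-scored bounded score; spline surfaces can diverge
  # in unoccupied corners of the covariate box, so forecasts are bounded
  # by the training outcome range (with a small margin)
  bound <- range(train$elo_z, na.rm = TRUE)
  pmin(pmax(out, bound[1] - 0.5), bound[2] + 0.5)
}

#' Cross-validate a rank GAMM
#'
#' Two schemes. `"stratified"`: each male's rows are randomly partitioned
#' into `k_folds` folds (stratified by male, seeded); each fold is
#' predicted from a model trained on the others. `"forward"`: rows are
#' ordered by date and cut into `k_folds` sequential blocks; the model is
#' trained on blocks `1..m` and predicts block `m + 1`, for
#' `m = 1..k_folds-1`, so every prediction uses only past data. Males not
#' yet seen in the training window are predicted at the population level.
#'
#' @inheritParams fit_gamm
#' @param scheme `"stratified"` or `"forward"`.
#' @param k_folds Number of folds/blocks (default 10).
#' @param seed Integer seed for the stratified partition.
#' @return A `cv_result`: `scheme`, per-fold `fold_mse` in squared
#'   cardinal units (the z-scale prediction errors are mapped back
#'   through the table's cardinal SD), overall `mse` (mean of fold MSEs),
#'   `mse_z` (same on the z scale), `seed`, and `fold_index` (the
#'   fold/block of each row, in input row order).
#' @export
cross_validate <- function(table, spec, scheme = c("stratified", "forward"),
                           k_folds = 10, seed = 1,
                           engine = c("gam", "bam")) {
  engine <- match.arg(engine)
  scheme <- match.arg(scheme)
  n <- nrow(table)
  fold <- integer(n)
  if (scheme == "stratified") {
    small <- table(table$male_id)
    if (any(small < k_folds)) {
      warning("cross_validate(): male(s) with fewer rows than folds; ",
              "their rows are pooled into folds")
    }
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    for (rows in split(seq_len(n), table$male_id)) {
      fold[rows] <- sample(rep_len(seq_len(k_folds), length(rows)))
    }
    fold_mse <- vapply(seq_len(k_folds), function(f) {
      train <- table[fold != f, , drop = FALSE]
      test <- table[fold == f, , drop = FALSE]
      m <- fit_gamm(train, spec, engine = engine)
      pred <- predict_gamm(m$fit, spec, test, train)
      mean((test$elo_z - pred)^2)
    }, numeric(1))
  } else {
    # sequential blocks of (near-)equal size in date order
    ord <- order(as.numeric(table$date))
    fold[ord] <- as.integer(cut(seq_len(n), breaks = k_folds, labels = FALSE))
    fold_mse <- vapply(seq_len(k_folds - 1L), function(m_) {
      train <- table[fold <= m_, , drop = FALSE]
      test <- table[fold == m_ + 1L, , drop = FALSE]
      m <- fit_gamm(train, spec, engine = engine)
      pred <- predict_gamm(m$fit, spec, test, train)
      mean((test$elo_z - pred)^2)
    }, numeric(1))
  }
  card_var <- if ("cardinal" %in% names(table)) {
    var(table$cardinal, na.rm = TRUE)
  } else 1
  if (!is.finite(card_var)) card_var <- 1
  structure(list(scheme = scheme, fold_mse = fold_mse * card_var,
                 mse = mean(fold_mse) * card_var, mse_z = mean(fold_mse),
                 seed = seed, fold_index = fold,
                 date = table$date),
            class = "cv_result")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing design column j on the other
#' columns. Exact collinearity yields `Inf`.
#'
#' @param design Numeric data frame or matrix (>= 2 columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  stopifnot(ncol(design) >= 2L)
  vapply(names(design), function(col) {
    fit <- lm(as.formula(paste0("`", col, "` ~ .")), data = design)
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}
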