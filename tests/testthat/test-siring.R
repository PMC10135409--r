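test_that("siring dates subtract the mean gestation length", {
  expect_equal(siring_date(as.Date("2000-01-01")), as.Date("1999-05-18"))
  expect_equal(siring_date(as.Date("2000-01-01"), gestation_days = 1),
               as.Date("1999-12-31"))
})

risk_fixture <- function() {
  if (is.null(.sim_cache[["risk"]])) {
    sim <- small_sim()
    b <- sim$bundle
    fit <- fit_ml_elo(b$interactions)
    daily <- daily_scores(fit$params, b$interactions, b$roster)
    traits <- score_traits(b$ratings)
    rows <- assemble_risk_sets(b$paternities, b$roster, daily,
                               b$relatedness, traits)
    .sim_cache[["risk"]] <- list(sim = sim, daily = daily, traits = traits,
                                 rows = rows)
  }
  .sim_cache[["risk"]]
}

test_that("risk sets have exactly one sire per event and valid candidates", {
  fx <- risk_fixture()
  rows <- fx$rows
  sired <- tapply(rows$sired, rows$event_id, sum)
  expect_true(all(sired == 1L))
  expect_true(all(rows$age >= 11))
  expect_equal(mean(rows$age_z), 0, tolerance = 1e-10)
  expect_equal(sd(rows$elo_z), 1, tolerance = 1e-10)
  expect_false(anyNA(rows$relatedness))
})

test_that("risk-set membership equals a row-wise brute-force filter", {
  fx <- risk_fixture()
  b <- fx$sim$bundle
  daily <- fx$daily
  rows <- fx$rows
  ev <- b$paternities[3, ]
  sdate <- ev$birth_date - 228
  birth <- setNames(b$roster$birth_date, b$roster$male_id)
  day <- daily[daily$date == sdate & !is.na(daily$cardinal), ]
  oracle <- character(0)
  for (id in day$male_id) {
    age <- as.numeric(sdate - birth[[id]]) / 365.25
    r <- b$relatedness$r_value[b$relatedness$mother_id == ev$mother_id &
                                 b$relatedness$male_id == id]
    if (age >= 11 && id %in% fx$traits$male_id && length(r) == 1) {
      oracle <- c(oracle, id)
    }
  }
  got <- rows$male_id[rows$event_id == ev$offspring_id]
  expect_setequal(got, oracle)
})

test_that("an ineligible recorded sire raises an integrity error", {
  fx <- risk_fixture()
  b <- fx$sim$bundle
  pat <- b$paternities
  pat$sire_id[1] <- setdiff(b$roster$male_id, pat$sire_id[1])[1]
  rel <- b$relatedness
  rel <- rel[!(rel$mother_id == pat$mother_id[1] &
                 rel$male_id == pat$sire_id[1]), ]
  expect_error(
    assemble_risk_sets(pat, b$roster, fx$daily, rel, fx$traits),
    "fails the candidacy filters")
})

test_that("the no-random-intercept path equals the logistic-regression oracle", {
  fx <- risk_fixture()
  rows <- fx$rows
  terms <- c("age_z", "elo_z", "relatedness")
  fit <- fit_siring_glmm(rows, terms, random_intercept = FALSE)
  oracle <- glm(sired ~ age_z + elo_z + relatedness, data = rows,
                family = binomial())
  expect_equal(fit$fixed$estimate, unname(coef(oracle)), tolerance = 1e-12)
  expect_equal(fit$fixed$odds_ratio, exp(unname(coef(oracle))),
               tolerance = 1e-12)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-12)
  expect_true(all(fit$fixed$or_ci_low <= fit$fixed$odds_ratio &
                    fit$fixed$odds_ratio <= fit$fixed$or_ci_high))
})

test_that("the mixed model reports a male random-intercept variance", {
  fx <- risk_fixture()
  fit <- fit_siring_glmm(fx$rows, c("age_z", "elo_z", "relatedness"))
  expect_gte(fit$re_variance, 0)
  expect_equal(fit$n_events, length(unique(fx$rows$event_id)))
  expect_s4_class(fit$model, "glmerMod")
})

test_that("the AICc correction matches hand evaluation", {
  expect_equal(aicc(-170, 3, 20), 2 * 170 + 6 + 2 * 3 * 4 / 16)
  expect_equal(aicc(-100, 5, 612), -2 * -100 + 10 + 60 / 606)
})

test_that("model comparison produces a coherent AICc table", {
  fx <- risk_fixture()
  fam <- siring_model_family()
  expect_length(fam, 14L)
  # mild separation warnings are possible in the richest models here
  tab <- suppressWarnings(aicc_compare(fx$rows, fam,
                                       random_intercept = FALSE))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_equal(tab$delta[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  expect_true(all(tab$delta >= 0))
  # duplicated models share AICc and split the weight evenly
  twins <- aicc_compare(fx$rows, list(a = c("age_z", "elo_z"),
                                      b = c("elo_z", "age_z")),
                        random_intercept = FALSE)
  expect_equal(twins$AICc[1], twins$AICc[2], tolerance = 1e-10)
  expect_equal(twins$weight, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("Akaike weights are invariant to a constant AICc shift", {
  a <- c(100, 101.5, 104)
  w <- function(x) { d <- x - min(x); exp(-d / 2) / sum(exp(-d / 2)) }
  expect_equal(w(a), w(a + 57.3), tolerance = 1e-12)
  expect_equal(sum(w(a)), 1)
})

test_that("a negative quadratic Dominance term implies a unimodal response", {
  fx <- risk_fixture()
  fit <- fit_siring_glmm(fx$rows, c("age_z", "elo_z", "relatedness",
                                    "dominance_z", "I(dominance_z^2)"),
                         random_intercept = FALSE)
  b1 <- fit$fixed$estimate[fit$fixed$term == "dominance_z"]
  b2 <- fit$fixed$estimate[fit$fixed$term == "I(dominance_z^2)"]
  # generator uses a negative quadratic: the log-odds parabola opens down,
  # peaking at an interior Dominance value
  expect_lt(b2, 0)
  peak <- -b1 / (2 * b2)
  expect_true(is.finite(peak))
  grid <- seq(-3, 3, by = 0.1)
  lo <- b1 * grid + b2 * grid^2
  expect_equal(grid[which.max(lo)], round(peak * 10) / 10, tolerance = 0.11)
})
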