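test_that("the modeling table conserves rows and standardizes columns", {
  tab <- gamm_table()
  expect_equal(mean(tab$age_z), 0, tolerance = 1e-10)
  expect_equal(sd(tab$age_z), 1, tolerance = 1e-10)
  expect_equal(mean(tab$elo_z), 0, tolerance = 1e-10)
  expect_equal(sd(tab$dominance_z), 1, tolerance = 1e-10)
  # conservation: one row per retained male-day
  expect_equal(nrow(tab), sum(table(tab$male_id)))
  expect_s3_class(tab$male_id, "factor")
})

test_that("the model suite matches its declared structure", {
  s1 <- gamm_spec(1)
  expect_length(s1$traits, 0)
  s5 <- gamm_spec(5)
  expect_length(s5$traits, 6)
  s6 <- gamm_spec(6)
  expect_true(any(grepl("date_f", s6$random_labels)))
  expect_false(any(grepl("date_f", deparse(s5$formula))))
  # model 2: age + Dominance mains, interaction, 4 random terms
  s2 <- gamm_spec(2)
  rhs <- deparse(s2$formula)
  expect_true(any(grepl("ti\\(age_z, dominance_z", rhs)))
  # random terms: per-male intercept plus age and Dominance slopes
  expect_length(s2$random_labels, 3)
})

test_that("GAMM fits report sane statistics and never lose deviance", {
  tab <- gamm_table()
  f1 <- fit_gamm(tab, gamm_spec(1))
  expect_true(f1$converged)
  expect_gte(f1$deviance_explained, 0)
  expect_lte(f1$deviance_explained, 1)
  expect_true(all(f1$term_table$edf <= f1$term_table$ref_df + 1e-6))
  # main-effect reference df is 4 with the default basis dimension
  expect_equal(f1$term_table$ref_df[f1$term_table$term == "ti(age_z)"], 4)
  f2 <- fit_gamm(tab, gamm_spec(2))
  expect_gte(f2$deviance_explained, f1$deviance_explained - 1e-8)
  cmp <- reml_compare(f1, f2)
  expect_gte(cmp$statistic, 0)
  expect_identical(reml_compare(f1, f1)$statistic, 0)
  expect_equal(reml_compare(f1, f1)$p_value, 1)
})

test_that("a strictly linear trait effect is recovered as a straight line", {
  set.seed(77)
  ids <- sprintf("M%02d", 1:20)
  dom <- rnorm(20)
  rows <- do.call(rbind, lapply(1:20, function(i) {
    age <- seq(-1.5, 1.5, length.out = 60)
    data.frame(male_id = ids[i], age_z = age,
               dominance_z = dom[i],
               elo_z = 0.3 * age + 0.5 * dom[i] + rnorm(60, 0, 0.5),
               date = as.Date("2000-01-01") + seq(0, 590, by = 10),
               cardinal = NA_real_, stringsAsFactors = FALSE)
  }))
  rows$male_id <- factor(rows$male_id)
  fit <- fit_gamm(rows, gamm_spec(2))
  # partial shrinkage: the smooth uses clearly fewer than its reference df
  edf_dom <- fit$term_table$edf[fit$term_table$term == "ti(dominance_z)"]
  expect_lt(edf_dom, 3.5)
  # the fitted partial effect tracks the generating line within 2 SE
  nd <- rows[!duplicated(rows$male_id), ]
  pr <- predict(fit$fit, nd, type = "terms", se.fit = TRUE)
  eff <- pr$fit[, "ti(dominance_z)"]
  se <- pr$se.fit[, "ti(dominance_z)"]
  truth <- 0.5 * nd$dominance_z
  truth <- truth - mean(truth) + mean(eff)  # term effects are centered
  expect_true(mean(abs(eff - truth) <= 2 * pmax(se, 1e-6)) >= 0.9)
})

test_that("variance inflation factors match the per-column oracle", {
  set.seed(21)
  X <- as.data.frame(matrix(rnorm(300), ncol = 3))
  v <- vif(X)
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-10)
  # columns orthogonal to each other and to the intercept -> VIFs 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200), ncol = 2))))[, 2:3]
  expect_equal(unname(vif(as.data.frame(Q))), c(1, 1), tolerance = 1e-10)
  # exact collinearity -> infinite
  X$V4 <- X$V1 + X$V2
  expect_true(any(is.infinite(vif(X))))
})

test_that("stratified folds cover each row exactly once", {
  tab <- gamm_table()
  tab <- tab[seq_len(min(nrow(tab), 1200)), ]
  # a male with fewer rows than folds triggers the documented pooling note
  expect_warning(
    cv <- cross_validate(tab, gamm_spec(1), scheme = "stratified",
                         k_folds = 5, seed = 3, engine = "bam"),
    "pooled into folds")
  expect_length(cv$fold_index, nrow(tab))
  expect_true(all(cv$fold_index %in% 1:5))
  expect_true(all(cv$fold_mse >= 0))
  expect_equal(cv$mse, mean(cv$fold_mse))
})

test_that("forward-chaining blocks tile the date range without overlap", {
  tab <- gamm_table()
  tab <- tab[seq_len(min(nrow(tab), 1200)), ]
  cv <- cross_validate(tab, gamm_spec(1), scheme = "forward",
                       k_folds = 5, engine = "bam")
  f <- cv$fold_index
  expect_setequal(unique(f), 1:5)
  for (m in 1:4) {
    expect_lte(max(as.numeric(cv$date[f == m])),
               min(as.numeric(cv$date[f == m + 1])))
  }
})

test_that("a noiseless smooth signal cross-validates to near-zero error", {
  set.seed(31)
  ids <- sprintf("M%02d", 1:10)
  rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
    age <- seq(-1.5, 1.5, length.out = 50)
    data.frame(male_id = ids[i], age_z = age,
               elo_z = sin(age),
               date = as.Date("2000-01-01") + seq(5 * i, 5 * i + 490,
                                                  by = 10),
               cardinal = NA_real_, stringsAsFactors = FALSE)
  }))
  rows$male_id <- factor(rows$male_id)
  cv <- cross_validate(rows, gamm_spec(1), scheme = "stratified",
                       k_folds = 5, seed = 1)
  expect_lt(cv$mse_z, 1e-3)
})
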