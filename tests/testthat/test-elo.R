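test_that("expected win probability has the logistic closed form", {
  expect_equal(expected_win_prob(1000, 1000), 0.5)
  expect_equal(expected_win_prob(1400, 1000, scale = 400), 10 / 11)
  set.seed(5)
  a <- rnorm(200, 1000, 300); b <- rnorm(200, 1000, 300)
  expect_equal(expected_win_prob(a, b) + expected_win_prob(b, a),
               rep(1, 200), tolerance = 1e-14)
})

test_that("sequence likelihood matches the coin-flip and ledger oracles", {
  roster <- toy_roster()
  one <- toy_interactions()[1, ]
  p <- elo_params(k = 20, entry_scores = c(AA = 1000, BB = 1000, CC = 1000))
  expect_equal(sequence_nll(one, p), log(2), tolerance = 1e-12)

  ints <- toy_interactions()
  entries <- c(AA = 1100, BB = 1000, CC = 900)
  params <- elo_params(k = 30, entry_scores = entries)
  ledger <- elo_ledger(ints$receiver_id, ints$giver_id,
                       as.list(entries), k = 30)
  expect_equal(sequence_nll(ints, params), ledger$nll, tolerance = 1e-12)
})

test_that("likelihood is invariant to translating all entry scores", {
  ints <- toy_interactions()
  entries <- c(AA = 1100, BB = 1000, CC = 900)
  nll0 <- sequence_nll(ints, elo_params(25, entries))
  for (shift in c(-500, 137.5, 2000)) {
    expect_equal(sequence_nll(ints, elo_params(25, entries + shift)), nll0,
                 tolerance = 1e-10)
  }
})

test_that("1-D optimization of k agrees with a grid-search oracle", {
  sim <- small_sim()
  ints <- sim$bundle$interactions[1:800, ]
  truth <- sim$truth$entry_scores
  prof <- function(k) sequence_nll(ints, elo_params(k, truth))
  grid <- seq(1, 60, by = 0.5)
  k_grid <- grid[which.min(vapply(grid, prof, numeric(1)))]
  k_opt <- optimize(prof, c(0.5, 80))$minimum
  expect_lt(abs(k_opt - k_grid), 0.5)
})

test_that("the joint ML fit is deterministic and rank-sane", {
  # degenerate data: AA wins everything
  ints <- data.frame(date = as.Date("2000-01-01") + 1:40,
                     giver_id = rep(c("BB", "CC"), 20),
                     receiver_id = "AA", stringsAsFactors = FALSE)
  fit <- fit_ml_elo(ints)
  expect_true(fit$converged)
  es <- fit$params$entry_scores
  expect_true(es[["AA"]] > max(es[c("BB", "CC")]))
  expect_equal(mean(es), 1000, tolerance = 1e-8)  # anchored
  fit2 <- fit_ml_elo(ints)
  expect_identical(fit$params$k, fit2$params$k)
  expect_identical(fit$params$entry_scores, fit2$params$entry_scores)
})

test_that("daily series step on interaction days and are flat otherwise", {
  roster <- toy_roster()
  ints <- toy_interactions()
  entries <- c(AA = 1100, BB = 1000, CC = 900)
  params <- elo_params(30, entries)
  daily <- daily_elo(params, ints, roster)
  ledger <- elo_ledger(ints$receiver_id, ints$giver_id,
                       as.list(entries), k = 30)
  # after the last interaction every male sits at his ledger score
  last <- daily[daily$date == max(daily$date), ]
  for (id in c("AA", "BB", "CC")) {
    expect_equal(last$raw_elo[last$male_id == id], ledger$scores[[id]],
                 tolerance = 1e-10)
  }
  # flat between interaction days
  aa <- daily[daily$male_id == "AA", ]
  mid <- aa[aa$date > as.Date("1988-01-10") & aa$date < as.Date("1988-03-15"), ]
  expect_equal(length(unique(mid$raw_elo)), 1L)
  # and equal to the ledger after the first day's two interactions
  expect_equal(unique(mid$raw_elo), ledger$trace[[2]]$AA, tolerance = 1e-10)
})

test_that("a male with no interactions after entry stays at his entry score", {
  roster <- toy_roster()
  ints <- toy_interactions()[1:2, ]  # only interactions on 1988-01-10
  params <- elo_params(30, c(AA = 1100, BB = 1000, CC = 900))
  daily <- daily_elo(params, ints, roster)
  bb <- daily[daily$male_id == "BB" & daily$date > as.Date("1988-01-10"), ]
  expect_equal(length(unique(bb$raw_elo)), 1L)
})

test_that("cardinal scores match the pairwise definition", {
  # n = 2, equal scores
  d2 <- data.frame(male_id = c("A", "B"), date = as.Date("2000-01-01"),
                   raw_elo = c(1000, 1000), stringsAsFactors = FALSE)
  out2 <- cardinal_scores(d2)
  expect_equal(out2$cardinal, c(0.5, 0.5))

  set.seed(11)
  d8 <- data.frame(male_id = letters[1:8], date = as.Date("2000-01-01"),
                   raw_elo = rnorm(8, 1000, 250), stringsAsFactors = FALSE)
  out <- cardinal_scores(d8)
  # brute-force double loop
  oracle <- vapply(1:8, function(i) {
    acc <- 0
    for (j in setdiff(1:8, i)) {
      acc <- acc + 1 / (1 + 10^(-(d8$raw_elo[i] - d8$raw_elo[j]) / 400))
    }
    acc / 7
  }, numeric(1))
  expect_equal(out$cardinal, oracle, tolerance = 1e-12)
  expect_equal(sum(out$cardinal), 8 / 2, tolerance = 1e-12)
  expect_true(all(out$cardinal >= 0 & out$cardinal <= 1))
  # order preservation
  expect_equal(order(out$cardinal), order(d8$raw_elo))
})

test_that("ordinal ranks use min-tie ordering with 1 = top", {
  d <- data.frame(male_id = c("A", "B", "C"), date = as.Date("2000-01-01"),
                  raw_elo = c(10, 5, 1), stringsAsFactors = FALSE)
  expect_equal(ordinal_ranks(d)$ordinal, c(1L, 2L, 3L))
  d$raw_elo <- c(10, 10, 1)
  expect_equal(ordinal_ranks(d)$ordinal, c(1L, 1L, 3L))
  set.seed(3)
  d$raw_elo <- rnorm(3)
  expect_equal(ordinal_ranks(d)$ordinal,
               as.integer(rank(-d$raw_elo, ties.method = "min")))
})

test_that("cardinal and ordinal outputs are anchor-invariant", {
  roster <- toy_roster()
  ints <- toy_interactions()
  entries <- c(AA = 1100, BB = 1000, CC = 900)
  d0 <- daily_scores(elo_params(30, entries), ints, roster)
  d1 <- daily_scores(elo_params(30, entries + 750), ints, roster)
  expect_equal(d0$cardinal, d1$cardinal, tolerance = 1e-10)
  expect_identical(d0$ordinal, d1$ordinal)
})

test_that("singleton days yield missing cardinal and ordinal", {
  roster <- toy_roster()
  roster$last_observed[2:3] <- as.Date("1988-06-01")
  roster$death_date[2:3] <- as.Date("1988-06-01")
  ints <- toy_interactions()
  daily <- daily_scores(elo_params(30, c(AA = 1100, BB = 1000, CC = 900)),
                        ints, roster)
  solo <- daily[daily$date > as.Date("1988-06-01"), ]
  expect_true(nrow(solo) > 0)
  expect_true(all(is.na(solo$cardinal)))
  expect_true(all(is.na(solo$ordinal)))
  expect_true(all(solo$n_present == 1L))
})
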