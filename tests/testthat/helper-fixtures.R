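# shared fixtures, all built in code

toy_roster <- function() {
  data.frame(
    male_id = c("AA", "BB", "CC"),
    birth_date = as.Date(c("1970-01-01", "1972-06-15", "1975-03-10")),
    first_observed = as.Date(c("1982-01-05", "1984-06-20", "1987-03-15")),
    last_observed = as.Date(c("1995-12-31", "1995-12-31", "1995-12-31")),
    death_date = as.Date(c(NA, NA, NA)),
    excluded_flag = FALSE,
    stringsAsFactors = FALSE)
}

toy_interactions <- function() {
  # all participants are adult on these dates
  data.frame(
    date = as.Date(c("1988-01-10", "1988-01-10", "1988-02-01",
                     "1988-03-15", "1988-04-20")),
    giver_id = c("BB", "CC", "CC", "AA", "CC"),
    receiver_id = c("AA", "AA", "BB", "BB", "AA"),
    stringsAsFactors = FALSE)
}

# independent step-by-step Elo ledger written in plain R: the oracle for
# the sequential likelihood implementation
elo_ledger <- function(winners, losers, entries, k, scale = 400) {
  s <- entries
  nll <- 0
  trace <- list()
  for (t in seq_along(winners)) {
    w <- winners[t]; l <- losers[t]
    p <- 1 / (1 + 10^(-(s[[w]] - s[[l]]) / scale))
    nll <- nll - log(p)
    s[[w]] <- s[[w]] + k * (1 - p)
    s[[l]] <- s[[l]] - k * (1 - p)
    trace[[t]] <- s
  }
  list(nll = nll, scores = s, trace = trace)
}

# small simulated bundles are reused across tests; cache per config label
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(label, config) {
  if (is.null(.sim_cache[[label]])) {
    .sim_cache[[label]] <- simulate_study(config)
  }
  .sim_cache[[label]]
}

small_sim <- function() {
  cached_sim("small", sim_config(n_males = 10, span_years = 10,
                                 interactions_per_male_year = 25,
                                 adult_fraction = 0.8,
                                 mortality_hazard = 0.02,
                                 n_events = 20, n_mothers = 10,
                                 seed = 421))
}

# conditions for the parameter-recovery benchmark: a fully co-resident
# community of 10 males and ~2,000 interactions
recovery_config <- function(seed) {
  sim_config(n_males = 10, span_years = 6,
             interactions_per_male_year = 35,
             adult_fraction = 1, mortality_hazard = 0.005,
             n_events = 5, n_mothers = 6, seed = seed)
}

# small daily table for GAMM tests: 8 males, thinned to every 4th day
gamm_table <- function() {
  if (is.null(.sim_cache[["gamm_table"]])) {
    sim <- cached_sim("gamm", sim_config(n_males = 8, span_years = 9,
                                         interactions_per_male_year = 25,
                                         adult_fraction = 0.7,
                                         mortality_hazard = 0.02,
                                         n_events = 10, n_mothers = 8,
                                         seed = 99))
    b <- sim$bundle
    fit <- fit_ml_elo(b$interactions)
    daily <- daily_scores(fit$params, b$interactions, b$roster)
    daily <- daily[as.numeric(daily$date) %% 4 == 0, ]
    traits <- score_traits(b$ratings)
    .sim_cache[["gamm_table"]] <- build_rank_table(daily, traits, b$roster)
  }
  .sim_cache[["gamm_table"]]
}
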