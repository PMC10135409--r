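#' Expected win probability under the logistic Elo model
#'
#' The probability that an individual with rating `score_i` beats one with
#' rating `score_j`, using the classical base-10 logistic with scale
#' constant `scale`: `p = 1 / (1 + 10^(-(score_i - score_j) / scale))`.
#' Satisfies `p(i, j) + p(j, i) = 1`.
#'
#' @param score_i,score_j Ratings (rating points); vectorized.
#' @param scale Positive logistic scale constant in rating points
#'   (default 400, the classical Elo convention).
#' @return Win probabilities in (0, 1).
#' @export
expected_win_prob <- function(score_i, score_j, scale = 400) {
  stopifnot(scale > 0)
  1 / (1 + 10^(-(score_i - score_j) / scale))
}

#' Elo parameter set
#'
#' Bundles the update constant `k`, per-male hierarchy-entry scores, the
#' logistic scale and the anchor (the fixed mean of entry scores; the
#' likelihood is invariant to translating all entry scores, so the anchor
#' merely selects a representative).
#'
#' @param k Update constant, rating points per interaction (> 0).
#' @param entry_scores Named numeric vector, `male_id` -> rating at
#'   hierarchy entry.
#' @param scale Logistic scale constant (rating points).
#' @param anchor Mean entry score (rating points).
#' @return An `elo_params` list.
#' @export
elo_params <- function(k, entry_scores, scale = 400, anchor = 1000) {
  stopifnot(k > 0, scale > 0, !is.null(names(entry_scores)))
  structure(list(k = k, entry_scores = entry_scores, scale = scale,
                 anchor = anchor),
            class = "elo_params")
}

# sort interactions by date, preserving input order within a day
# (the within-day order is part of the data contract)
order_interactions <- function(interactions) {
  interactions[order(as.numeric(interactions$date)), , drop = FALSE]
}

# map the giver/receiver stream to winner/loser indices over the male set
interaction_indices <- function(interactions, ids) {
  w <- match(interactions$receiver_id, ids)  # receiver of a pant-grunt wins
  l <- match(interactions$giver_id, ids)
  if (anyNA(w) || anyNA(l)) {
    stop("participant without an entry score: ",
         paste(unique(c(interactions$receiver_id[is.na(w)],
                        interactions$giver_id[is.na(l)])), collapse = ", "))
  }
  list(winner = w, loser = l)
}

#' Negative log-likelihood of an interaction sequence
#'
#' Scores start at each male's entry value; for each interaction in date
#' order the likelihood contribution is `-ln p(winner beats loser)` at the
#' current scores, after which winner and loser are updated by
#' `+/- k * (1 - p_win)`. The pant-grunt receiver is the winner.
#'
#' @param interactions Interaction data frame (`date`, `giver_id`,
#'   `receiver_id`); sorted internally by date with input order kept
#'   within a day.
#' @param params An [elo_params()] object covering every participant.
#' @return Negative log-likelihood in nats.
#' @export
sequence_nll <- function(interactions, params) {
  interactions <- order_interactions(interactions)
  ids <- names(params$entry_scores)
  idx <- interaction_indices(interactions, ids)
  elo_seq_nll(idx$winner, idx$loser, unname(params$entry_scores),
              params$k, params$scale)
}

#' Maximum-likelihood Elo fit
#'
#' Jointly estimates the update constant `k` and every participant's
#' hierarchy-entry score by minimizing [sequence_nll()]. `k` is optimized
#' on the log scale to enforce positivity; entry scores are parameterized
#' as anchored deviations (their mean is fixed at `anchor`), removing the
#' flat translation direction of the likelihood. Deterministic given the
#' fixed documented starting point (`k = k_init`, all entries at the
#' anchor).
#'
#' @inheritParams sequence_nll
#' @param scale,anchor See [elo_params()].
#' @param k_init Starting value for `k` (default 16).
#' @param maxit Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @return An `elo_fit`: `params` ([elo_params()]), `nll`, `converged`,
#'   `n_interactions`, `n_males`, and the optimizer `trace` summary.
#'   Non-convergence is reported via `converged = FALSE`, not an error.
#' @export
fit_ml_elo <- function(interactions, scale = 400, anchor = 1000,
                       k_init = 16, maxit = 500, reltol = 1e-10) {
  interactions <- order_interactions(interactions)
  ids <- sort(unique(c(interactions$giver_id, interactions$receiver_id)))
  m <- length(ids)
  if (m < 2L || nrow(interactions) < 1L) {
    stop("fit_ml_elo(): need at least 2 males and 1 interaction")
  }
  idx <- interaction_indices(interactions, ids)

  unpack <- function(theta) {
    k <- exp(theta[1])
    d <- theta[-1]
    entries <- anchor + c(d, -sum(d))
    list(k = k, entries = entries)
  }
  objective <- function(theta) {
    p <- unpack(theta)
    elo_seq_nll(idx$winner, idx$loser, p$entries, p$k, scale)
  }
  theta0 <- c(log(k_init), rep(0, m - 1L))
  opt <- optim(theta0, objective, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  p <- unpack(opt$par)
  entry_scores <- setNames(p$entries, ids)
  structure(list(
    params = elo_params(p$k, entry_scores, scale = scale, anchor = anchor),
    nll = opt$value,
    converged = opt$convergence == 0L,
    n_interactions = nrow(interactions),
    n_males = m,
    trace = list(counts = opt$counts, convergence = opt$convergence,
                 message = opt$message)
  ), class = "elo_fit")
}

#' @exportS3Method base::print
print.elo_fit <- function(x, ...) {
  cat("Maximum-likelihood Elo fit\n")
  cat(sprintf("  %d interactions among %d males\n", x$n_interactions,
              x$n_males))
  cat(sprintf("  k = %.3f (scale %g, anchor %g)\n", x$params$k,
              x$params$scale, x$params$anchor))
  cat(sprintf("  nll = %.4f  converged: %s\n", x$nll, x$converged))
  invisible(x)
}

#' Daily raw Elo score series
#'
#' Expands fitted parameters into one record per male per day, from his
#' hierarchy-entry date to his last day in the study (death date if known,
#' otherwise last observation, capped at `study_end`). The raw score is
#' constant between interaction days and steps on an interaction day after
#' that day's updates.
#'
#' @inheritParams sequence_nll
#' @param roster Roster data frame.
#' @param study_end Optional `Date` capping every male's series.
#' @return Data frame `male_id`, `date`, `raw_elo`.
#' @export
daily_elo <- function(params, interactions, roster, study_end = NULL) {
  interactions <- order_interactions(interactions)
  ids <- names(params$entry_scores)
  idx <- interaction_indices(interactions, ids)
  run <- elo_seq_run(idx$winner, idx$loser, unname(params$entry_scores),
                     params$k, params$scale)
  entry <- hierarchy_entry_dates(roster, interactions)
  entry <- entry[!is.na(entry$entry_date) & entry$male_id %in% ids, ,
                 drop = FALSE]
  int_dates <- as.numeric(interactions$date)

  per_male <- lapply(seq_len(nrow(entry)), function(i) {
    id <- entry$male_id[i]
    r <- roster[roster$male_id == id, ]
    last <- if (!is.na(r$death_date)) min(r$death_date, r$last_observed)
            else r$last_observed
    if (!is.null(study_end)) last <- min(last, as.Date(study_end))
    if (last < entry$entry_date[i]) return(NULL)
    days <- seq(entry$entry_date[i], last, by = "day")
    j <- match(id, ids)
    pos <- findInterval(as.numeric(days), int_dates)
    raw <- ifelse(pos == 0L, params$entry_scores[[j]], run$trace[pmax(pos, 1L), j])
    data.frame(male_id = id, date = days, raw_elo = raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_male)
  rownames(out) <- NULL
  out
}

#' Cardinal scores for a daily series
#'
#' For each male-day, the mean probability of beating each other male
#' present in that day's hierarchy:
#' `cardinal_i = (1 / (n - 1)) * sum_{j != i} p(e_i beats e_j)`. Bounded in
#' `[0, 1]`, strictly increasing in the raw score within a day, and the
#' day's values sum to `n / 2`. Days with a single male present yield `NA`.
#'
#' @param daily Data frame from [daily_elo()].
#' @param scale Logistic scale constant (must match the fit).
#' @return `daily` with columns `cardinal` and `n_present` added.
#' @export
cardinal_scores <- function(daily, scale = 400) {
  daily$cardinal <- NA_real_
  daily$n_present <- NA_integer_
  for (rows in split(seq_len(nrow(daily)), as.numeric(daily$date))) {
    n <- length(rows)
    daily$n_present[rows] <- n
    if (n < 2L) next
    e <- daily$raw_elo[rows]
    p <- expected_win_prob(outer(e, e, "-"), 0, scale)
    daily$cardinal[rows] <- (rowSums(p) - 0.5) / (n - 1)
  }
  daily
}

#' Ordinal ranks for a daily series
#'
#' Rank 1 is the day's highest raw score; ties share the smallest
#' applicable rank. Days with a single male present yield `NA`.
#'
#' @inheritParams cardinal_scores
#' @return `daily` with columns `ordinal` and `n_present` added.
#' @export
ordinal_ranks <- function(daily) {
  daily$ordinal <- NA_integer_
  if (!"n_present" %in% names(daily)) daily$n_present <- NA_integer_
  for (rows in split(seq_len(nrow(daily)), as.numeric(daily$date))) {
    n <- length(rows)
    daily$n_present[rows] <- n
    if (n < 2L) next
    daily$ordinal[rows] <- as.integer(rank(-daily$raw_elo[rows],
                                           ties.method = "min"))
  }
  daily
}

#' Full daily score series (raw, cardinal, ordinal)
#'
#' Convenience wrapper running [daily_elo()], [cardinal_scores()] and
#' [ordinal_ranks()].
#'
#' @inheritParams daily_elo
#' @return Data frame `male_id`, `date`, `raw_elo`, `cardinal`, `ordinal`,
#'   `n_present`.
#' @export
daily_scores <- function(params, interactions, roster, study_end = NULL) {
  daily <- daily_elo(params, interactions, roster, study_end)
  daily <- cardinal_scores(daily, scale = params$scale)
  ordinal_ranks(daily)
}
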