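#' Default item-to-trait scoring key
#'
#' A unit-weighted key mapping questionnaire adjectives to the six
#' personality traits (Dominance, Extraversion, Conscientiousness,
#' Agreeableness, Neuroticism, Openness). Nineteen of the instrument's 24
#' items are keyed; negatively keyed items (sign `-`) are reverse-scored as
#' `x -> 8 - x` before averaging. This default is a synthetic key built
#' from the standard adjective descriptions of the six traits; studies with
#' a published instrument key should supply it via [read_scoring_key()].
#'
#' @return Named list: trait -> named character vector of item signs
#'   (`"+"` or `"-"`).
#' @export
default_scoring_key <- function() {
  list(
    Dominance = c(dominant = "+", decisive = "+", dependent = "-",
                  fearful = "-", timid = "-"),
    Extraversion = c(sociable = "+", active = "+", solitary = "-",
                     individualistic = "-"),
    Conscientiousness = c(predictable = "+", impulsive = "-",
                          reckless = "-"),
    Agreeableness = c(sympathetic = "+", helpful = "+", gentle = "+"),
    Neuroticism = c(excitable = "+", stable = "-"),
    Openness = c(curious = "+", inventive = "+")
  )
}

# the 24 instrument items: 19 keyed plus 5 unkeyed (insufficient
# interrater reliability)
questionnaire_items <- function() {
  c(unlist(lapply(default_scoring_key(), names), use.names = FALSE),
    "bullying", "stingy", "manipulative", "cautious", "irritable")
}

#' Read a scoring key from YAML
#'
#' The YAML file maps each trait to a mapping of item name to sign, e.g.
#' `Dominance: {dominant: "+", fearful: "-"}`.
#'
#' @param path Path to a YAML key file.
#' @return A scoring key in the format of [default_scoring_key()].
#' @export
read_scoring_key <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(tr) {
    out <- vapply(tr, as.character, character(1))
    if (!all(out %in% c("+", "-"))) stop("key signs must be '+' or '-'")
    out
  })
}

validate_scoring_key <- function(key) {
  for (trait in names(key)) {
    items <- names(key[[trait]])
    if (anyDuplicated(items)) {
      stop("scoring key: item keyed twice within trait ", trait)
    }
  }
  invisible(key)
}

#' Score personality traits from questionnaire ratings
#'
#' Negatively keyed items are reversed (`x -> 8 - x`); each rater's trait
#' score is the mean of their keyed item scores (missing items excluded
#' pairwise); each male's trait score is the mean over raters. Males with
#' no raters are omitted with a warning.
#'
#' @param ratings Long-format ratings data frame with columns `rater_id`,
#'   `male_id`, `item`, `score` (1-7).
#' @param key Scoring key as from [default_scoring_key()].
#' @return Data frame: `male_id`, one column per trait (1-7 scale),
#'   `n_raters`.
#' @export
score_traits <- function(ratings, key = default_scoring_key()) {
  validate_scoring_key(key)
  males <- unique(ratings$male_id)
  rows <- lapply(males, function(id) {
    sub <- ratings[ratings$male_id == id, , drop = FALSE]
    raters <- unique(sub$rater_id)
    if (length(raters) == 0L) return(NULL)
    scores <- vapply(names(key), function(trait) {
      signs <- key[[trait]]
      per_rater <- vapply(raters, function(r) {
        rr <- sub[sub$rater_id == r & sub$item %in% names(signs), ,
                  drop = FALSE]
        if (nrow(rr) == 0L) return(NA_real_)
        vals <- ifelse(signs[rr$item] == "-", 8 - rr$score, rr$score)
        mean(vals)
      }, numeric(1))
      mean(per_rater, na.rm = TRUE)
    }, numeric(1))
    c(list(male_id = id), as.list(scores), list(n_raters = length(raters)))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) < length(males)) {
    warning("score_traits(): ", length(males) - length(rows),
            " male(s) with zero raters omitted")
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Interrater reliability of mean ratings, ICC(3,k)
#'
#' Two-way consistency intraclass correlation for the mean of k raters
#' (Shrout-Fleiss ICC(3,k)): `(BMS - EMS) / BMS`, where BMS and EMS are
#' the between-target and residual mean squares of the targets x raters
#' ANOVA. For unbalanced designs the rating matrix may contain missing
#' cells; the effective k reported is the harmonic mean of raters per
#' target.
#'
#' @param ratings_matrix Numeric matrix, targets in rows, raters in
#'   columns; `NA` for unrated cells.
#' @param name Optional label for the scored trait or item.
#' @return A `reliability_result`: `name`, `icc_mean_raters`,
#'   `k_effective`, `n_targets`.
#' @export
icc_mean_raters <- function(ratings_matrix, name = NULL) {
  ratings_matrix <- as.matrix(ratings_matrix)
  if (nrow(ratings_matrix) < 2L) {
    stop("icc_mean_raters(): need at least 2 targets")
  }
  long <- data.frame(
    score = as.vector(ratings_matrix),
    target = factor(rep(seq_len(nrow(ratings_matrix)),
                        ncol(ratings_matrix))),
    rater = factor(rep(seq_len(ncol(ratings_matrix)),
                       each = nrow(ratings_matrix))))
  long <- long[!is.na(long$score), , drop = FALSE]
  k_per_target <- table(long$target)
  k_per_target <- k_per_target[k_per_target > 0]
  k_eff <- length(k_per_target) / sum(1 / as.numeric(k_per_target))
  # rater entered first so the target mean square is adjusted for raters;
  # perfect agreement makes the fit exact, which summary flags needlessly
  tab <- suppressWarnings(anova(lm(score ~ rater + target, data = long)))
  bms <- tab["target", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  icc <- (bms - ems) / bms
  structure(list(name = name, icc_mean_raters = icc, k_effective = k_eff,
                 n_targets = nrow(ratings_matrix)),
            class = "reliability_result")
}

#' @exportS3Method base::print
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC(3,k)%s = %.3f (k_eff = %.2f, %d targets)\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              x$icc_mean_raters, x$k_effective, x$n_targets))
  invisible(x)
}

#' Trait-score reliability across raters
#'
#' Builds, for each trait, the targets x raters matrix of per-rater trait
#' scores and computes [icc_mean_raters()].
#'
#' @inheritParams score_traits
#' @return List of `reliability_result`, one per trait.
#' @export
trait_reliability <- function(ratings, key = default_scoring_key()) {
  validate_scoring_key(key)
  males <- sort(unique(ratings$male_id))
  raters <- sort(unique(ratings$rater_id))
  lapply(setNames(names(key), names(key)), function(trait) {
    signs <- key[[trait]]
    mat <- matrix(NA_real_, length(males), length(raters),
                  dimnames = list(males, raters))
    for (i in seq_len(nrow(ratings))) {
      if (!ratings$item[i] %in% names(signs)) next
      v <- if (signs[[ratings$item[i]]] == "-") 8 - ratings$score[i]
           else ratings$score[i]
      m <- ratings$male_id[i]; r <- ratings$rater_id[i]
      cur <- mat[m, r]
      mat[m, r] <- if (is.na(cur)) v else cur + v  # accumulate, average below
    }
    # per-rater trait score = mean over that rater's keyed items
    counts <- matrix(0L, length(males), length(raters),
                     dimnames = list(males, raters))
    keyed <- ratings[ratings$item %in% names(signs), , drop = FALSE]
    tb <- table(factor(keyed$male_id, males), factor(keyed$rater_id, raters))
    counts[] <- as.integer(tb)
    mat <- mat / ifelse(counts == 0L, NA, counts)
    icc_mean_raters(mat, name = trait)
  })
}
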