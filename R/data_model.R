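#' Decimal age in years on a given date
#'
#' Ages are computed in whole days and converted to years by dividing by
#' 365.25, so a male born exactly 4383 days before `date` is 12.0 years old.
#'
#' @param birth_date `Date` vector of birth dates.
#' @param date `Date` vector (recycled against `birth_date`).
#' @return Numeric vector of ages in decimal years.
#' @examples
#' age_on(as.Date("2000-01-01"), as.Date("2000-01-01") + 4383)
#' @export
age_on <- function(birth_date, date) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  days <- as.numeric(date - birth_date)
  if (any(days < 0, na.rm = TRUE)) {
    stop("age_on(): date precedes birth_date for ",
         sum(days < 0, na.rm = TRUE), " record(s)")
  }
  days / 365.25
}

# date at which a male turns `years` old, in whole days (years * 365.25,
# rounded to the nearest day)
age_date <- function(birth_date, years = 12) {
  as.Date(birth_date) + round(years * 365.25)
}

# ---- readers / validators -------------------------------------------------

#' @rdname load_study_tables
#' @export
study_table_schemas <- function() {
  list(
    roster = list(
      required = c("male_id", "birth_date", "first_observed", "last_observed"),
      optional = c("death_date", "excluded_flag"),
      dates    = c("birth_date", "first_observed", "last_observed",
                   "death_date")),
    interactions = list(
      required = c("date", "giver_id", "receiver_id"),
      optional = character(),
      dates    = "date"),
    ratings = list(
      required = c("rater_id", "male_id", "item", "score"),
      optional = character(),
      dates    = character()),
    paternities = list(
      required = c("offspring_id", "birth_date", "mother_id", "sire_id"),
      optional = character(),
      dates    = "birth_date"),
    relatedness = list(
      required = c("mother_id", "male_id", "r_value"),
      optional = character(),
      dates    = character())
  )
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE,
           check.names = FALSE, na.strings = c("NA", ""))
}

parse_date_col <- function(x, col, table) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(rep(NA_real_, length(x)))
  filled <- !is.na(x) & nzchar(as.character(x))
  parsed <- as.Date(as.character(x[filled]), format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(filled)[is.na(parsed)]
    stop(sprintf("table '%s', column '%s': unparseable date at row %s",
                 table, col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  out[filled] <- parsed
  out
}

validate_study_table <- function(df, name, colmap = NULL) {
  schema <- study_table_schemas()[[name]]
  if (is.null(schema)) stop("unknown study table: ", name)
  if (!is.null(colmap[[name]])) {
    m <- unlist(colmap[[name]])
    idx <- match(m, names(df))
    ok <- !is.na(idx)
    names(df)[idx[ok]] <- names(m)[ok]
  }
  missing <- setdiff(schema$required, names(df))
  if (length(missing)) {
    stop(sprintf("table '%s': missing required column(s): %s",
                 name, paste(missing, collapse = ", ")))
  }
  for (col in intersect(schema$dates, names(df))) {
    df[[col]] <- parse_date_col(df[[col]], col, name)
  }
  if (name == "roster") {
    if (!"death_date" %in% names(df)) df$death_date <- as.Date(NA)
    if (!"excluded_flag" %in% names(df)) df$excluded_flag <- FALSE
    df$excluded_flag <- as.logical(df$excluded_flag)
    df$excluded_flag[is.na(df$excluded_flag)] <- FALSE
    bad <- df$birth_date > df$first_observed | df$first_observed > df$last_observed
    if (any(bad)) {
      stop("roster: birth_date <= first_observed <= last_observed violated for: ",
           paste(df$male_id[bad], collapse = ", "))
    }
    dd <- !is.na(df$death_date) & df$death_date < df$last_observed - 1
    if (any(dd)) {
      stop("roster: death_date earlier than last_observed for: ",
           paste(df$male_id[dd], collapse = ", "))
    }
  }
  if (name == "interactions" && any(df$giver_id == df$receiver_id)) {
    stop("interactions: giver_id == receiver_id at row(s) ",
         paste(utils::head(which(df$giver_id == df$receiver_id), 5),
               collapse = ", "))
  }
  if (name == "ratings") {
    df$score <- as.numeric(df$score)
    if (any(!df$score %in% 1:7)) {
      stop("ratings: scores must be integers in 1..7")
    }
    key <- paste(df$rater_id, df$male_id, df$item)
    if (anyDuplicated(key)) {
      stop("ratings: duplicated rater x male x item entries")
    }
  }
  if (name == "relatedness") {
    df$r_value <- as.numeric(df$r_value)
    if (anyDuplicated(paste(df$mother_id, df$male_id))) {
      stop("relatedness: duplicated mother x male dyads")
    }
  }
  df
}

check_referential_integrity <- function(bundle) {
  males <- bundle$roster$male_id
  offenders <- character()
  ids <- unique(c(bundle$interactions$giver_id, bundle$interactions$receiver_id))
  offenders <- c(offenders, setdiff(ids, males))
  offenders <- c(offenders, setdiff(unique(bundle$ratings$male_id), males))
  offenders <- c(offenders, setdiff(unique(bundle$paternities$sire_id), males))
  offenders <- c(offenders, setdiff(unique(bundle$relatedness$male_id), males))
  offenders <- unique(offenders)
  if (length(offenders)) {
    stop("referential integrity: unknown male id(s): ",
         paste(offenders, collapse = ", "))
  }
  invisible(bundle)
}

#' Load and validate a study bundle from delimited text tables
#'
#' Reads the five study tables (roster, interactions, ratings, paternities,
#' relatedness) from comma- or tab-delimited text with a header, checks
#' schemas, parses ISO-8601 dates, and enforces referential integrity: every
#' male id appearing in a child table must exist in the roster.
#'
#' @param paths Named list/character vector mapping table names
#'   (`roster`, `interactions`, `ratings`, `paternities`, `relatedness`)
#'   to file paths. Tables other than `roster` and `interactions` are
#'   optional.
#' @param colmap Optional nested list renaming file columns to canonical
#'   names, e.g. `list(roster = c(male_id = "ID"))`. May also be a path to
#'   a YAML file with the same structure.
#' @return A `study_bundle`: a list of validated data frames.
#' @export
load_study_tables <- function(paths, colmap = NULL) {
  if (is.character(colmap) && length(colmap) == 1L) {
    colmap <- yaml::read_yaml(colmap)
  }
  if (!all(c("roster", "interactions") %in% names(paths))) {
    stop("paths must name at least 'roster' and 'interactions'")
  }
  bundle <- list()
  for (name in names(study_table_schemas())) {
    if (!is.null(paths[[name]])) {
      bundle[[name]] <- validate_study_table(read_delim_auto(paths[[name]]),
                                             name, colmap)
    } else {
      schema <- study_table_schemas()[[name]]
      empty <- as.data.frame(setNames(
        rep(list(character(0)), length(schema$required)), schema$required))
      bundle[[name]] <- validate_study_table(empty, name, colmap = NULL)
    }
  }
  bundle <- structure(bundle, class = "study_bundle")
  check_referential_integrity(bundle)
  message(sprintf(
    "study bundle: %d males, %d interactions, %d ratings, %d paternities, %d relatedness dyads",
    nrow(bundle$roster), nrow(bundle$interactions), nrow(bundle$ratings),
    nrow(bundle$paternities), nrow(bundle$relatedness)))
  bundle
}

#' @describeIn load_study_tables Write a bundle back to comma-delimited text;
#'   reloading the written files yields an identical bundle.
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if absent).
#' @export
write_study_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (name in names(study_table_schemas())) {
    p <- file.path(dir, paste0(name, ".csv"))
    write.csv(bundle[[name]], p, row.names = FALSE, quote = FALSE)
    paths[[name]] <- p
  }
  invisible(paths)
}

#' @exportS3Method base::print
print.study_bundle <- function(x, ...) {
  cat("study_bundle\n")
  for (name in names(study_table_schemas())) {
    cat(sprintf("  %-13s %6d rows\n", name, nrow(x[[name]])))
  }
  invisible(x)
}

# ---- filters and entry dates ---------------------------------------------

#' Restrict interactions to adult dyads
#'
#' Keeps exactly the interactions where both the giver and the receiver were
#' at least 12.0 years old on the interaction date (inclusive boundary).
#' Row order is preserved; the operation is idempotent.
#'
#' @param interactions Interaction data frame (`date`, `giver_id`,
#'   `receiver_id`).
#' @param roster Roster data frame with `male_id` and `birth_date`.
#' @param min_age Adult age cutoff in years (default 12).
#' @return The filtered interaction data frame.
#' @export
filter_adult_interactions <- function(interactions, roster, min_age = 12) {
  birth <- setNames(roster$birth_date, roster$male_id)
  unknown <- setdiff(unique(c(interactions$giver_id, interactions$receiver_id)),
                     names(birth))
  if (length(unknown)) {
    stop("filter_adult_interactions(): unknown male id(s): ",
         paste(unknown, collapse = ", "))
  }
  a_g <- age_on(birth[interactions$giver_id], interactions$date)
  a_r <- age_on(birth[interactions$receiver_id], interactions$date)
  out <- interactions[a_g >= min_age & a_r >= min_age, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hierarchy-entry dates
#'
#' A male's hierarchy-entry date is the later of the date he turns 12.0
#' years and his first appearance in the (already adult-filtered)
#' interaction record. Males absent from the interaction record get `NA`
#' and are excluded from rating.
#'
#' @inheritParams filter_adult_interactions
#' @param entry_age Age in years that defines eligibility to enter (default
#'   12).
#' @return Data frame with `male_id`, `entry_date`, `entry_age`.
#' @export
hierarchy_entry_dates <- function(roster, interactions, entry_age = 12) {
  first_seen <- vapply(roster$male_id, function(id) {
    rows <- interactions$giver_id == id | interactions$receiver_id == id
    if (!any(rows)) NA_real_ else as.numeric(min(interactions$date[rows]))
  }, numeric(1))
  first_seen <- as.Date(first_seen, origin = "1970-01-01")
  turns <- age_date(roster$birth_date, entry_age)
  entry <- as.Date(ifelse(is.na(first_seen), NA,
                          pmax(as.numeric(first_seen), as.numeric(turns))),
                   origin = "1970-01-01")
  data.frame(male_id = roster$male_id,
             entry_date = entry,
             entry_age = age_on(roster$birth_date, entry),
             stringsAsFactors = FALSE)
}
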