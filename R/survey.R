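#' Read a long-format survey file
#'
#' Reads a UTF-8 CSV with header `participant_id,identity,behaviour`, one row
#' per participant--identity--behaviour triple. The behaviour field may be
#' empty for identity-only rows. Labels are whitespace-normalized and
#' case-folded on ingestion, duplicate triples are collapsed, and rows with an
#' empty identity are dropped with a warning.
#'
#' @param path Path to the CSV file.
#' @return A validated [survey_data][as_survey] object.
#' @seealso [write_survey()], [as_survey()], [summary.survey_data()]
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", na.strings = character())
  as_survey(df)
}

#' Construct and validate a survey dataset
#'
#' The canonical representation is a long data frame with columns
#' `participant_id`, `identity` and `behaviour` (empty string for
#' identity-only rows), carrying class `survey_data`. Row order encodes the
#' order in which identities were reported.
#'
#' Validation enforces: required columns present; labels non-empty after
#' whitespace normalization and case folding; duplicate
#' (participant, identity, behaviour) triples collapsed; at most a warning if a
#' participant reports more than 10 identities (the survey instrument capped
#' entry boxes at 10, so more usually signals an upstream coding problem).
#'
#' @param df A data frame with columns `participant_id`, `identity`,
#'   `behaviour` (the last may be absent and is then treated as all-empty).
#' @return A `survey_data` object.
#' @export
as_survey <- function(df) {
  required <- c("participant_id", "identity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("survey format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"behaviour" %in% names(df)) df$behaviour <- ""
  df <- df[, c("participant_id", "identity", "behaviour")]

  df$participant_id <- normalize_label(df$participant_id)
  df$identity <- normalize_label(df$identity)
  df$behaviour <- normalize_label(df$behaviour)

  if (any(df$participant_id == "")) {
    stop("survey format error: empty participant_id")
  }
  drop <- df$identity == ""
  if (any(drop)) {
    warning(sum(drop), " row(s) with empty identity rejected")
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("survey format error: no valid rows")

  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL

  n_ident <- tapply(df$identity, df$participant_id,
                    function(x) length(unique(x)))
  if (any(n_ident > 10L)) {
    warning("participant(s) with more than 10 identities kept: ",
            paste(names(n_ident)[n_ident > 10L], collapse = ", "))
  }
  class(df) <- c("survey_data", "data.frame")
  df
}

normalize_label <- function(x) {
  x[is.na(x)] <- ""
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Write a survey dataset to CSV
#'
#' Writes the same long CSV dialect read by [read_survey()], so that
#' `read_survey(write_survey(x, f))` round-trips.
#'
#' @param x A `survey_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(x, path) {
  stopifnot(inherits(x, "survey_data"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.survey_data <- function(x, ...) {
  ids <- unique(x$participant_id)
  cat("Survey dataset:", length(ids), "participants,",
      length(unique(x$identity)), "identity labels,",
      length(unique(x$behaviour[x$behaviour != ""])), "behaviour labels\n")
  invisible(x)
}

#' Per-participant identity lists
#'
#' @param x A `survey_data` object.
#' @return A named list, one character vector of identity labels per
#'   participant, in reporting order.
#' @export
participant_identities <- function(x) {
  stopifnot(inherits(x, "survey_data"))
  split_ids <- split(x$identity, x$participant_id)
  lapply(split_ids, unique)
}

#' Occurrence counts of identity labels
#'
#' The occurrence count of an identity is the number of participants reporting
#' it (each participant contributes at most once).
#'
#' @param x A `survey_data` object.
#' @return A named integer vector, sorted decreasing.
#' @export
identity_counts <- function(x) {
  stopifnot(inherits(x, "survey_data"))
  pi <- unique(x[, c("participant_id", "identity")])
  sort(table_to_int(table(pi$identity)), decreasing = TRUE)
}

#' Occurrence counts of behaviour labels
#'
#' The occurrence count of a behaviour is the number of
#' (participant, identity) entries listing it, matching the sample definition
#' used by the behaviour-network permutations.
#'
#' @param x A `survey_data` object.
#' @return A named integer vector, sorted decreasing.
#' @export
behaviour_counts <- function(x) {
  stopifnot(inherits(x, "survey_data"))
  b <- x[x$behaviour != "", c("participant_id", "identity", "behaviour")]
  b <- unique(b)
  sort(table_to_int(table(b$behaviour)), decreasing = TRUE)
}

table_to_int <- function(tab) {
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Filter labels by occurrence count
#'
#' Retains labels observed strictly more than `min_count` times. The default
#' threshold of 3 keeps nodes observed more than three times, the filter
#' applied before all structural analyses.
#'
#' @param counts Named integer vector of label occurrence counts.
#' @param min_count Strict lower threshold (retain count > `min_count`).
#' @return Character vector of retained labels.
#' @export
filter_items <- function(counts, min_count = 3) {
  stopifnot(min_count >= 0)
  out <- names(counts)[counts > min_count]
  if (is.null(out)) character(0) else out
}

#' Summarize a survey dataset
#'
#' Computes the descriptive statistics used to characterize a survey:
#' identities per participant, behaviours per identity (over identity entries
#' with at least one behaviour), and behaviours per person (total behaviour
#' mentions), each as (mean, sd, mode, min, max) with sample SD and ties in
#' the mode resolved to the smallest value; plus label occurrence counts.
#'
#' @param object A `survey_data` object.
#' @param ... Unused.
#' @return A `survey_summary` list with elements `n_participants`,
#'   `identities_per_participant`, `behaviours_per_identity`,
#'   `behaviours_per_person`, `identity_counts`, `behaviour_counts`.
#' @export
summary.survey_data <- function(object, ...) {
  ids <- participant_identities(object)
  n_ident <- vapply(ids, length, integer(1))

  b <- unique(object[object$behaviour != "", ])
  per_entry <- table(paste(b$participant_id, b$identity, sep = "\r"))
  per_person <- tapply(b$behaviour, b$participant_id, length)
  per_person <- per_person[names(ids)]
  per_person[is.na(per_person)] <- 0L

  out <- list(
    n_participants = length(ids),
    identities_per_participant = describe_counts(n_ident),
    behaviours_per_identity = describe_counts(as.integer(per_entry)),
    behaviours_per_person = describe_counts(as.integer(per_person)),
    identity_counts = identity_counts(object),
    behaviour_counts = behaviour_counts(object)
  )
  class(out) <- "survey_summary"
  out
}

describe_counts <- function(x) {
  if (length(x) == 0L) {
    return(c(mean = NA_real_, sd = NA_real_, mode = NA_real_,
             min = NA_real_, max = NA_real_))
  }
  tab <- table(x)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  c(mean = mean(x), sd = stats::sd(x), mode = min(modes),
    min = min(x), max = max(x))
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("Survey summary (", x$n_participants, " participants)\n", sep = "")
  stats_tab <- rbind(
    `identities / participant` = x$identities_per_participant,
    `behaviours / identity` = x$behaviours_per_identity,
    `behaviours / person` = x$behaviours_per_person
  )
  print(round(stats_tab, 2))
  cat("identity vocabulary:", length(x$identity_counts),
      "labels; behaviour vocabulary:", length(x$behaviour_counts), "labels\n")
  invisible(x)
}
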