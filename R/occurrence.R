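#' Build a binary samples-by-items occurrence matrix
#'
#' Derives, from a survey dataset, the binary incidence matrix underlying one
#' of the three network constructions. Rows are samples, columns are the items
#' that become network nodes:
#'
#' * `identity_by_identity`: one row per participant, one column per identity;
#'   a cell is 1 iff the participant reported the identity.
#' * `behaviour_by_identity`: one row per (participant, identity) entry that
#'   lists at least one retained behaviour, one column per behaviour.
#' * `identity_by_behaviour`: one row per distinct behaviour label
#'   (population-aggregated), one column per identity; a cell is 1 iff any
#'   participant linked that behaviour to that identity.
#'
#' Rows that are all-zero after restricting columns to `retained` are dropped:
#' they carry no association information and would freeze the swap chain used
#' by the permutation null.
#'
#' @param x A `survey_data` object.
#' @param kind One of `"identity_by_identity"`, `"behaviour_by_identity"`,
#'   `"identity_by_behaviour"`.
#' @param retained Optional character vector of item labels to keep as
#'   columns (e.g. from [filter_items()] on this matrix's column totals via
#'   [occurrence_counts()]). `NULL` keeps the full vocabulary.
#' @return An `occurrence_matrix`: a binary integer matrix with sample row
#'   names and item column names, and a `kind` attribute.
#' @examples
#' s <- as_survey(data.frame(
#'   participant_id = c("p1", "p1", "p2", "p3", "p3"),
#'   identity = c("a", "b", "a", "b", "c"),
#'   behaviour = ""
#' ))
#' build_occurrence(s, "identity_by_identity")
#' @export
build_occurrence <- function(x,
                             kind = c("identity_by_identity",
                                      "behaviour_by_identity",
                                      "identity_by_behaviour"),
                             retained = NULL) {
  stopifnot(inherits(x, "survey_data"))
  kind <- match.arg(kind)

  pairs <- switch(kind,
    identity_by_identity = {
      d <- unique(x[, c("participant_id", "identity")])
      data.frame(sample = d$participant_id, item = d$identity)
    },
    behaviour_by_identity = {
      d <- unique(x[x$behaviour != "", ])
      data.frame(sample = paste(d$participant_id, d$identity, sep = ":"),
                 item = d$behaviour)
    },
    identity_by_behaviour = {
      d <- unique(x[x$behaviour != "", c("identity", "behaviour")])
      data.frame(sample = d$behaviour, item = d$identity)
    }
  )

  if (!is.null(retained)) {
    vocab <- unique(pairs$item)
    unknown <- setdiff(retained, vocab)
    if (length(unknown) > 0L) {
      stop("retained labels not in the ", kind, " vocabulary: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    pairs <- pairs[pairs$item %in% retained, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    stop("degenerate input: no occurrences left for kind ", kind)
  }

  rows <- sort(unique(pairs$sample))
  cols <- sort(unique(pairs$item))
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(pairs$sample, rows), match(pairs$item, cols))] <- 1L

  # all-zero rows cannot arise here (every row has >= 1 retained item by
  # construction), but all-zero columns can't either; assert both anyway
  stopifnot(all(rowSums(m) > 0L), all(colSums(m) > 0L))
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop("degenerate input: empty occurrence matrix for kind ", kind)
  }
  structure(m, kind = kind, class = c("occurrence_matrix", class(m)))
}

#' Column totals of an occurrence matrix
#'
#' The per-item occurrence counts used by the node-frequency filter: the
#' number of samples in which each item appears.
#'
#' @param occ An `occurrence_matrix`.
#' @return Named integer vector of column totals.
#' @export
occurrence_counts <- function(occ) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  cs <- colSums(occ)
  storage.mode(cs) <- "integer"
  cs
}

#' Apply the node-frequency filter to an occurrence matrix
#'
#' Retains columns whose occurrence count (column total) is strictly greater
#' than `min_count`, then drops rows left all-zero. Errors if no columns
#' survive.
#'
#' @param occ An `occurrence_matrix`.
#' @param min_count Strict threshold; the default 3 retains nodes observed
#'   more than three times.
#' @return A filtered `occurrence_matrix`.
#' @export
filter_occurrence <- function(occ, min_count = 3) {
  stopifnot(inherits(occ, "occurrence_matrix"), min_count >= 0)
  keep_cols <- colSums(occ) > min_count
  if (!any(keep_cols)) {
    stop("degenerate input: no nodes survive filter at threshold ", min_count)
  }
  m <- occ[, keep_cols, drop = FALSE]
  m <- m[rowSums(m) > 0L, , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("degenerate input: no samples left after filtering")
  }
  structure(m, kind = attr(occ, "kind"),
            class = c("occurrence_matrix", "matrix", "array"))
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("Occurrence matrix (", attr(x, "kind"), "): ",
      nrow(x), " samples x ", ncol(x), " items, ",
      sum(x), " incidences\n", sep = "")
  invisible(x)
}

#' Write an occurrence matrix to CSV
#'
#' @param occ An `occurrence_matrix`.
#' @param path Output path.
#' @param sparse If `TRUE`, writes a triplet CSV (`sample,item,value`) of the
#'   nonzero cells instead of the dense matrix with headers.
#' @return `path`, invisibly.
#' @export
write_occurrence <- function(occ, path, sparse = FALSE) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  if (sparse) {
    idx <- which(occ == 1L, arr.ind = TRUE)
    trip <- data.frame(sample = rownames(occ)[idx[, 1]],
                       item = colnames(occ)[idx[, 2]],
                       value = 1L)
    utils::write.csv(trip, path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(unclass(occ)), path, row.names = TRUE)
  }
  invisible(path)
}
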