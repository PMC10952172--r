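#' Run the full co-occurrence network analysis
#'
#' One-call orchestration of the whole analysis, in the standard order:
#' build each requested occurrence matrix, apply the node-frequency filter,
#' compute the SRI association network, structural metrics (density, CV,
#' betweenness, walktrap modularity), the datastream permutation test (global
#' CV and per-dyad preferred/avoided classification), and a Mantel
#' correlation between the identity-by-identity and identity-by-behaviour
#' networks when both are built.
#'
#' @param input A `survey_data` object, a path to a long CSV (read with
#'   [read_survey()]), or a [generator_config()] (a synthetic dataset is then
#'   generated).
#' @param networks Which network kinds to build.
#' @param min_count Node-frequency filter threshold (strict; default 3).
#' @param perm A [perm_config()] for the permutation tests.
#' @param weight_mode Betweenness convention, see [node_betweenness()].
#' @param include_zeros CV dyad set, see [cv_edge_weights()].
#' @param steps Walktrap walk length.
#' @param mantel_permutations Permutations for the Mantel test.
#' @param seed Optional master seed; set once before any random stage so a
#'   rerun with the same seed and options reproduces every number.
#' @param out_dir Optional output directory; when given, edge lists, metrics,
#'   dyad tables, null distributions, Mantel result and a manifest are
#'   written there as CSV/JSON.
#' @param dyads Compute per-dyad tests (default `TRUE`).
#' @return A `cooc_pipeline` list: per network kind `counts_unfiltered`,
#'   `n_nodes_unfiltered`, `n_nodes_filtered`, `network`, `metrics`,
#'   `permutation`; plus `mantel`, `summary` (of the input survey) and
#'   `manifest`.
#' @export
run_cooc_pipeline <- function(input,
                              networks = c("identity_by_identity",
                                           "behaviour_by_identity",
                                           "identity_by_behaviour"),
                              min_count = 3,
                              perm = perm_config(),
                              weight_mode = "cost",
                              include_zeros = TRUE,
                              steps = 4,
                              mantel_permutations = 10000,
                              seed = NULL,
                              out_dir = NULL,
                              dyads = TRUE) {
  networks <- match.arg(networks, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)

  survey <- if (inherits(input, "survey_data")) {
    input
  } else if (inherits(input, "generator_config")) {
    generate_survey(input)
  } else if (is.character(input) && length(input) == 1L) {
    read_survey(input)
  } else {
    stop("validation error: input must be a survey_data, a generator_config ",
         "or a file path")
  }

  perm$include_zero_pairs <- include_zeros
  results <- list()
  for (kind in networks) {
    stage <- list(kind = kind)
    occ_full <- build_occurrence(survey, kind)
    counts <- occurrence_counts(occ_full)
    stage$counts_unfiltered <- counts
    stage$n_nodes_unfiltered <- ncol(occ_full)
    retained <- filter_items(counts, min_count)
    if (length(retained) == 0L) {
      stage$n_nodes_filtered <- 0L
      stage$note <- paste0("no nodes survive filter at threshold ", min_count)
      results[[kind]] <- stage
      next
    }
    occ <- build_occurrence(survey, kind, retained = retained)
    stage$n_nodes_filtered <- ncol(occ)
    stage$network <- assoc_network(occ)
    stage$metrics <- network_metrics(stage$network, weight_mode = weight_mode,
                                     include_zeros = include_zeros,
                                     steps = steps)
    stage$permutation <- permutation_test(occ, config = perm, dyads = dyads)
    results[[kind]] <- stage
  }

  mantel <- NULL
  if (!is.null(results$identity_by_identity$network) &&
      !is.null(results$identity_by_behaviour$network)) {
    mantel <- tryCatch(
      mantel_test(results$identity_by_identity$network,
                  results$identity_by_behaviour$network,
                  n_permutations = mantel_permutations),
      error = function(e) {
        warning("Mantel stage skipped: ", conditionMessage(e))
        NULL
      })
  }

  manifest <- list(
    package = "coocnet",
    version = as.character(utils::packageVersion("coocnet")),
    seed = seed,
    min_count = min_count,
    networks = networks,
    weight_mode = weight_mode,
    include_zeros = include_zeros,
    walktrap_steps = steps,
    permutation = unclass(perm),
    mantel_permutations = mantel_permutations,
    nodes = lapply(results, function(s)
      list(unfiltered = s$n_nodes_unfiltered, filtered = s$n_nodes_filtered))
  )

  out <- structure(list(networks = results, mantel = mantel,
                        summary = summary(survey), manifest = manifest),
                   class = "cooc_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' Write pipeline outputs to a directory
#'
#' Emits, per network: edge list, betweenness table, dyad table and null CV
#' distribution as CSV, metrics as JSON; plus the Mantel result, the survey
#' summary and a manifest (all options and seeds) as JSON. Every number shown
#' by the print method appears in one of these files.
#'
#' @param x A `cooc_pipeline` result.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(x, out_dir) {
  stopifnot(inherits(x, "cooc_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(obj, file) {
    jsonlite::write_json(obj, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  for (kind in names(x$networks)) {
    s <- x$networks[[kind]]
    utils::write.csv(
      data.frame(label = names(s$counts_unfiltered),
                 count = as.integer(s$counts_unfiltered)),
      file.path(out_dir, paste0(kind, "_counts.csv")), row.names = FALSE)
    if (is.null(s$network)) {
      wj(list(kind = kind, note = s$note), paste0(kind, "_metrics.json"))
      next
    }
    utils::write.csv(edge_list(s$network),
                     file.path(out_dir, paste0(kind, "_edges.csv")),
                     row.names = FALSE)
    utils::write.csv(betweenness_table(s$network,
                                       s$metrics$options$weight_mode),
                     file.path(out_dir, paste0(kind, "_betweenness.csv")),
                     row.names = FALSE)
    m <- s$metrics
    wj(list(kind = kind,
            n_nodes_unfiltered = s$n_nodes_unfiltered,
            n_nodes_filtered = s$n_nodes_filtered,
            n_edges = m$n_edges,
            density = m$density,
            cv_edge_weights = m$cv_edge_weights,
            modularity = m$partition$modularity,
            n_modules = m$partition$n_modules,
            global_p = s$permutation$global_p,
            observed_cv = s$permutation$observed_cv,
            n_frozen = s$permutation$n_frozen,
            options = m$options),
       paste0(kind, "_metrics.json"))
    if (!is.null(s$permutation$dyads)) {
      utils::write.csv(s$permutation$dyads,
                       file.path(out_dir, paste0(kind, "_dyads.csv")),
                       row.names = FALSE)
    }
    utils::write.csv(data.frame(null_cv = s$permutation$null_cv),
                     file.path(out_dir, paste0(kind, "_null_cv.csv")),
                     row.names = FALSE)
  }
  if (!is.null(x$mantel)) {
    wj(list(r = x$mantel$r, p = x$mantel$p,
            n_shared_nodes = x$mantel$n_shared_nodes,
            n_permutations = x$mantel$n_permutations),
       "mantel.json")
    utils::write.csv(data.frame(node = x$mantel$shared_nodes),
                     file.path(out_dir, "mantel_shared_nodes.csv"),
                     row.names = FALSE)
  }
  wj(list(n_participants = x$summary$n_participants,
          identities_per_participant =
            as.list(x$summary$identities_per_participant),
          behaviours_per_identity =
            as.list(x$summary$behaviours_per_identity),
          behaviours_per_person =
            as.list(x$summary$behaviours_per_person)),
     "survey_summary.json")
  wj(x$manifest, "manifest.json")
  invisible(out_dir)
}

#' @export
print.cooc_pipeline <- function(x, ...) {
  cat("Co-occurrence network pipeline\n")
  for (kind in names(x$networks)) {
    s <- x$networks[[kind]]
    cat("\n== ", kind, " ==\n", sep = "")
    cat("  nodes: ", s$n_nodes_unfiltered, " unfiltered -> ",
        s$n_nodes_filtered, " filtered\n", sep = "")
    if (is.null(s$network)) {
      cat(" ", s$note, "\n")
      next
    }
    cat("  density: ", round(s$metrics$density, 3),
        "  modularity: ", round(s$metrics$partition$modularity, 3),
        "  CV: ", round(s$metrics$cv_edge_weights, 3), "\n", sep = "")
    cat("  global p (CV vs null): ",
        format.pval(s$permutation$global_p, digits = 3), "\n", sep = "")
    if (!is.null(s$permutation$dyads)) {
      tab <- table(factor(s$permutation$dyads$class,
                          levels = c("preferred", "neutral", "avoided")))
      cat("  dyads: ", tab[["preferred"]], " preferred / ",
          tab[["avoided"]], " avoided\n", sep = "")
    }
  }
  if (!is.null(x$mantel)) {
    cat("\nMantel (identity_by_identity vs identity_by_behaviour): r = ",
        round(x$mantel$r, 4), ", n = ", x$mantel$n_shared_nodes,
        ", p = ", format.pval(x$mantel$p, digits = 3), "\n", sep = "")
  }
  invisible(x)
}
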