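#' Exact-match reconciliation of KG predictions and regression results
#'
#' A match requires the same FRD, the same destination/feature CURIE, a KG
#' prediction score above the threshold, and a regression tier of
#' significant or suggestive. Matching is by CURIE identity only: no credit
#' is given for ontologically related (ancestor/descendant) terms, though a
#' `related_matches` column is reported separately for exploration.
#'
#' @param kg_predictions `link_predictions` data frame (all FRDs together).
#' @param regression_results named list of `regression_result` objects,
#'   keyed by FRD CURIE.
#' @param ontologies optional ontology list enabling the related-match
#'   column.
#' @return List of class `comparison_report`: `per_frd` (data frame with
#'   `frd`, `n_kg_pass`, `n_reg_significant`, `n_reg_suggestive`,
#'   `n_exact_matches`), `matches` (named list of matched CURIEs per FRD),
#'   `related` and `totals`.
#' @export
exact_match <- function(kg_predictions, regression_results,
                        ontologies = NULL) {
  kg_frds <- unique(kg_predictions$source)
  reg_frds <- names(regression_results)
  only_one <- c(setdiff(kg_frds, reg_frds), setdiff(reg_frds, kg_frds))
  if (length(only_one) > 0)
    warning("FRD(s) present in one result stream only: ",
            paste(only_one, collapse = ", "))
  frds <- union(kg_frds, reg_frds)
  matches <- list()
  related <- list()
  rows <- lapply(frds, function(frd) {
    kg_pass <- kg_predictions$destination[
      kg_predictions$source == frd & kg_predictions$passed_threshold]
    reg <- regression_results[[frd]]
    sig <- if (is.null(reg)) character(0)
           else reg$feature[reg$tier == "significant"]
    sug <- if (is.null(reg)) character(0)
           else reg$feature[reg$tier == "suggestive"]
    tiered <- union(sig, sug)
    matches[[frd]] <<- sort(intersect(kg_pass, tiered))
    rel <- character(0)
    if (!is.null(ontologies) && length(tiered) > 0 && length(kg_pass) > 0) {
      for (curie in setdiff(tiered, matches[[frd]])) {
        fam <- tryCatch(get_ancestors(curie, ontologies),
                        error = function(e) character(0))
        if (length(intersect(fam, kg_pass)) > 0) rel <- c(rel, curie)
      }
    }
    related[[frd]] <<- sort(rel)
    data.frame(frd = frd, n_kg_pass = length(kg_pass),
               n_reg_significant = length(sig),
               n_reg_suggestive = length(sug),
               n_exact_matches = length(matches[[frd]]))
  })
  per_frd <- do.call(rbind, rows)
  totals <- list(n_kg_pass = sum(per_frd$n_kg_pass),
                 n_reg_significant = sum(per_frd$n_reg_significant),
                 n_reg_suggestive = sum(per_frd$n_reg_suggestive),
                 n_exact_matches = sum(per_frd$n_exact_matches))
  structure(list(per_frd = per_frd, matches = matches, related = related,
                 totals = totals),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  print(x$per_frd)
  cat(sprintf("total exact matches: %d\n", x$totals$n_exact_matches))
  invisible(x)
}

#' Render a machine- and human-readable run summary
#'
#' Collects graph statistics, the achieved split fraction, held-out AUROC,
#' per-FRD comparison counts, seeds, and the defaults in force into one
#' JSON-serialisable list; a plain-text rendering is attached as attribute
#' `"text"`. The summary is a pure function of its inputs.
#'
#' @param report a `comparison_report`.
#' @param graph_stats a `kg_stats`.
#' @param auroc_value held-out AUROC.
#' @param config the `synthetic_config` (or any list of run parameters).
#' @param split optional `edge_split` for the achieved fraction.
#' @param path optional file to write the JSON to.
#' @return The summary list, invisibly when `path` is given.
#' @export
render_summary <- function(report, graph_stats, auroc_value, config,
                           split = NULL, path = NULL) {
  summary <- list(
    seed = config$seed,
    graph = unclass(graph_stats),
    split = if (is.null(split)) NULL else
      list(requested = split$test_fraction_requested,
           achieved = split$test_fraction_achieved),
    test_auroc = auroc_value,
    per_frd = report$per_frd,
    exact_matches = report$matches,
    totals = report$totals,
    defaults = list(edge_operator = "hadamard", neg_ratio = 1,
                    rf_trees = 501, rf_max_depth = 15,
                    score_threshold = 0.8, alpha_mix = 0.5,
                    tiers = c(significant = 0.005, suggestive = 0.05)))
  lines <- c(
    sprintf("seed: %s", summary$seed),
    sprintf("graph: %d nodes, %d edges, %d components",
            graph_stats$n_nodes, graph_stats$n_edges,
            graph_stats$n_components),
    sprintf("test AUROC: %.3f", auroc_value),
    sprintf("total exact matches: %d", report$totals$n_exact_matches))
  attr(summary, "text") <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(summary))
  }
  summary
}
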