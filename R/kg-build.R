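#' Construct a knowledge-graph object
#'
#' A heterogeneous directed multigraph: `nodes` is a data frame of `id`,
#' `category`, `name`; `edges` a data frame of `subject`, `predicate`,
#' `object`, `provenance`. Validation enforces that every edge endpoint is a
#' known node and that no (subject, predicate, object) triple is duplicated.
#'
#' @param nodes,edges data frames as above.
#' @param validate check invariants (default `TRUE`).
#' @return Object of class `exposome_kg`.
#' @export
kg_new <- function(nodes, edges, validate = TRUE) {
  kg <- structure(list(nodes = nodes, edges = edges), class = "exposome_kg")
  if (validate) {
    endpoints <- c(edges$subject, edges$object)
    if (!all(endpoints %in% nodes$id))
      stop_config("edge endpoints missing from the node table")
    if (anyDuplicated(nodes$id))
      stop_config("duplicate node ids")
    triple <- paste(edges$subject, edges$predicate, edges$object)
    if (anyDuplicated(triple))
      stop_config("duplicate (subject, predicate, object) triples")
  }
  kg
}

#' @export
print.exposome_kg <- function(x, ...) {
  cat(sprintf("<exposome_kg> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$category))
  invisible(x)
}

# undirected igraph view used for all connectivity computations
kg_igraph <- function(kg) {
  g <- igraph::graph_from_data_frame(
    kg$edges[, c("subject", "object")], directed = FALSE,
    vertices = kg$nodes$id)
  g
}

#' Transform survey responses into knowledge-graph edges
#'
#' Emits one directed edge per positive response: `Person:<id>` linked to the
#' question's ontology term with a predicate determined by the term's domain
#' (`has_phenotype`, `has_disease`, `affected_by`, `consumes`, `exposed_to`,
#' `undergone`). `"no"` answers and missing cells create no edge. Free-text
#' answers are resolved with [map_free_text()]; every free-text response is
#' logged to a review table (attribute `"review"`), and an audit map linking
#' each edge back to the (respondent, question) cell that produced it is kept
#' as attribute `"audit"`.
#'
#' @param table survey response table.
#' @param keys translation keys.
#' @param ontologies ontology list the keys refer to.
#' @return Data frame of survey edges (`subject`, `predicate`, `object`,
#'   `provenance = "survey"`), with `review` and `audit` attributes.
#' @export
transform_responses <- function(table, keys, ontologies) {
  missing_q <- setdiff(keys$question_id, names(table))
  if (length(missing_q) > 0)
    stop_config("keys reference unknown question ids: %s",
                paste(missing_q, collapse = ", "))
  person <- paste0("Person:", table$respondent_id)
  sub <- pred <- obj <- resp <- qid <- character(0)
  add <- function(rows, curie, predicate, question) {
    sub <<- c(sub, person[rows])
    pred <<- c(pred, rep(predicate, length(rows)))
    obj <<- c(obj, rep(curie, length(rows)))
    resp <<- c(resp, table$respondent_id[rows])
    qid <<- c(qid, rep(question, length(rows)))
  }

  bin <- keys[keys$question_type == "binary", ]
  for (i in seq_len(nrow(bin))) {
    cell <- table[[bin$question_id[i]]]
    add(which(!is.na(cell) & cell == "yes"), bin$curie[i], bin$predicate[i],
        bin$question_id[i])
  }
  cat_keys <- keys[keys$question_type == "categorical", ]
  for (i in seq_len(nrow(cat_keys))) {
    cell <- table[[cat_keys$question_id[i]]]
    add(which(!is.na(cell) & cell == cat_keys$option_label[i]),
        cat_keys$curie[i], cat_keys$predicate[i], cat_keys$question_id[i])
  }

  review <- data.frame(respondent_id = character(),
                       question_id = character(),
                       raw_text = character(), status = character())
  ft <- keys[keys$question_type == "freetext", ]
  if (nrow(ft) > 0) {
    lex <- build_lexicon(ontologies)
    for (i in seq_len(nrow(ft))) {
      cell <- table[[ft$question_id[i]]]
      answered <- which(!is.na(cell) & nzchar(trimws(cell)))
      for (r in answered) {
        m <- map_free_text(cell[r], lex)
        status <- if (m$curie == "UNMAPPED") "unmapped"
                  else if (m$ambiguous) "ambiguous"
                  else paste0("mapped_", m$match_kind)
        review <- rbind(review, data.frame(
          respondent_id = table$respondent_id[r],
          question_id = ft$question_id[i],
          raw_text = cell[r], status = status))
        if (m$curie != "UNMAPPED")
          add(r, m$curie, ft$predicate[i], ft$question_id[i])
      }
    }
  }

  edges <- data.frame(subject = sub, predicate = pred, object = obj,
                      provenance = rep("survey", length(sub)))
  audit <- data.frame(respondent_id = resp, question_id = qid)
  keep <- !duplicated(paste(edges$subject, edges$predicate, edges$object))
  edges <- edges[keep, , drop = FALSE]
  audit <- audit[keep, , drop = FALSE]
  rownames(edges) <- rownames(audit) <- NULL
  attr(edges, "review") <- review
  attr(edges, "audit") <- audit
  # every respondent is a node even without positive answers; such persons
  # end up as singletons and are dropped with the largest component
  attr(edges, "persons") <- person
  edges
}

#' Merge survey edges, ontologies and supplemental links into one KG
#'
#' Nodes are deduplicated by id with categories assigned from the CURIE
#' prefix; ontology is_a hierarchies and supplemental link tables are merged
#' wholesale; triples are deduplicated across provenances.
#'
#' @param survey_edges edges from [transform_responses()].
#' @param ontologies ontology list.
#' @param supplemental supplemental link table (may be `NULL`).
#' @return An `exposome_kg`.
#' @export
merge_graphs <- function(survey_edges, ontologies = list(),
                         supplemental = NULL) {
  ont_edges <- do.call(rbind, c(list(
    data.frame(subject = character(), predicate = character(),
               object = character(), provenance = character())),
    lapply(ontologies, function(o) {
      if (nrow(o$edges) == 0) return(NULL)
      data.frame(subject = o$edges$child, predicate = "is_a",
                 object = o$edges$parent, provenance = "ontology")
    })))
  supp_edges <- if (is.null(supplemental) || nrow(supplemental) == 0) {
    NULL
  } else {
    data.frame(subject = supplemental$subject,
               predicate = supplemental$predicate,
               object = supplemental$object, provenance = "supplemental")
  }
  edges <- rbind(survey_edges[, c("subject", "predicate", "object",
                                  "provenance")],
                 ont_edges, supp_edges)
  edges <- edges[!duplicated(paste(edges$subject, edges$predicate,
                                   edges$object)), , drop = FALSE]
  rownames(edges) <- NULL

  term_nodes <- do.call(rbind, c(list(
    data.frame(id = character(), name = character())),
    lapply(ontologies, function(o)
      data.frame(id = o$terms$curie, label = o$terms$label))))
  names(term_nodes) <- c("id", "name")
  persons <- attr(survey_edges, "persons") %||% character(0)
  extra_ids <- setdiff(unique(c(edges$subject, edges$object, persons)),
                       term_nodes$id)
  nodes <- rbind(term_nodes,
                 data.frame(id = extra_ids, name = extra_ids))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- data.frame(id = nodes$id, category = node_category(nodes$id),
                      name = nodes$name)
  rownames(nodes) <- NULL
  kg_new(nodes, edges)
}

#' Merge two knowledge graphs
#'
#' Union of nodes (by id) and edges (by triple). Node ids present in both
#' graphs with different categories raise a merge error. Merging a graph
#' with itself returns an identical graph.
#'
#' @param a,b `exposome_kg` objects.
#' @return Merged `exposome_kg`.
#' @export
merge_kg <- function(a, b) {
  nodes <- rbind(a$nodes, b$nodes)
  conflict <- stats::aggregate(category ~ id, nodes,
                               function(x) length(unique(x)))
  if (any(conflict$category > 1))
    stop_config("node ids with conflicting categories: %s",
                paste(conflict$id[conflict$category > 1], collapse = ", "))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(match(nodes$id, c(a$nodes$id, b$nodes$id))), ,
                 drop = FALSE]
  edges <- rbind(a$edges, b$edges)
  edges <- edges[!duplicated(paste(edges$subject, edges$predicate,
                                   edges$object)), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  kg_new(nodes, edges)
}

#' Extract the largest connected component
#'
#' Connectivity is computed on the undirected view of the graph. Returns the
#' induced subgraph of the largest (weakly) connected component along with
#' the number and fraction of person nodes that were removed.
#'
#' @param kg an `exposome_kg`.
#' @return List with `kg` (the component subgraph), `removed_persons` and
#'   `removed_fraction` (of all person nodes; 0 when there are none).
#' @export
largest_component <- function(kg) {
  if (nrow(kg$nodes) == 0) stop_config("empty graph")
  comp <- igraph::components(kg_igraph(kg))
  keep_comp <- which.max(comp$csize)
  keep_ids <- kg$nodes$id[comp$membership[kg$nodes$id] == keep_comp]
  nodes <- kg$nodes[kg$nodes$id %in% keep_ids, , drop = FALSE]
  edges <- kg$edges[kg$edges$subject %in% keep_ids &
                      kg$edges$object %in% keep_ids, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  persons <- kg$nodes$id[kg$nodes$category == "person"]
  removed <- sum(!(persons %in% keep_ids))
  list(kg = kg_new(nodes, edges),
       removed_persons = removed,
       removed_fraction = if (length(persons) == 0) 0
                          else removed / length(persons))
}

#' Knowledge-graph summary statistics
#'
#' Node, edge, connected-component and singleton counts plus the sizes of the
#' largest and smallest components, all on the undirected view.
#'
#' @param kg an `exposome_kg`.
#' @return List of class `kg_stats`.
#' @export
graph_stats <- function(kg) {
  if (nrow(kg$nodes) == 0) {
    return(structure(list(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                          n_singletons = 0L, largest_size = 0L,
                          smallest_size = 0L), class = "kg_stats"))
  }
  comp <- igraph::components(kg_igraph(kg))
  structure(list(
    n_nodes = nrow(kg$nodes),
    n_edges = nrow(kg$edges),
    n_components = comp$no,
    n_singletons = sum(comp$csize == 1),
    largest_size = max(comp$csize),
    smallest_size = min(comp$csize)), class = "kg_stats")
}

#' @export
print.kg_stats <- function(x, ...) {
  cat(sprintf(paste0("%d nodes, %d edges, %d components ",
                     "(%d singletons); largest %d, smallest %d\n"),
              x$n_nodes, x$n_edges, x$n_components, x$n_singletons,
              x$largest_size, x$smallest_size))
  invisible(x)
}

#' Write / read a knowledge graph as KGX-style TSV
#'
#' `nodes.tsv` has columns `id`, `category`, `name`; `edges.tsv` has
#' `subject`, `predicate`, `object`, `provenance`. The round trip is
#' lossless.
#'
#' @param kg an `exposome_kg`.
#' @param dir directory receiving (or holding) `nodes.tsv` and `edges.tsv`.
#' @export
write_kgx <- function(kg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(kg$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(kg$edges, file.path(dir, "edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_kgx
#' @export
read_kgx <- function(dir) {
  nodes <- read.delim(file.path(dir, "nodes.tsv"), colClasses = "character")
  edges <- read.delim(file.path(dir, "edges.tsv"), colClasses = "character")
  kg_new(nodes, edges)
}
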