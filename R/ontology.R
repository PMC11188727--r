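#' Write / read an ontology as OBO-graph JSON
#'
#' Serialises an `ontology_graph` in the OBO-graph JSON shape: `nodes` with
#' `id`, `lbl` and a `meta$synonyms` list, and `edges` with `sub`, `pred`
#' (always `"is_a"`) and `obj`.
#'
#' @param ontology an `ontology_graph`.
#' @param path file path.
#' @return `read_obograph_json` returns an `ontology_graph`.
#' @export
write_obograph_json <- function(ontology, path) {
  nodes <- lapply(seq_len(nrow(ontology$terms)), function(i) {
    curie <- ontology$terms$curie[i]
    node <- list(id = curie, lbl = ontology$terms$label[i])
    syns <- ontology$synonyms[[curie]]
    if (length(syns) > 0)
      node$meta <- list(synonyms = lapply(syns, function(s)
        list(pred = "hasExactSynonym", val = s)))
    node
  })
  edges <- lapply(seq_len(nrow(ontology$edges)), function(i)
    list(sub = ontology$edges$child[i], pred = "is_a",
         obj = ontology$edges$parent[i]))
  doc <- list(graphs = list(list(id = ontology$prefix, nodes = nodes,
                                 edges = edges)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_obograph_json
#' @export
read_obograph_json <- function(path) {
  doc <- jsonlite::read_json(path)
  g <- doc$graphs[[1]]
  curies <- vapply(g$nodes, function(n) n$id, "")
  labels <- vapply(g$nodes, function(n) n$lbl, "")
  synonyms <- lapply(g$nodes, function(n) {
    syns <- n$meta$synonyms
    if (is.null(syns)) character(0)
    else vapply(syns, function(s) s$val, "")
  })
  names(synonyms) <- curies
  edges <- if (length(g$edges) == 0) {
    data.frame(child = character(), parent = character())
  } else {
    data.frame(child = vapply(g$edges, function(e) e$sub, ""),
               parent = vapply(g$edges, function(e) e$obj, ""))
  }
  prefix <- curie_prefix(curies[1])
  structure(list(domain = g$id %||% prefix, prefix = prefix,
                 terms = data.frame(curie = curies, label = labels),
                 synonyms = synonyms, edges = edges),
            class = "ontology_graph")
}

#' Write / read translation keys as TSV
#'
#' @param keys translation-key data frame.
#' @param path file path.
#' @export
write_translation_keys <- function(keys, path) {
  write.table(keys, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_translation_keys
#' @export
read_translation_keys <- function(path) {
  keys <- read.delim(path, colClasses = "character")
  for (col in c("option_label", "curie"))
    keys[[col]][is.na(keys[[col]])] <- ""
  keys
}

#' Normalise a label for lexical matching
#'
#' Case-folds, strips punctuation, and collapses runs of whitespace. The
#' function is idempotent, so already-normalised text passes through
#' unchanged.
#'
#' @param text character vector.
#' @return Normalised character vector.
#' @examples
#' normalize_label("Omeprazole (20mg)") # "omeprazole 20mg"
#' @export
normalize_label <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z0-9 ]+", " ", text)
  text <- gsub("\\s+", " ", text)
  trimws(text)
}

token_sort <- function(text) {
  vapply(strsplit(text, " ", fixed = TRUE), function(tok)
    paste(sort(tok), collapse = " "), "")
}

# Flat lookup tables over an ontology list, built once and cached on the
# list via attribute when used through map_free_text repeatedly.
build_lexicon <- function(ontologies) {
  rows <- lapply(ontologies, function(o) {
    syn_counts <- lengths(o$synonyms[o$terms$curie])
    data.frame(
      curie = c(o$terms$curie, rep(o$terms$curie, syn_counts)),
      text = c(o$terms$label, unlist(o$synonyms[o$terms$curie],
                                     use.names = FALSE)),
      kind = c(rep("label", nrow(o$terms)),
               rep("synonym", sum(syn_counts))))
  })
  lex <- do.call(rbind, rows)
  rownames(lex) <- NULL
  lex$norm <- normalize_label(lex$text)
  lex$tokens <- token_sort(lex$norm)
  lex
}

#' Map a free-text response to an ontology term
#'
#' Lexical resolution of free-text survey answers, emulating a
#' named-entity-recognition step. Match precedence: exact normalised label,
#' then exact normalised synonym, then token-sorted label match (so word
#' order is ignored). Ties within a precedence level are broken by the
#' lexicographically smallest CURIE and flagged ambiguous. No fuzzy
#' matching is attempted; unmatched text returns `"UNMAPPED"`.
#'
#' @param response a single free-text answer.
#' @param ontologies ontology list (or a prebuilt lexicon from
#'   `build_lexicon`).
#' @return List with `curie` (`"UNMAPPED"` when no match), `match_kind`
#'   (`"label"`, `"synonym"`, `"token_sorted"` or `"none"`) and `ambiguous`.
#' @export
map_free_text <- function(response, ontologies) {
  lex <- if (is.data.frame(ontologies)) ontologies
         else build_lexicon(ontologies)
  norm <- normalize_label(response)
  if (is.na(norm) || !nzchar(norm))
    return(list(curie = "UNMAPPED", match_kind = "none", ambiguous = FALSE))
  pick <- function(hits, kind) {
    curies <- sort(unique(lex$curie[hits]))
    list(curie = curies[1], match_kind = kind,
         ambiguous = length(curies) > 1)
  }
  hits <- which(lex$norm == norm & lex$kind == "label")
  if (length(hits)) return(pick(hits, "label"))
  hits <- which(lex$norm == norm & lex$kind == "synonym")
  if (length(hits)) return(pick(hits, "synonym"))
  hits <- which(lex$tokens == token_sort(norm) & lex$kind == "label")
  if (length(hits)) return(pick(hits, "token_sorted"))
  list(curie = "UNMAPPED", match_kind = "none", ambiguous = FALSE)
}

#' Transitive is_a ancestors of a term
#'
#' @param curie a known term CURIE.
#' @param ontology an `ontology_graph`, or a list of them (searched by
#'   prefix).
#' @return Character vector of ancestor CURIEs, excluding the term itself.
#' @export
get_ancestors <- function(curie, ontology) {
  if (!inherits(ontology, "ontology_graph")) {
    ontology <- ontology[[curie_prefix(curie)]]
    if (is.null(ontology)) stop_config("unknown CURIE prefix: %s", curie)
  }
  if (!curie %in% ontology$terms$curie)
    stop_config("unknown CURIE: %s", curie)
  anc <- character(0)
  frontier <- curie
  while (length(frontier) > 0) {
    parents <- ontology$edges$parent[ontology$edges$child %in% frontier]
    frontier <- setdiff(parents, anc)
    anc <- union(anc, frontier)
  }
  setdiff(anc, curie)
}

#' Write a free-text review file
#'
#' Records every free-text response and its mapping status as TSV so that
#' ambiguous or unmapped answers can be reviewed manually, mirroring the
#' supplemental curation step a fully automated pipeline cannot reproduce.
#'
#' @param review data frame with columns `respondent_id`, `question_id`,
#'   `raw_text`, `status`.
#' @param path file path.
#' @export
write_review_file <- function(review, path) {
  write.table(review, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
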