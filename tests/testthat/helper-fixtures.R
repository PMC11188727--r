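# Small in-code fixtures shared across test files.

# a hand-sized study: tiny ontologies, short cohort, same wiring as the
# full-scale simulation
small_study <- function(seed = 1, n = 300) {
  simulate_study(seed = seed, n_respondents = n,
                 ontology_sizes = c(HP = 25, MONDO = 15, CHEBI = 20,
                                    FOODON = 20, ECTO = 20, MAXO = 8))
}

# minimal two-ontology world with hand-written labels and synonyms, for
# lexical-mapping tests
lexicon_ontology <- function() {
  terms <- data.frame(
    curie = c("CHEBI:0000001", "CHEBI:0000002", "CHEBI:0000003"),
    label = c("lansoprazole", "omeprazole", "desiccated thyroid extract"))
  structure(list(
    domain = "chemical", prefix = "CHEBI", terms = terms,
    synonyms = list("CHEBI:0000001" = c("prevacid"),
                    "CHEBI:0000002" = character(0),
                    "CHEBI:0000003" = c("thyroid extract")),
    edges = data.frame(child = c("CHEBI:0000002", "CHEBI:0000003"),
                       parent = c("CHEBI:0000001", "CHEBI:0000001"))),
    class = "ontology_graph")
}

# toy knowledge graph from "a-b" strings (undirected sense, stored directed)
toy_kg <- function(edge_pairs, categories = NULL) {
  from <- vapply(strsplit(edge_pairs, "-", fixed = TRUE), `[`, "", 1)
  to <- vapply(strsplit(edge_pairs, "-", fixed = TRUE), `[`, "", 2)
  ids <- unique(c(from, to))
  cats <- if (is.null(categories)) setNames(rep("other", length(ids)), ids)
          else categories
  kg_new(data.frame(id = ids, category = unname(cats[ids]), name = ids),
         data.frame(subject = from, predicate = "linked", object = to,
                    provenance = "survey"))
}
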