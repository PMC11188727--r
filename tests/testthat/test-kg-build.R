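toy_keys <- function() {
  data.frame(
    question_id = c("Qb1", "Qb2", "Qc1", "Qc1", "Qt1"),
    question_type = c("binary", "binary", "categorical", "categorical",
                      "freetext"),
    option_label = c("", "", "lansoprazole", "omeprazole", ""),
    curie = c("HP:0000138", "MONDO:0006195", "CHEBI:0000001",
              "CHEBI:0000002", ""),
    predicate = c("has_phenotype", "has_disease", "affected_by",
                  "affected_by", "affected_by"),
    survey = c("health", "health", "internal", "internal", "internal"))
}

toy_ontologies <- function() {
  hp <- structure(list(domain = "phenotype", prefix = "HP",
    terms = data.frame(curie = "HP:0000138", label = "ovarian cyst"),
    synonyms = list("HP:0000138" = character(0)),
    edges = data.frame(child = character(), parent = character())),
    class = "ontology_graph")
  mondo <- structure(list(domain = "disease", prefix = "MONDO",
    terms = data.frame(curie = "MONDO:0006195", label = "uterine polyp"),
    synonyms = list("MONDO:0006195" = character(0)),
    edges = data.frame(child = character(), parent = character())),
    class = "ontology_graph")
  list(HP = hp, MONDO = mondo, CHEBI = lexicon_ontology())
}

toy_table <- function() {
  data.frame(
    respondent_id = sprintf("%07d", 1:5),
    sex = c("female", "female", "male", "female", "male"),
    completed_health = TRUE, completed_internal = TRUE,
    completed_external = TRUE,
    Qb1 = c("yes", "no", "no", NA, "yes"),
    Qb2 = c("no", "yes", "no", "no", NA),
    Qc1 = c("lansoprazole", NA, "omeprazole", "lansoprazole", "omeprazole"),
    Qt1 = c("Prevacid", "", "no such drug", NA, "omeprazole"))
}

test_that("positive responses become edges with domain predicates", {
  edges <- transform_responses(toy_table(), toy_keys(), toy_ontologies())
  # hand enumeration: Qb1 yes for 1,5; Qb2 yes for 2; Qc1 five minus one NA
  # = 4 option edges; Qt1 maps Prevacid -> lansoprazole (duplicate of
  # person 1's Qc1 triple) and omeprazole -> omeprazole (duplicate of
  # person 5's), so both deduplicate; "no such drug" stays unmapped
  expect_equal(nrow(edges), 2 + 1 + 4 + 0)
  expect_true(all(edges$provenance == "survey"))
  e1 <- edges[edges$subject == "Person:0000001", ]
  expect_setequal(paste(e1$predicate, e1$object),
                  c("has_phenotype HP:0000138",
                    "affected_by CHEBI:0000001"))
  # person 5: Qb1 yes, Qc1 omeprazole, Qt1 omeprazole (deduplicated triple)
  e5 <- edges[edges$subject == "Person:0000005", ]
  expect_setequal(paste(e5$predicate, e5$object),
                  c("has_phenotype HP:0000138",
                    "affected_by CHEBI:0000002"))
  review <- attr(edges, "review")
  expect_true("unmapped" %in%
                review$status[review$respondent_id == "0000003"])
  # audit map points every edge at exactly one producing cell
  audit <- attr(edges, "audit")
  expect_equal(nrow(audit), nrow(edges))
  tab <- toy_table()
  for (k in seq_len(nrow(edges))) {
    cell <- tab[tab$respondent_id == audit$respondent_id[k],
                audit$question_id[k]]
    expect_false(is.na(cell) || cell %in% c("no", ""))
  }
})

test_that("all-negative tables yield no survey edges and schema errors fire", {
  tab <- toy_table()
  tab$Qb1 <- "no"; tab$Qb2 <- "no"; tab$Qc1 <- NA; tab$Qt1 <- NA
  edges <- transform_responses(tab, toy_keys(), toy_ontologies())
  expect_equal(nrow(edges), 0)
  bad_keys <- rbind(toy_keys(),
                    data.frame(question_id = "Q_missing",
                               question_type = "binary", option_label = "",
                               curie = "HP:0000138",
                               predicate = "has_phenotype",
                               survey = "health"))
  expect_error(transform_responses(tab, bad_keys, toy_ontologies()),
               "unknown question")
})

test_that("merging deduplicates nodes and triples across sources", {
  edges <- transform_responses(toy_table(), toy_keys(), toy_ontologies())
  kg <- merge_graphs(edges, toy_ontologies())
  # one node per respondent even with several answers
  expect_equal(sum(kg$nodes$category == "person"), 5)
  expect_false(anyDuplicated(kg$nodes$id) > 0)
  expect_false(anyDuplicated(paste(kg$edges$subject, kg$edges$predicate,
                                   kg$edges$object)) > 0)
  # ontology is_a edges are merged wholesale
  expect_equal(sum(kg$edges$provenance == "ontology"),
               nrow(lexicon_ontology()$edges))
  # categories come from prefixes
  expect_equal(kg$nodes$category[kg$nodes$id == "CHEBI:0000001"],
               "chemical")
  expect_equal(kg$nodes$category[kg$nodes$id == "HP:0000138"], "phenotype")
  # merging a graph with itself is the identity
  expect_equal(merge_kg(kg, kg), kg)
  # conflicting categories refuse to merge
  other <- kg
  other$nodes$category[other$nodes$id == "HP:0000138"] <- "chemical"
  expect_error(merge_kg(kg, other), "conflicting")
})

test_that("node and edge counts equal set-union sizes on toy inputs", {
  a <- toy_kg(c("A-B", "B-C"))
  b <- toy_kg(c("B-C", "C-D"))
  m <- merge_kg(a, b)
  expect_setequal(m$nodes$id, c("A", "B", "C", "D"))
  expect_equal(nrow(m$edges), 3)
})

test_that("largest component extraction matches BFS labelling", {
  # connected toy graph passes through unchanged
  kg <- toy_kg(c("A-B", "B-C", "C-A"))
  lc <- largest_component(kg)
  expect_equal(lc$kg, kg)
  expect_equal(lc$removed_persons, 0)
  # triangle plus an isolated person: person removed and counted
  kg2 <- kg_new(rbind(kg$nodes,
                      data.frame(id = "Person:01", category = "person",
                                 name = "Person:01")),
                kg$edges)
  lc2 <- largest_component(kg2)
  expect_setequal(lc2$kg$nodes$id, c("A", "B", "C"))
  expect_equal(lc2$removed_persons, 1)
  expect_equal(lc2$removed_fraction, 1)

  # random graphs against the BFS oracle
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(10:60, 1)
    ids <- sprintf("N%03d", seq_len(n))
    m <- sample(5:80, 1)
    from <- ids[sample(n, m, replace = TRUE)]
    to <- ids[sample(n, m, replace = TRUE)]
    keep <- from != to & !duplicated(paste(from, to))
    kg3 <- kg_new(data.frame(id = ids, category = "other", name = ids),
                  data.frame(subject = from[keep], predicate = "linked",
                             object = to[keep], provenance = "survey"))
    membership <- oracle_components(ids, from[keep], to[keep])
    sizes <- table(membership)
    lc3 <- largest_component(kg3)
    expect_equal(nrow(lc3$kg$nodes), max(sizes))
    # the extracted component is itself connected
    mem2 <- oracle_components(lc3$kg$nodes$id, lc3$kg$edges$subject,
                              lc3$kg$edges$object)
    expect_equal(length(unique(mem2)), 1)
    st <- graph_stats(kg3)
    expect_equal(st$n_components, length(sizes))
    expect_equal(st$n_singletons, sum(sizes == 1))
    expect_equal(st$largest_size, max(sizes))
    expect_equal(st$smallest_size, min(sizes))
  }
})

test_that("graph statistics handle empty and hand-counted graphs", {
  empty <- kg_new(data.frame(id = character(), category = character(),
                             name = character()),
                  data.frame(subject = character(), predicate = character(),
                             object = character(), provenance = character()))
  st <- graph_stats(empty)
  expect_equal(st$n_nodes, 0)
  expect_equal(st$n_components, 0)
  # two triangles plus three singletons
  kg <- toy_kg(c("A-B", "B-C", "C-A", "D-E", "E-F", "F-D"))
  kg <- kg_new(rbind(kg$nodes,
                     data.frame(id = c("S1", "S2", "S3"),
                                category = "other",
                                name = c("S1", "S2", "S3"))),
               kg$edges)
  st2 <- graph_stats(kg)
  expect_equal(st2$n_components, 5)
  expect_equal(st2$n_singletons, 3)
  expect_equal(st2$largest_size, 3)
  expect_equal(st2$smallest_size, 1)
})

test_that("KGX TSV round-trips losslessly", {
  sim <- small_study(seed = 4, n = 50)
  edges <- transform_responses(sim$table, sim$keys, sim$ontologies)
  kg <- merge_graphs(edges, sim$ontologies, sim$supplemental)
  dir <- tempfile()
  write_kgx(kg, dir)
  back <- read_kgx(dir)
  expect_equal(back$nodes, kg$nodes)
  expect_equal(back$edges, kg$edges)
})
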