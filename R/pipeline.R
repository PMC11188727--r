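#' Run the knowledge-graph analysis arm
#'
#' Transforms positive survey responses into edges, merges them with the
#' ontologies and supplemental links, restricts to the largest connected
#' component, makes a connectivity-preserving 70/30 edge split, embeds the
#' training graph, trains the random-forest edge classifier, evaluates
#' held-out AUROC, then retrains on the full graph embedding and scores all
#' (FRD, candidate) links against the 0.8 threshold.
#'
#' Embedding defaults here are the simulation-scale configuration used for
#' synthetic cohorts (d = 10, 6 walks of 20 nodes, 4 epochs); see
#' [embed_kg()] for the larger method defaults. The default edge operator is
#' concatenation: on a heterogeneous person-term graph the plausibility of an
#' edge is driven by the identity and connectivity of its endpoints, which
#' symmetric operators such as the Hadamard product discard.
#'
#' @param sim a study list from [simulate_study()] (or any list with
#'   `table`, `keys`, `ontologies`, `supplemental`, `frd_curies`).
#' @param seed integer seed for split, embedding, sampling and forests.
#' @param test_fraction held-out edge fraction.
#' @param d,walks_per_node,walk_length,window,negatives,epochs,learning_rate
#'   embedding hyperparameters.
#' @param neg_ratio negatives per positive for classifier training.
#' @param operator edge operator.
#' @param n_trees,max_depth random-forest size (501 trees, depth 15).
#' @param threshold prediction-score cut.
#' @return List with `kg`, `largest`, `stats`, `split`, `test_auroc`,
#'   `predictions` and `frd_nodes`.
#' @export
run_kg_analysis <- function(sim, seed = 1L, test_fraction = 0.3,
                            d = 10, walks_per_node = 6, walk_length = 20,
                            window = 5, negatives = 5, epochs = 4,
                            learning_rate = 0.025, neg_ratio = 1,
                            operator = "concat", n_trees = 501,
                            max_depth = 15, threshold = 0.8) {
  seed <- as.integer(seed)
  survey_edges <- transform_responses(sim$table, sim$keys, sim$ontologies)
  kg <- merge_graphs(survey_edges, sim$ontologies, sim$supplemental)
  lc <- largest_component(kg)
  split <- connectivity_preserving_split(lc$kg, test_fraction, seed)

  kg_train <- kg_new(lc$kg$nodes, split$train_edges)
  emb_train <- embed_kg(kg_train, d = d, walks_per_node = walks_per_node,
                        walk_length = walk_length, window = window,
                        negatives = negatives, epochs = epochs,
                        learning_rate = learning_rate, seed = seed + 10L)
  ts <- make_training_set(split, emb_train, neg_ratio = neg_ratio,
                          operator = operator, seed = seed + 20L)
  model_eval <- train_rf(ts$x, ts$y, n_trees = n_trees,
                         max_depth = max_depth, seed = seed + 30L)
  all_edges <- lc$kg$edges[, c("subject", "object")]
  eval_negatives <- sample_non_edges(
    rownames(emb_train), rbind(all_edges, ts$negatives),
    nrow(split$test_edges), seed + 40L)
  test_auroc <- evaluate_auroc(model_eval, split$test_edges,
                               eval_negatives, emb_train, operator)

  emb_full <- embed_kg(lc$kg, d = d, walks_per_node = walks_per_node,
                       walk_length = walk_length, window = window,
                       negatives = negatives, epochs = epochs,
                       learning_rate = learning_rate, seed = seed + 50L)
  full_split <- list(train_edges = lc$kg$edges,
                     test_edges = lc$kg$edges[0, , drop = FALSE])
  ts_full <- make_training_set(full_split, emb_full, neg_ratio = neg_ratio,
                               operator = operator, seed = seed + 60L)
  model_full <- train_rf(ts_full$x, ts_full$y, n_trees = n_trees,
                         max_depth = max_depth, seed = seed + 70L)
  frd_nodes <- intersect(unname(sim$frd_curies), lc$kg$nodes$id)
  predictions <- score_candidate_links(model_full, emb_full, lc$kg,
                                       frd_nodes, threshold = threshold,
                                       operator = operator)
  list(kg = kg, largest = lc, stats = graph_stats(kg), split = split,
       test_auroc = test_auroc, predictions = predictions,
       frd_nodes = frd_nodes)
}

#' Run the comparison regression arm
#'
#' Cohort restriction (female, all three surveys), missForest-style
#' imputation, then the elastic net, permutation importance, logistic
#' regression, Bonferroni and tier stages once per FRD outcome.
#'
#' @param sim a study list from [simulate_study()].
#' @param seed integer seed.
#' @param n_repeats permutation-importance repeats.
#' @return Named list of `regression_result` objects keyed by FRD CURIE,
#'   with the imputed cohort attached as attribute `"cohort"`.
#' @export
run_regression_analysis <- function(sim, seed = 1L, n_repeats = 5) {
  seed <- as.integer(seed)
  cohort <- build_cohort_table(sim$table, sim$keys, sim$ontologies,
                               sim$frd_curies)
  cohort <- impute_rf_iterative(cohort, seed = seed + 1L)
  results <- lapply(seq_along(sim$frd_curies), function(i)
    run_regression_frd(cohort, unname(sim$frd_curies[i]),
                       seed = seed + 100L * i, n_repeats = n_repeats))
  names(results) <- unname(sim$frd_curies)
  attr(results, "cohort") <- cohort
  results
}

#' Run the complete synthetic study end to end
#'
#' Chains the generator, the KG link-prediction arm, the regression arm, and
#' the exact-match reconciliation, and renders the run summary.
#'
#' @param config optional [synthetic_config()].
#' @param seed integer seed for the whole run.
#' @param ... further arguments passed to [run_kg_analysis()].
#' @return List with `sim`, `kg` (analysis list), `regression`, `report`
#'   and `summary`.
#' @export
run_study <- function(config = NULL, seed = 1L, ...) {
  sim <- simulate_study(config, seed = seed)
  kgres <- run_kg_analysis(sim, seed = seed + 1L, ...)
  regres <- run_regression_analysis(sim, seed = seed + 2L)
  report <- exact_match(kgres$predictions, regres,
                        ontologies = sim$ontologies)
  summary <- render_summary(report, kgres$stats, kgres$test_auroc,
                            sim$config, split = kgres$split)
  list(sim = sim, kg = kgres, regression = regres, report = report,
       summary = summary)
}
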