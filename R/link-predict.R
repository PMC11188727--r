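#' Rank-based AUROC
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) class labels.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_config("AUROC undefined: one class is empty")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# uniform non-edge sampler: node pairs that are neither train nor test edges
sample_non_edges <- function(kg_or_nodes, forbidden_edges, n, seed) {
  ids <- if (is.character(kg_or_nodes)) kg_or_nodes else kg_or_nodes$nodes$id
  forbid <- c(paste(forbidden_edges$subject, forbidden_edges$object),
              paste(forbidden_edges$object, forbidden_edges$subject))
  set.seed(seed)
  out_s <- character(0)
  out_o <- character(0)
  while (length(out_s) < n) {
    k <- max(2L * (n - length(out_s)), 100L)
    s <- ids[sample.int(length(ids), k, replace = TRUE)]
    o <- ids[sample.int(length(ids), k, replace = TRUE)]
    ok <- s != o & !(paste(s, o) %in% forbid) &
      !duplicated(paste(pmin(s, o), pmax(s, o)))
    ok <- ok & !(paste(pmin(s, o), pmax(s, o)) %in%
                   paste(pmin(out_s, out_o), pmax(out_s, out_o)))
    out_s <- c(out_s, s[ok])
    out_o <- c(out_o, o[ok])
  }
  data.frame(subject = out_s[seq_len(n)], object = out_o[seq_len(n)])
}

#' Build the link-prediction training set
#'
#' Positives are the training edges of the split; negatives are node pairs
#' sampled uniformly that appear in neither the train nor the test edge set
#' (in either orientation), `neg_ratio` per positive. Features come from the
#' configured edge operator.
#'
#' @param split an `edge_split`.
#' @param emb embedding matrix covering all endpoints.
#' @param neg_ratio negatives per positive (> 0).
#' @param operator edge operator (see [edge_features()]).
#' @param seed integer seed.
#' @return List with `x` (feature matrix), `y` (0/1 labels), `pairs` (the
#'   positive and negative node pairs) and `negatives`.
#' @export
make_training_set <- function(split, emb, neg_ratio = 1,
                              operator = "hadamard", seed = 1L) {
  if (neg_ratio <= 0) stop_config("neg_ratio must be > 0")
  pos <- split$train_edges[, c("subject", "object")]
  all_edges <- rbind(pos, split$test_edges[, c("subject", "object")])
  n_neg <- round(neg_ratio * nrow(pos))
  neg <- sample_non_edges(rownames(emb), all_edges, n_neg, seed)
  pairs <- rbind(pos, neg)
  x <- edge_feature_matrix(emb, pairs, operator)
  y <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  list(x = x, y = y, pairs = pairs, negatives = neg)
}

#' Train the random-forest edge classifier
#'
#' Probability random forest with the defaults used throughout: 501 trees
#' and maximum depth 15.
#'
#' @param x feature matrix.
#' @param y 0/1 labels (both classes must be present).
#' @param n_trees,max_depth forest size and depth cap.
#' @param seed integer seed.
#' @return A fitted `ranger` probability forest.
#' @export
train_rf <- function(x, y, n_trees = 501, max_depth = 15, seed = 1L) {
  y <- factor(as.integer(y), levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2)
    stop_config("training labels contain a single class")
  ranger::ranger(x = as.data.frame(x), y = y, probability = TRUE,
                 num.trees = n_trees, max.depth = max_depth,
                 num.threads = 1, seed = seed)
}

rf_scores <- function(model, x) {
  p <- predict(model, data = as.data.frame(x), num.threads = 1)$predictions
  p[, "1"]
}

#' Evaluate held-out AUROC of the edge classifier
#'
#' Scores the held-out test edges against sampled non-edges and computes the
#' rank-based AUROC.
#'
#' @param model fitted classifier from [train_rf()].
#' @param test_edges held-out edges (data frame with `subject`, `object`).
#' @param negatives sampled non-edge pairs.
#' @param emb embedding matrix.
#' @param operator edge operator used in training.
#' @return AUROC in [0, 1].
#' @export
evaluate_auroc <- function(model, test_edges, negatives, emb,
                           operator = "hadamard") {
  if (nrow(test_edges) == 0) stop_config("test set is empty")
  pairs <- rbind(test_edges[, c("subject", "object")],
                 negatives[, c("subject", "object")])
  x <- edge_feature_matrix(emb, pairs, operator)
  scores <- rf_scores(model, x)
  auroc(scores, c(rep(1L, nrow(test_edges)), rep(0L, nrow(negatives))))
}

#' Score candidate FRD-variable links
#'
#' Scores every (FRD, candidate) pair where the candidate is a term node of
#' category chemical, phenotype, disease, food, exposure or procedure,
#' excluding person nodes, the FRD itself and its is_a ancestors (which
#' would be trivially predictable). Pairs above the score threshold are
#' flagged. The classifier should be retrained on the full (no-holdout)
#' embedding before scoring.
#'
#' @param model classifier retrained on the full graph.
#' @param emb full-graph embedding.
#' @param kg the knowledge graph (provides candidate categories and is_a
#'   edges for ancestor exclusion).
#' @param frd_nodes character vector of FRD node ids.
#' @param threshold prediction-score cut, default 0.8.
#' @param operator edge operator used in training.
#' @return Data frame of class `link_predictions`: `source`, `destination`,
#'   `destination_category`, `score`, `passed_threshold`, sorted by
#'   descending score with ties broken by destination id.
#' @export
score_candidate_links <- function(model, emb, kg, frd_nodes, threshold = 0.8,
                                  operator = "hadamard") {
  if (!all(frd_nodes %in% kg$nodes$id))
    stop_config("unknown FRD node(s): %s",
                paste(setdiff(frd_nodes, kg$nodes$id), collapse = ", "))
  cats <- c("chemical", "phenotype", "disease", "food", "exposure",
            "procedure")
  is_a <- kg$edges[kg$edges$predicate == "is_a", c("subject", "object")]
  ancestors_of <- function(id) {
    anc <- character(0)
    frontier <- id
    while (length(frontier) > 0) {
      parents <- is_a$object[is_a$subject %in% frontier]
      frontier <- setdiff(parents, anc)
      anc <- union(anc, frontier)
    }
    setdiff(anc, id)
  }
  out <- lapply(frd_nodes, function(frd) {
    cand <- kg$nodes$id[kg$nodes$category %in% cats]
    cand <- setdiff(cand, c(frd, ancestors_of(frd)))
    cand <- cand[cand %in% rownames(emb)]
    pairs <- data.frame(subject = frd, object = cand)
    x <- edge_feature_matrix(emb, pairs, operator)
    data.frame(source = frd, destination = cand,
               destination_category =
                 kg$nodes$category[match(cand, kg$nodes$id)],
               score = rf_scores(model, x))
  })
  out <- do.call(rbind, out)
  out$passed_threshold <- out$score > threshold
  out <- out[order(-out$score, out$destination), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("link_predictions", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Write link predictions as TSV
#'
#' @param predictions from [score_candidate_links()].
#' @param path file path.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
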