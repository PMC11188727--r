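#' Connectivity-preserving train/test edge split
#'
#' Holds out a test fraction of edges without fragmenting the graph: a random
#' spanning tree (forest, if the input is disconnected) is built from
#' uniformly weighted edges and its edges are never held out, so removing any
#' subset of the remaining edges cannot create a new component. Test edges
#' are sampled uniformly without replacement from the non-tree edges, up to
#' `min(round(test_fraction * n_edges), n_non_tree)`.
#'
#' @param kg an `exposome_kg` (typically the largest-component subgraph).
#' @param test_fraction requested held-out fraction in (0, 1).
#' @param seed integer seed.
#' @return List of class `edge_split`: `train_edges`, `test_edges` (rows of
#'   `kg$edges`), `test_fraction_requested`, `test_fraction_achieved`.
#' @export
connectivity_preserving_split <- function(kg, test_fraction = 0.3,
                                          seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_config("test_fraction must be in (0, 1)")
  m <- nrow(kg$edges)
  if (m == 0) stop_config("graph has no edges")
  set.seed(seed)
  g <- kg_igraph(kg)
  igraph::E(g)$edge_row <- seq_len(m)
  tree <- igraph::mst(g, weights = runif(m))
  tree_rows <- igraph::E(tree)$edge_row
  non_tree <- setdiff(seq_len(m), tree_rows)
  n_test <- min(round(test_fraction * m), length(non_tree))
  if (length(non_tree) == 0)
    warning("graph is a tree/forest: no edge can be held out")
  test_rows <- if (n_test > 0) sort(sample(non_tree, n_test)) else integer(0)
  split <- list(
    train_edges = kg$edges[setdiff(seq_len(m), test_rows), , drop = FALSE],
    test_edges = kg$edges[test_rows, , drop = FALSE],
    test_fraction_requested = test_fraction,
    test_fraction_achieved = n_test / m)
  rownames(split$train_edges) <- rownames(split$test_edges) <- NULL
  class(split) <- "edge_split"
  split
}

# 0-based adjacency lists of the undirected view, in node-table order
kg_adjacency <- function(kg) {
  idx <- match(c(kg$edges$subject, kg$edges$object), kg$nodes$id)
  n <- nrow(kg$nodes)
  m <- nrow(kg$edges)
  from <- c(idx[seq_len(m)], idx[m + seq_len(m)])
  to <- c(idx[m + seq_len(m)], idx[seq_len(m)])
  adj <- split(to - 1L, factor(from, levels = seq_len(n)))
  unname(adj)
}

#' Generate a uniform random-walk corpus
#'
#' For each node, `walks_per_node` uniform random walks of `walk_length`
#' nodes on the undirected view of the graph. The corpus order (pass by
#' pass, node by node) and the walks themselves are deterministic under a
#' fixed seed. Isolated nodes yield single-node walks.
#'
#' @param kg an `exposome_kg`.
#' @param walks_per_node walks started from each node.
#' @param walk_length number of nodes per walk (>= 1).
#' @param seed integer seed.
#' @return List of class `walk_corpus`: `walks` (list of integer node-index
#'   vectors) and `node_ids` mapping indices to node ids.
#' @export
generate_walks <- function(kg, walks_per_node = 10, walk_length = 40,
                           seed = 1L) {
  if (walk_length < 1) stop_config("walk_length must be >= 1")
  adj <- kg_adjacency(kg)
  walks <- .cpp_generate_walks(adj, as.integer(walks_per_node),
                               as.integer(walk_length), as.numeric(seed))
  structure(list(walks = walks, node_ids = kg$nodes$id),
            class = "walk_corpus")
}

#' Train Skipgram node embeddings on a walk corpus
#'
#' Stochastic gradient descent over (center, context) pairs within a window,
#' with negative sampling from the unigram^0.75 distribution and a linearly
#' decaying learning rate. Training is single-threaded and deterministic
#' under a fixed seed. Defaults follow common DeepWalk practice.
#'
#' @param corpus a `walk_corpus`.
#' @param d embedding dimension (>= 2).
#' @param window context window half-width.
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the corpus.
#' @param learning_rate initial SGD step size.
#' @param seed integer seed.
#' @return Numeric matrix (nodes x d) with node ids as row names; the
#'   hyperparameters are attached as attribute `"hyperparams"`.
#' @export
train_skipgram <- function(corpus, d = 64, window = 5, negatives = 5,
                           epochs = 5, learning_rate = 0.025, seed = 1L) {
  if (d < 2) stop_config("embedding dimension must be >= 2")
  if (length(corpus$walks) == 0) stop_config("corpus is empty")
  emb <- .cpp_train_skipgram(corpus$walks, length(corpus$node_ids),
                             as.integer(d), as.integer(window),
                             as.integer(negatives), as.integer(epochs),
                             learning_rate, as.numeric(seed))
  rownames(emb) <- corpus$node_ids
  stopifnot(all(is.finite(emb)))
  attr(emb, "hyperparams") <- list(d = d, window = window,
                                   negatives = negatives, epochs = epochs,
                                   learning_rate = learning_rate, seed = seed)
  emb
}

#' Embed a knowledge graph
#'
#' Convenience wrapper: random-walk corpus followed by Skipgram training.
#'
#' @inheritParams generate_walks
#' @inheritParams train_skipgram
#' @return Embedding matrix as from [train_skipgram()].
#' @export
embed_kg <- function(kg, d = 64, walks_per_node = 10, walk_length = 40,
                     window = 5, negatives = 5, epochs = 5,
                     learning_rate = 0.025, seed = 1L) {
  corpus <- generate_walks(kg, walks_per_node, walk_length, seed)
  train_skipgram(corpus, d, window, negatives, epochs, learning_rate,
                 seed + 1L)
}

#' Combine two node vectors into an edge feature vector
#'
#' Operators: `hadamard` (default, element-wise product), `average`, `L1`
#' (absolute difference), `L2` (squared difference), `concat`. All but
#' `concat` are symmetric in the endpoints and of length `d`; `concat` has
#' length `2d`.
#'
#' @param emb embedding matrix with node ids as row names.
#' @param u,v node ids.
#' @param operator one of `"hadamard"`, `"average"`, `"L1"`, `"L2"`,
#'   `"concat"`.
#' @return Numeric feature vector.
#' @export
edge_features <- function(emb, u, v, operator = "hadamard") {
  if (!u %in% rownames(emb)) stop_config("unknown node: %s", u)
  if (!v %in% rownames(emb)) stop_config("unknown node: %s", v)
  edge_feature_matrix(emb, data.frame(subject = u, object = v), operator)[1, ]
}

# vectorised edge-operator over a data frame of (subject, object) pairs
edge_feature_matrix <- function(emb, pairs, operator = "hadamard") {
  iu <- match(pairs$subject, rownames(emb))
  iv <- match(pairs$object, rownames(emb))
  if (anyNA(iu) || anyNA(iv))
    stop_config("pairs reference nodes missing from the embedding")
  U <- emb[iu, , drop = FALSE]
  V <- emb[iv, , drop = FALSE]
  x <- switch(operator,
    hadamard = U * V,
    average = (U + V) / 2,
    L1 = abs(U - V),
    L2 = (U - V)^2,
    concat = cbind(U, V),
    stop_config("unknown edge operator: %s", operator))
  dimnames(x) <- list(NULL, paste0("f", seq_len(ncol(x))))
  x
}

#' Write / read an embedding as TSV with a JSON sidecar
#'
#' The TSV holds `node_id` plus one column per dimension; the sidecar
#' (`<path>.json`) records the training hyperparameters.
#'
#' @param emb embedding matrix from [train_skipgram()].
#' @param path TSV file path.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(node_id = rownames(emb), emb, check.names = FALSE)
  colnames(df) <- c("node_id", paste0("v", seq_len(ncol(emb))))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  hp <- attr(emb, "hyperparams")
  if (!is.null(hp))
    jsonlite::write_json(hp, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- read.delim(path)
  emb <- as.matrix(df[, -1, drop = FALSE])
  rownames(emb) <- df$node_id
  colnames(emb) <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(emb, "hyperparams") <- jsonlite::read_json(sidecar,
                                                    simplifyVector = TRUE)
  emb
}
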