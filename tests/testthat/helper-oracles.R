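# Independent oracles used to cross-check package computations. These stay
# deliberately naive (brute force, fixed-point iteration, IRLS written from
# the likelihood) and share no code with the implementation paths they test.

# O(n^2) pairwise AUROC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# BFS connected components over an undirected edge list; returns the
# membership vector over `ids`
oracle_components <- function(ids, from, to) {
  adj <- lapply(setNames(vector("list", length(ids)), ids), function(x) x)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  membership <- setNames(rep(NA_integer_, length(ids)), ids)
  comp <- 0L
  for (start in ids) {
    if (!is.na(membership[start])) next
    comp <- comp + 1L
    queue <- start
    membership[start] <- comp
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[v]]) {
        if (is.na(membership[nb])) {
          membership[nb] <- comp
          queue <- c(queue, nb)
        }
      }
    }
  }
  membership
}

# transitive ancestor closure by fixed-point expansion over the parent map
oracle_ancestors <- function(curie, child, parent) {
  anc <- character(0)
  repeat {
    frontier <- unique(parent[child %in% c(curie, anc)])
    new <- setdiff(frontier, c(anc, curie))
    if (length(new) == 0) break
    anc <- c(anc, new)
  }
  sort(setdiff(anc, curie))
}

# logistic regression by hand-written iteratively reweighted least squares;
# returns coefficients, standard errors and Wald p-values
oracle_logistic <- function(x, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, as.matrix(x))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    fisher <- crossprod(X, X * W)
    beta_new <- solve(fisher, crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  fisher <- crossprod(X, X * (mu * (1 - mu)))
  se <- unname(sqrt(diag(solve(fisher))))
  z <- as.vector(beta) / se
  list(beta = as.vector(beta), se = se, p = unname(2 * pnorm(-abs(z))))
}

# random connected graph as an exposome_kg: a spanning tree plus extra edges
random_connected_kg <- function(n, extra_edges, seed) {
  set.seed(seed)
  ids <- sprintf("N%04d", seq_len(n))
  parent <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), 0L))
  from <- ids[2:n]
  to <- ids[parent[2:n]]
  if (extra_edges > 0) {
    a <- sample(n, extra_edges, replace = TRUE)
    b <- sample(n, extra_edges, replace = TRUE)
    ok <- a != b
    from <- c(from, ids[a[ok]])
    to <- c(to, ids[b[ok]])
  }
  key <- paste(pmin(from, to), pmax(from, to))
  keep <- !duplicated(key)
  edges <- data.frame(subject = from[keep], predicate = "linked",
                      object = to[keep], provenance = "survey")
  kg_new(data.frame(id = ids, category = "other", name = ids), edges)
}
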