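# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Ancestor closure of `term` (term included) by naive recursion over a
# (child, parent) edge data frame.
bf_ancestors <- function(edges, term) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(edges$parent[edges$child %in% frontier], seen)
  }
  seen
}

# Disease semantic similarity by explicit ancestor-set enumeration per pair.
bf_semantic_similarity <- function(edges, diseases) {
  n <- length(diseases)
  anc <- lapply(diseases, function(d) bf_ancestors(edges, d))
  all_terms <- unique(unlist(anc))
  n_dags <- vapply(all_terms,
                   function(t) sum(vapply(anc, function(a) t %in% a,
                                          logical(1))),
                   numeric(1))
  names(n_dags) <- all_terms
  contrib <- lapply(anc, function(a) {
    v <- -log(n_dags[a] / n); names(v) <- a; v
  })
  DV <- vapply(contrib, sum, numeric(1))
  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    den <- DV[i] + DV[j]
    if (den == 0) {
      S[i, j] <- as.numeric(i == j)
    } else {
      sh <- intersect(anc[[i]], anc[[j]])
      S[i, j] <- sum(contrib[[i]][sh] + contrib[[j]][sh]) / den
    }
  }
  S
}

# Random layered DAG over <= n_terms terms: node i may only point at
# lower-indexed nodes, which guarantees acyclicity independently of the
# package's own generator.
bf_random_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- paste0("t", seq_len(n_terms))
  edges <- do.call(rbind, lapply(2:n_terms, function(i) {
    np <- sample(0:min(2, i - 1), 1)
    if (np == 0) return(NULL)
    data.frame(child = terms[i],
               parent = terms[sample.int(i - 1, np)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = terms[2], parent = terms[1],
                        stringsAsFactors = FALSE)
  }
  diseases <- sort(sample(terms, max(2, rbinom(1, n_terms, 0.6))))
  list(edges = edges, terms = terms, diseases = diseases)
}

# Hypergraph smoothness by the explicit normalized double sum over all
# (e, u, v) triples, with the squared difference.
bf_regularizer <- function(H, w, f) {
  total <- 0
  d <- as.numeric(H %*% w)
  delta <- colSums(H)
  for (e in seq_len(ncol(H))) {
    for (u in seq_len(nrow(H))) {
      for (v in seq_len(nrow(H))) {
        total <- total + w[e] * H[u, e] * H[v, e] / delta[e] *
          (f[u] / sqrt(d[u]) - f[v] / sqrt(d[v]))^2
      }
    }
  }
  total / 2
}

# AUC by exhaustive pairwise comparison, ties counted half.
bf_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# Small random binary profile matrix with at least one nonzero entry.
rand_profiles <- function(n, p, seed, density = 0.4) {
  set.seed(seed)
  P <- matrix(rbinom(n * p, 1, density), n, p)
  if (sum(P) == 0) P[1, 1] <- 1
  P
}
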