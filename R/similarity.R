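#' Gaussian interaction-profile kernel
#'
#' Each entity is represented by its binary interaction profile `BV(i)`
#' (a row of the profile matrix); similarity between two entities is a
#' Gaussian of the squared Euclidean distance between their profiles,
#'
#' \deqn{K(i,j) = \exp(-\gamma \,\|BV(i)-BV(j)\|^2),\qquad
#'       \gamma = \Big(\frac{1}{n}\sum_i \|BV(i)\|^2\Big)^{-1}.}
#'
#' The bandwidth is the reciprocal of the mean squared profile norm, so
#' it adapts to the overall density of known interactions. For miRNAs pass
#' the association matrix as is (rows are profiles); for diseases pass its
#' transpose.
#'
#' @param profiles binary matrix, one entity per row.
#' @return list with elements `K` (a [similarity_matrix()]) and `gamma`
#'   (the bandwidth actually used).
#' @export
gip_kernel <- function(profiles) {
  P <- as.matrix(unclass(profiles))
  if (anyNA(P) || !all(P %in% c(0, 1))) {
    stop("interaction profiles must be binary")
  }
  norms2 <- rowSums(P^2)
  if (sum(norms2) == 0) {
    stop("bandwidth undefined: all interaction profiles are zero")
  }
  gamma <- 1 / mean(norms2)
  # squared Euclidean distances via the Gram expansion
  G <- tcrossprod(P)
  d2 <- outer(norms2, norms2, "+") - 2 * G
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  ids <- rownames(P)
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(P)))
  list(K = similarity_matrix(K, ids), gamma = gamma)
}

# Per-term DAG membership counts over the diseases of interest:
# how many disease DAGs (ancestor closures) contain each term.
dag_membership_counts <- function(ontology) {
  anc <- lapply(ontology$disease_ids, function(d) term_ancestors(ontology, d))
  names(anc) <- ontology$disease_ids
  counts <- table(factor(unlist(anc), levels = ontology$terms))
  list(ancestors = anc, counts = as.numeric(counts),
       terms = ontology$terms)
}

#' Semantic value of a disease and its per-term contributions
#'
#' The DAG of a disease is the disease plus all its ancestor terms. Each
#' term `t` in the DAG contributes
#' \deqn{D_d(t) = -\log\big(\,n_{DAG}(t) / n_{diseases}\,\big)}
#' where `n_DAG(t)` counts how many diseases of interest have `t` in
#' their DAG. Rare, specific terms therefore contribute more than broad
#' ones (a term shared by every disease contributes 0). The semantic
#' value `DV(d)` is the sum of the contributions. Natural logarithms are
#' used; the base cancels in [semantic_similarity()].
#'
#' @param ontology a [disease_ontology()].
#' @param disease a disease-of-interest identifier.
#' @return list with elements `DV` (numeric) and `contributions`
#'   (named numeric vector over the disease's DAG terms).
#' @export
semantic_value <- function(ontology, disease) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (!disease %in% ontology$disease_ids) {
    stop(sprintf("'%s' is not a disease of interest in the ontology",
                 disease))
  }
  mem <- dag_membership_counts(ontology)
  dag <- mem$ancestors[[disease]]
  contrib <- -log(mem$counts[match(dag, mem$terms)] /
                    length(ontology$disease_ids))
  names(contrib) <- dag
  list(DV = sum(contrib), contributions = contrib)
}

#' Pairwise disease semantic similarity over DAGs
#'
#' For diseases `i` and `j` with DAG term sets `D(i)` and `D(j)`,
#' \deqn{SD(i,j) = \frac{\sum_{t \in D(i)\cap D(j)}
#'       \big(D_i(t)+D_j(t)\big)}{DV(i)+DV(j)}}
#' i.e. the contribution mass of the shared terms relative to the total.
#' When `DV(i) + DV(j) = 0` (both diseases are root terms present in
#' every DAG) the ratio is 0/0; self-similarity is then defined as 1 and
#' cross-similarity as 0.
#'
#' @param ontology a [disease_ontology()].
#' @return list with elements `SD_sem` (a [similarity_matrix()] over the
#'   diseases of interest), `DV` (named numeric vector) and
#'   `contributions` (named list of per-term contribution vectors).
#' @export
semantic_similarity <- function(ontology) {
  stopifnot(inherits(ontology, "disease_ontology"))
  ids <- ontology$disease_ids
  n <- length(ids)
  mem <- dag_membership_counts(ontology)
  contrib <- lapply(ids, function(d) {
    dag <- mem$ancestors[[d]]
    v <- -log(mem$counts[match(dag, mem$terms)] / n)
    names(v) <- dag
    v
  })
  names(contrib) <- ids
  DV <- vapply(contrib, sum, numeric(1))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      denom <- DV[i] + DV[j]
      if (denom == 0) {
        S[i, j] <- as.numeric(i == j)
      } else {
        shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
        S[i, j] <- sum(contrib[[i]][shared] + contrib[[j]][shared]) / denom
      }
      S[j, i] <- S[i, j]
    }
  }
  list(SD_sem = similarity_matrix(S, ids), DV = DV, contributions = contrib)
}

#' Fuse a base similarity matrix with a GIP kernel
#'
#' Sparse functional/semantic similarity matrices carry many structural
#' zeros that convey no information. Fusion fills them from the kernel:
#' where the base similarity is exactly 0 the kernel value is used alone;
#' everywhere else the two are averaged.
#'
#' @param base the functional or semantic [similarity_matrix()].
#' @param gip the Gaussian interaction-profile kernel matrix with the
#'   same identifiers in the same order.
#' @return the fused [similarity_matrix()].
#' @export
fuse_similarity <- function(base, gip) {
  if (!all(dim(base) == dim(gip))) stop("shape mismatch between matrices")
  if (!identical(rownames(base), rownames(gip))) {
    stop("identifier mismatch between matrices")
  }
  B <- unclass(base); G <- unclass(gip)
  fused <- ifelse(B == 0, G, (B + G) / 2)
  similarity_matrix(fused, rownames(base))
}

#' Build fused miRNA and disease similarity matrices
#'
#' Convenience wrapper running the full similarity stage: GIP kernels are
#' computed from the association matrix (rows for miRNAs, columns for
#' diseases) and fused with the base miRNA functional similarity and with
#' the DAG-derived disease semantic similarity.
#'
#' @param A an [association_matrix()].
#' @param SM_base miRNA functional [similarity_matrix()] aligned with the
#'   rows of `A`.
#' @param ontology a [disease_ontology()] whose diseases of interest are
#'   the columns of `A`, or a precomputed semantic [similarity_matrix()].
#' @return list with fused `SM` and `SD` similarity matrices.
#' @export
build_similarity <- function(A, SM_base, ontology) {
  if (!identical(rownames(SM_base), rownames(A))) {
    stop("SM_base identifiers must match the rows of A")
  }
  SD_sem <- if (inherits(ontology, "disease_ontology")) {
    res <- semantic_similarity(ontology)
    sd <- res$SD_sem
    if (!all(colnames(A) %in% rownames(sd))) {
      stop("ontology is missing diseases present in A")
    }
    similarity_matrix(unclass(sd)[colnames(A), colnames(A)], colnames(A))
  } else {
    if (!identical(rownames(ontology), colnames(A))) {
      stop("semantic similarity identifiers must match the columns of A")
    }
    ontology
  }
  GKM <- gip_kernel(unclass(A))$K
  GKD <- gip_kernel(t(unclass(A)))$K
  list(SM = fuse_similarity(SM_base, GKM),
       SD = fuse_similarity(SD_sem, GKD))
}
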