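#' KNN hypergraph over feature rows
#'
#' One hyperedge is generated per vertex: the vertex itself (the
#' centroid) plus its `k` nearest neighbours by Euclidean distance on
#' the rows of `X`, so every hyperedge has degree `k + 1` and the
#' incidence matrix is `n x n`. Distance ties are broken toward the
#' lower vertex index. All hyperedges receive the equal weight
#' `1 / |E| = 1/n`. Hyperedges of vertices with identical neighbourhoods
#' are retained as distinct columns.
#'
#' @param X numeric matrix, one vertex per row.
#' @param k number of nearest neighbours per hyperedge (centroid
#'   excluded from the count), `1 <= k <= n - 1`.
#' @return object of class `"hypergraph"` with fields `n_vertices`, `H`
#'   (n x n binary incidence), `w` (hyperedge weights), `Dv`, `De`
#'   (degree vectors), `k`.
#' @export
knn_hyperedges <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least two vertices")
  if (k < 1 || k > n - 1) stop("k must satisfy 1 <= k <= n - 1")
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite feature values")
  norms2 <- rowSums(X^2)
  d2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  H <- matrix(0L, n, n)
  for (v in seq_len(n)) {
    dv <- d2[, v]
    dv[v] <- Inf                       # centroid joins explicitly
    nb <- order(dv, seq_len(n))[seq_len(k)]   # ties to lower index
    H[c(v, nb), v] <- 1L
  }
  w <- rep(1 / n, n)
  hg <- structure(list(n_vertices = n, H = H, w = w, k = as.integer(k)),
                  class = "hypergraph")
  deg <- hypergraph_degrees(H, w)
  hg$Dv <- deg$Dv
  hg$De <- deg$De
  hg
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("hypergraph: %d vertices, %d hyperedges (k = %d)\n",
              x$n_vertices, ncol(x$H), x$k))
  invisible(x)
}

#' Vertex and hyperedge degrees
#'
#' The degree of a vertex is the weighted count of hyperedges containing
#' it, `d(v) = sum_e w(e) H(v,e)`; the degree of a hyperedge is its
#' vertex count, `delta(e) = sum_v H(v,e)`.
#'
#' @param H binary incidence matrix (vertices x hyperedges).
#' @param w positive hyperedge weights.
#' @return list with numeric vectors `Dv` and `De`.
#' @export
hypergraph_degrees <- function(H, w) {
  H <- as.matrix(H)
  if (!all(H %in% c(0, 1))) stop("incidence matrix must be binary")
  if (length(w) != ncol(H) || any(w <= 0)) {
    stop("need one positive weight per hyperedge")
  }
  Dv <- as.numeric(H %*% w)
  De <- colSums(H)
  if (any(Dv == 0)) {
    stop("zero-degree vertex: cannot normalize the hypergraph")
  }
  list(Dv = Dv, De = De)
}

#' Normalized hypergraph operator
#'
#' Computes `Theta = Dv^{-1/2} H W De^{-1} H' Dv^{-1/2}` and the
#' hypergraph Laplacian `Delta = I - Theta`. `Delta` is symmetric
#' positive semi-definite and serves as the smoothness regularizer: for
#' any vertex function `f`, `f' Delta f` equals half the
#' degree-normalized sum of squared differences of `f` within each
#' hyperedge.
#'
#' @param hg a `"hypergraph"`.
#' @return list of class `"normalized_operator"` with matrices `Theta`
#'   and `Delta`.
#' @export
normalized_operator <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  if (any(hg$De == 0)) stop("empty hyperedge: singular degree")
  dv_is <- 1 / sqrt(hg$Dv)
  # Dv^{-1/2} H W De^{-1} H^T Dv^{-1/2}, kept symmetric by construction
  B <- (dv_is * hg$H) %*% diag(hg$w / hg$De, ncol(hg$H))
  Theta <- tcrossprod(B, dv_is * hg$H)
  Theta <- (Theta + t(Theta)) / 2
  Delta <- diag(hg$n_vertices) - Theta
  structure(list(Theta = Theta, Delta = Delta),
            class = "normalized_operator")
}
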