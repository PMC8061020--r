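# Internal RNG scoping: run code with a given seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Derive a reproducible sub-seed from a master seed and a stream index.
sub_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483563)
}

# Row-major (i, j) index pairs of entries of A equal to `value`.
pairs_where <- function(A, value) {
  idx <- which(t(unclass(A)) == value)
  nd <- ncol(A)
  cbind(i = (idx - 1L) %/% nd + 1L, j = (idx - 1L) %% nd + 1L)
}

#' Feature vector of one miRNA-disease pair
#'
#' A pair `(m(i), d(j))` is represented by the concatenation of row `i`
#' of the miRNA similarity matrix and row `j` of the disease similarity
#' matrix: the pair's position in both similarity networks is its
#' feature. With 495 miRNAs and 383 diseases this is the 878-dimensional
#' representation used at HMDD scale.
#'
#' @param SM miRNA [similarity_matrix()].
#' @param SD disease [similarity_matrix()].
#' @param i miRNA row index.
#' @param j disease row index.
#' @return numeric vector of length `nrow(SM) + nrow(SD)`.
#' @export
pair_feature <- function(SM, SD, i, j) {
  if (i < 1 || i > nrow(SM)) stop("miRNA index out of range")
  if (j < 1 || j > nrow(SD)) stop("disease index out of range")
  c(unclass(SM)[i, ], unclass(SD)[j, ])
}

# Feature matrix for a set of (i, j) pairs: rows of SM indexed by i,
# column-bound with rows of SD indexed by j.
pair_feature_matrix <- function(SM, SD, pairs) {
  cbind(unclass(SM)[pairs[, 1], , drop = FALSE],
        unclass(SD)[pairs[, 2], , drop = FALSE])
}

#' Build the balanced training set of pair features
#'
#' All known associations become positive examples; an equal number of
#' unknown pairs is drawn uniformly without replacement as negatives.
#' Since known associations are a small fraction of all pairs (about
#' 2.9% at HMDD scale), the contamination of the negative sample by true
#' but unconfirmed associations is negligible. Row order is positives in
#' row-major order of `A`, then negatives in sampled order; sampling is
#' driven entirely by `seed`.
#'
#' @param A an [association_matrix()].
#' @param SM,SD fused similarity matrices aligned with the rows/columns
#'   of `A`.
#' @param seed integer seed for the negative sample.
#' @return list of class `"pair_feature_set"` with elements `pairs`
#'   (n x 2 index matrix), `X` (n x (nm+nd) feature matrix), `y` (0/1
#'   labels) and `rng_seed`.
#' @export
build_training_set <- function(A, SM, SD, seed) {
  pos <- pairs_where(A, 1L)
  neg_pool <- pairs_where(A, 0L)
  npos <- nrow(pos)
  if (npos == 0) stop("association matrix has no known associations")
  if (nrow(neg_pool) < npos) {
    stop("fewer unknown pairs than known associations; cannot balance")
  }
  sel <- with_seed(seed, sample.int(nrow(neg_pool), npos))
  neg <- neg_pool[sel, , drop = FALSE]
  pairs <- rbind(pos, neg)
  structure(list(pairs = pairs,
                 X = pair_feature_matrix(SM, SD, pairs),
                 y = rep(c(1L, 0L), each = npos),
                 rng_seed = as.integer(seed %% 2147483647)),
            class = "pair_feature_set")
}

#' Enumerate candidate (unknown) pairs
#'
#' All pairs with `A[i, j] == 0`, minus an optional exclusion set, in
#' row-major order. These are the pairs the fitted model is asked to
#' rank.
#'
#' @param A an [association_matrix()].
#' @param exclude optional 2-column index matrix of pairs to drop.
#' @return integer matrix with columns `i`, `j`.
#' @export
enumerate_candidates <- function(A, exclude = NULL) {
  cand <- pairs_where(A, 0L)
  if (!is.null(exclude) && length(exclude)) {
    exclude <- matrix(as.integer(exclude), ncol = 2)
    key <- cand[, 1] * (ncol(A) + 1L) + cand[, 2]
    exkey <- exclude[, 1] * (ncol(A) + 1L) + exclude[, 2]
    cand <- cand[!key %in% exkey, , drop = FALSE]
  }
  cand
}
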