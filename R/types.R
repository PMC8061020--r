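#' Construct a validated binary association matrix
#'
#' The association matrix `A` encodes experimentally confirmed
#' miRNA-disease links: `A[i, j] == 1` iff miRNA `i` is known to be
#' associated with disease `j`, and 0 otherwise. Rows are miRNAs,
#' columns are diseases.
#'
#' @param A numeric or integer matrix with entries in `{0, 1}`.
#' @param miRNA_ids,disease_ids optional character vectors of identifiers;
#'   default to the dimnames of `A`.
#' @return an integer matrix of class `"association_matrix"` with
#'   identifier dimnames.
#' @export
association_matrix <- function(A, miRNA_ids = rownames(A),
                               disease_ids = colnames(A)) {
  A <- as.matrix(A)
  if (is.null(miRNA_ids) || is.null(disease_ids)) {
    stop("association matrix requires miRNA and disease identifiers")
  }
  if (nrow(A) < 1L || ncol(A) < 1L) {
    stop("association matrix must have at least one row and one column")
  }
  if (length(miRNA_ids) != nrow(A) || length(disease_ids) != ncol(A)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(miRNA_ids) || anyDuplicated(disease_ids)) {
    stop("duplicate identifiers are not allowed")
  }
  if (anyNA(A) || !all(A %in% c(0, 1))) {
    stop("association matrix entries must be 0 or 1")
  }
  storage.mode(A) <- "integer"
  dimnames(A) <- list(as.character(miRNA_ids), as.character(disease_ids))
  class(A) <- c("association_matrix", class(matrix()))
  A
}

#' Construct a validated similarity matrix
#'
#' A square symmetric matrix of pairwise similarities in `[0, 1]`
#' (e.g. miRNA functional similarity, disease semantic similarity, or a
#' Gaussian interaction-profile kernel). Asymmetries up to `1e-8` are
#' repaired by averaging, as float-formatted files routinely carry that
#' much round-off; larger asymmetries are an error.
#'
#' @param S square numeric matrix.
#' @param ids character vector of identifiers; defaults to rownames.
#' @return a numeric matrix of class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(S, ids = rownames(S)) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(S)))
  if (length(ids) != nrow(S)) stop("identifier length mismatch")
  if (anyDuplicated(ids)) stop("duplicate identifiers are not allowed")
  if (anyNA(S)) stop("similarity matrix contains NA/NaN entries")
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8) {
    stop(sprintf("similarity matrix asymmetry %.3g exceeds tolerance 1e-8",
                 asym))
  }
  S <- (S + t(S)) / 2
  if (min(S) < 0 || max(S) > 1 + 1e-8) {
    stop("similarity values must lie in [0, 1]")
  }
  S[S > 1] <- 1
  dimnames(S) <- list(as.character(ids), as.character(ids))
  class(S) <- c("similarity_matrix", class(matrix()))
  S
}

#' Construct a disease ontology (forest of term DAGs)
#'
#' Disease terms form a directed acyclic graph via child-to-parent edges;
#' the DAG of one disease is the disease itself plus all its ancestors.
#' Semantic similarity between diseases is computed from per-term
#' contribution values over these DAGs.
#'
#' @param edges two-column data frame or matrix of (child, parent)
#'   identifier pairs; may have zero rows.
#' @param terms character vector of all term identifiers; defaults to the
#'   identifiers appearing in `edges`.
#' @param disease_ids subset of `terms` designated as the diseases of
#'   interest; defaults to all terms.
#' @return an object of class `"disease_ontology"` with elements `terms`,
#'   `edges`, `disease_ids` and an `igraph` graph used for ancestor queries.
#' @export
disease_ontology <- function(edges, terms = NULL, disease_ids = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && ncol(edges) < 2) {
    stop("edges must have (child, parent) columns")
  }
  if (nrow(edges) == 0) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = as.character(edges[[1]]),
                        parent = as.character(edges[[2]]),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$child == edges$parent)) {
    bad <- edges$child[edges$child == edges$parent][1]
    stop(sprintf("self-loop on term '%s'", bad))
  }
  if (is.null(terms)) terms <- unique(c(edges$child, edges$parent))
  terms <- unique(as.character(terms))
  if (!all(c(edges$child, edges$parent) %in% terms)) {
    stop("edges reference terms outside the declared term set")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    member <- names(comp$membership)[comp$membership %in%
                                       which(comp$csize > 1)][1]
    stop(sprintf("ontology edges contain a cycle (involving term '%s')",
                 member))
  }
  if (is.null(disease_ids)) disease_ids <- terms
  disease_ids <- as.character(disease_ids)
  if (!all(disease_ids %in% terms)) {
    stop("every disease of interest must be a term of the ontology")
  }
  structure(list(terms = terms, edges = edges,
                 disease_ids = disease_ids, graph = g),
            class = "disease_ontology")
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf("disease_ontology: %d terms, %d edges, %d diseases of interest\n",
              length(x$terms), nrow(x$edges), length(x$disease_ids)))
  invisible(x)
}

#' Ancestor set of a term (the term itself included)
#'
#' Returns the node set of the term's DAG: the term plus every term
#' reachable through child-to-parent edges.
#'
#' @param ontology a `disease_ontology`.
#' @param term a term identifier.
#' @return character vector of term identifiers.
#' @export
term_ancestors <- function(ontology, term) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (!term %in% ontology$terms) {
    stop(sprintf("term '%s' is not in the ontology", term))
  }
  igraph::as_ids(igraph::subcomponent(ontology$graph, term, mode = "out"))
}
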