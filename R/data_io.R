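#' Read a binary association matrix from disk
#'
#' Two on-disk formats are supported. `"edge-list"` (the canonical
#' interchange format, matching HMDD-style downloads) is a headerless TSV
#' of `(miRNA_id, disease_id)` rows; lines starting with `#` are skipped
#' and identifier order is first-appearance order unless an explicit id
#' universe is supplied. `"dense"` is a TSV with a header row of disease
#' identifiers and a first column of miRNA identifiers; every cell must be
#' 0 or 1.
#'
#' @param path file path.
#' @param format `"edge-list"` or `"dense"`.
#' @param miRNA_ids,disease_ids optional identifier universes for the
#'   edge-list format (required to represent entities with no known
#'   association, e.g. an empty edge list).
#' @return an [association_matrix()].
#' @export
read_associations <- function(path, format = c("edge-list", "dense"),
                              miRNA_ids = NULL, disease_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "edge-list") {
    df <- tryCatch(
      utils::read.table(path, sep = "\t", header = FALSE,
                        comment.char = "#", colClasses = "character",
                        blank.lines.skip = TRUE),
      error = function(e) {
        if (grepl("no lines available", conditionMessage(e))) {
          data.frame(V1 = character(), V2 = character())
        } else stop(e)
      })
    if (nrow(df) > 0 && ncol(df) < 2) {
      stop("edge list rows must have (miRNA_id, disease_id) columns")
    }
    m <- if (nrow(df)) df[[1]] else character()
    d <- if (nrow(df)) df[[2]] else character()
    if (anyDuplicated(paste0(m, "\r", d))) {
      warning("duplicate edges in association list; keeping one copy")
      keep <- !duplicated(paste0(m, "\r", d))
      m <- m[keep]; d <- d[keep]
    }
    if (is.null(miRNA_ids)) miRNA_ids <- unique(m)
    if (is.null(disease_ids)) disease_ids <- unique(d)
    if (length(miRNA_ids) == 0 || length(disease_ids) == 0) {
      stop("empty edge list requires declared miRNA_ids and disease_ids")
    }
    if (!all(m %in% miRNA_ids) || !all(d %in% disease_ids)) {
      stop("edge list references identifiers outside the declared universe")
    }
    A <- matrix(0L, length(miRNA_ids), length(disease_ids))
    A[cbind(match(m, miRNA_ids), match(d, disease_ids))] <- 1L
    association_matrix(A, miRNA_ids, disease_ids)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE,
                            comment.char = "#")
    A <- as.matrix(df)
    if (anyNA(A) || !all(A %in% c(0, 1))) {
      stop("dense association matrix entries must be 0 or 1")
    }
    association_matrix(A, rownames(df), colnames(df))
  }
}

#' Write an association matrix to disk
#'
#' Inverse of [read_associations()]; round trips are bit-exact in both
#' formats (the edge-list round trip additionally needs the id universes
#' when some entity has no association).
#'
#' @param A an [association_matrix()].
#' @param path output file path.
#' @param format `"edge-list"` or `"dense"`.
#' @export
write_associations <- function(A, path, format = c("edge-list", "dense")) {
  format <- match.arg(format)
  if (format == "edge-list") {
    idx <- which(t(unclass(A)) == 1L)   # row-major pair order
    nd <- ncol(A)
    i <- (idx - 1L) %/% nd + 1L
    j <- (idx - 1L) %% nd + 1L
    utils::write.table(
      data.frame(rownames(A)[i], colnames(A)[j]),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    df <- as.data.frame(unclass(A))
    utils::write.table(cbind(id = rownames(A), df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Read a dense similarity matrix from disk
#'
#' Expects a TSV with a header row and a first column both carrying the
#' same identifiers in the same order. Values must be finite and in
#' `[0, 1]`; asymmetries up to `1e-8` are averaged away, larger ones are
#' rejected.
#'
#' @param path file path.
#' @return a [similarity_matrix()].
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  S <- as.matrix(df)
  if (nrow(S) != ncol(S)) stop("similarity table must be square")
  if (!identical(rownames(S), colnames(S))) {
    stop("row and column identifiers must match")
  }
  similarity_matrix(S, rownames(S))
}

#' Write a similarity matrix to disk
#'
#' @param S a [similarity_matrix()] (or plain named square matrix).
#' @param path output file path.
#' @export
write_similarity <- function(S, path) {
  utils::write.table(cbind(id = rownames(S), as.data.frame(unclass(S))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a disease ontology from a child-parent edge list
#'
#' @param path TSV of `child<TAB>parent` rows; `#` comments skipped.
#' @param diseases optional character vector, or path to a one-column
#'   file, naming the diseases of interest; defaults to all terms.
#' @return a [disease_ontology()].
#' @export
read_ontology <- function(path, diseases = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", colClasses = "character",
                          blank.lines.skip = TRUE)
  if (is.character(diseases) && length(diseases) == 1 &&
      file.exists(diseases)) {
    diseases <- utils::read.table(diseases, header = FALSE,
                                  colClasses = "character")[[1]]
  }
  disease_ontology(df, disease_ids = diseases)
}

#' Write ranked association scores to disk
#'
#' Produces a TSV with columns `miRNA_id`, `disease_id`, `score`, `rank`,
#' where rank 1 is the highest score and ties keep input order.
#'
#' @param pairs two-column data frame (miRNA_id, disease_id).
#' @param scores numeric vector, one score per pair.
#' @param path output file path.
#' @return the written data frame, invisibly.
#' @export
write_scores <- function(pairs, scores, path) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) != length(scores)) {
    stop("pairs and scores must have equal length")
  }
  rnk <- integer(length(scores))
  rnk[order(-scores, seq_along(scores))] <- seq_along(scores)
  df <- data.frame(miRNA_id = if (nrow(pairs)) as.character(pairs[[1]]) else character(),
                   disease_id = if (nrow(pairs)) as.character(pairs[[2]]) else character(),
                   score = as.numeric(scores), rank = rnk,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
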