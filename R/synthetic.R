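#' Specification of a synthetic benchmark dataset
#'
#' The generator emulates the three inputs of the pipeline at desk
#' scale: a sparse binary association matrix with planted block
#' structure (functionally related miRNAs associate with related
#' diseases), a noisy base similarity matrix with structural zeros
#' (emulating the sparsity of precomputed functional-similarity
#' downloads), and a forest of layered disease DAGs whose subtrees
#' follow the disease blocks so that semantic similarity carries real
#' signal.
#'
#' @param nm,nd numbers of miRNAs and diseases (each >= `n_blocks`).
#' @param n_blocks number of planted miRNA-disease co-clusters.
#' @param density_in probability of a known association inside a
#'   co-cluster.
#' @param density_out probability outside (must be < `density_in`).
#' @param sim_noise SD of the half-normal noise on the block-indicator
#'   similarity.
#' @param sim_sparsity fraction of off-diagonal base-similarity entries
#'   forced to exactly 0.
#' @param dag_depth number of internal ancestor layers per block subtree.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(nm = 30, nd = 20, n_blocks = 3,
                           density_in = 0.5, density_out = 0.02,
                           sim_noise = 0.1, sim_sparsity = 0.3,
                           dag_depth = 3, seed = 7) {
  if (nm < n_blocks || nd < n_blocks) {
    stop("nm and nd must be at least n_blocks")
  }
  if (density_in <= 0 || density_in > 1 || density_out < 0 ||
      density_out >= 1 || density_in <= density_out) {
    stop("need 0 <= density_out < density_in <= 1")
  }
  if (sim_noise < 0 || sim_sparsity < 0 || sim_sparsity >= 1) {
    stop("invalid noise/sparsity settings")
  }
  if (dag_depth < 1) stop("dag_depth must be at least 1")
  structure(list(nm = nm, nd = nd, n_blocks = n_blocks,
                 density_in = density_in, density_out = density_out,
                 sim_noise = sim_noise, sim_sparsity = sim_sparsity,
                 dag_depth = dag_depth, seed = as.integer(seed)),
            class = "synthetic_spec")
}

block_assignment <- function(n, n_blocks) {
  sort(rep(seq_len(n_blocks), length.out = n))
}

#' Generate a synthetic benchmark dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `"synthetic_data"` with elements `A`
#'   ([association_matrix()]), `SM_base` ([similarity_matrix()]),
#'   `ontology` ([disease_ontology()]), the block assignments
#'   `miRNA_blocks`, `disease_blocks`, and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    mb <- block_assignment(spec$nm, spec$n_blocks)
    db <- block_assignment(spec$nd, spec$n_blocks)
    mids <- sprintf("mir-%03d", seq_len(spec$nm))
    dids <- sprintf("dis-%03d", seq_len(spec$nd))

    same <- outer(mb, db, "==")
    p <- ifelse(same, spec$density_in, spec$density_out)
    A <- matrix(as.integer(stats::runif(spec$nm * spec$nd) < p),
                spec$nm, spec$nd)
    # guarantee the GIP bandwidth is defined even at extreme settings
    if (sum(A) == 0) A[1, 1] <- 1L

    # block-indicator similarity with half-normal perturbations; exact
    # zeros come only from the forced-sparsity mask below
    msame <- outer(mb, mb, "==")
    noise <- abs(matrix(stats::rnorm(spec$nm^2, 0, spec$sim_noise),
                        spec$nm, spec$nm))
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    S <- ifelse(msame, pmax(0, 1 - noise), pmin(1, noise))
    ut <- which(upper.tri(S))
    drop <- ut[stats::runif(length(ut)) < spec$sim_sparsity]
    S[drop] <- 0
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    diag(S) <- 1

    # one subtree per block: a chain of dag_depth internal terms with the
    # block's diseases as leaves; subtrees are disjoint (a forest), so
    # cross-block semantic similarity is exactly 0
    edges <- do.call(rbind, lapply(seq_len(spec$n_blocks), function(b) {
      internal <- sprintf("blk%d_anc%d", b, seq_len(spec$dag_depth))
      chain <- if (spec$dag_depth > 1) {
        data.frame(child = internal[-1],
                   parent = internal[-spec$dag_depth])
      } else NULL
      leaves <- data.frame(child = dids[db == b],
                           parent = internal[spec$dag_depth])
      rbind(chain, leaves)
    }))
    ont <- disease_ontology(edges, disease_ids = dids)

    structure(list(A = association_matrix(A, mids, dids),
                   SM_base = similarity_matrix(S, mids),
                   ontology = ont,
                   miRNA_blocks = mb, disease_blocks = db,
                   spec = spec),
              class = "synthetic_data")
  })
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat(sprintf(
    "synthetic_data: %d miRNAs x %d diseases, %d blocks, %d known associations\n",
    x$spec$nm, x$spec$nd, x$spec$n_blocks, sum(unclass(x$A))))
  invisible(x)
}

#' Planted held-out truth pairs of a synthetic dataset
#'
#' The within-block pairs whose association entry is 0: unknown to the
#' model but structurally likely, so a good predictor should rank them
#' above out-of-block unknown pairs. Disjoint from the known positives
#' by construction.
#'
#' @param data a `"synthetic_data"` object.
#' @return integer matrix of `(i, j)` index pairs (row-major order).
#' @export
planted_truth <- function(data) {
  stopifnot(inherits(data, "synthetic_data"))
  zeros <- pairs_where(data$A, 0L)
  same <- data$miRNA_blocks[zeros[, 1]] == data$disease_blocks[zeros[, 2]]
  zeros[same, , drop = FALSE]
}

#' Write a synthetic dataset in the package's on-disk formats
#'
#' Materializes `associations.tsv` (edge list), `mirnas.tsv` /
#' `diseases.tsv` (identifier universes), `sm_base.tsv` (dense
#' similarity) and `ontology.tsv` (child-parent edges) under `dir`.
#'
#' @param data a `"synthetic_data"` object.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  stopifnot(inherits(data, "synthetic_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_associations(data$A, file.path(dir, "associations.tsv"),
                     "edge-list")
  writeLines(rownames(data$A), file.path(dir, "mirnas.tsv"))
  writeLines(colnames(data$A), file.path(dir, "diseases.tsv"))
  write_similarity(data$SM_base, file.path(dir, "sm_base.tsv"))
  utils::write.table(data$ontology$edges, file.path(dir, "ontology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}
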