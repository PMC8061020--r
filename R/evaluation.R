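#' Area under the ROC curve from two score samples
#'
#' The AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted half:
#' `AUC = P(s+ > s-) + 0.5 P(s+ = s-)`. This equals the area obtained by
#' sweeping every observed score as a rank threshold and plotting TPR
#' against FPR. Computed via the rank-sum (Mann-Whitney) identity, which
#' handles ties exactly.
#'
#' @param scores_pos scores of the positive examples.
#' @param scores_neg scores of the negative examples.
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both score vectors must be nonempty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points from a threshold sweep
#'
#' @param scores_pos,scores_neg score samples as in [roc_auc()].
#' @return data frame with columns `threshold`, `FPR`, `TPR`, one row per
#'   distinct score (scores at or above the threshold are called
#'   positive), plus the (1, 1) endpoint.
#' @export
roc_points <- function(scores_pos, scores_neg) {
  thr <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  data.frame(
    threshold = c(thr, -Inf),
    FPR = c(vapply(thr, function(t) mean(scores_neg >= t), numeric(1)), 1),
    TPR = c(vapply(thr, function(t) mean(scores_pos >= t), numeric(1)), 1))
}

new_cv_result <- function(scheme, per_fold_auc, mean_auc, sd_auc,
                          n_repeats, seeds) {
  structure(list(scheme = scheme, per_fold_auc = per_fold_auc,
                 mean_auc = mean_auc, sd_auc = sd_auc,
                 n_repeats = n_repeats, seeds = seeds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation: mean AUC %.4f (sd %.4f, %d repeats, %d folds)\n",
              x$scheme, x$mean_auc, x$sd_auc, x$n_repeats,
              length(x$per_fold_auc)))
  invisible(x)
}

# Resolve the disease semantic similarity once: DAGs do not depend on A,
# so only the GIP kernels are recomputed inside CV folds.
resolve_sd_sem <- function(A, ontology) {
  if (inherits(ontology, "disease_ontology")) {
    sd <- semantic_similarity(ontology)$SD_sem
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
}

# One CV evaluation: zero the held-out positives in A, recompute GIP
# kernels and fusion, build the balanced training set, fit, and score the
# held-out pairs against all unknown candidate pairs of the original A.
cv_fold_eval <- function(A, SM_base, SD_sem, heldout, candidates, config,
                         fold_seed) {
  A2 <- unclass(A)
  A2[heldout] <- 0L
  A2 <- association_matrix(A2, rownames(A), colnames(A))
  sims <- build_similarity(A2, SM_base, SD_sem)
  ts <- build_training_set(A2, sims$SM, sims$SD, fold_seed)
  model <- hgl_fit(ts$X, ts$y, config)
  s_test <- hgl_score(model, pair_feature_matrix(sims$SM, sims$SD, heldout))
  s_cand <- hgl_score(model, pair_feature_matrix(sims$SM, sims$SD, candidates))
  list(auc = roc_auc(s_test, s_cand), s_test = s_test, s_cand = s_cand)
}

#' Leave-one-out cross-validation over known associations
#'
#' Each known association is held out in turn: its entry in `A` is set
#' to 0, the GIP kernels and fused similarities are recomputed from the
#' modified matrix (the kernels depend on `A`, so the held-out link must
#' not leak), a balanced training set is drawn from the remaining
#' positives, the model is fitted, and the held-out pair is scored
#' against all unknown candidate pairs. Each fold's AUC is the held-out
#' pair's percentile among the candidate scores (ties counted half); the
#' global AUC pools these rank thresholds by averaging.
#'
#' @param A an [association_matrix()] with at least 2 positives.
#' @param SM_base miRNA functional [similarity_matrix()].
#' @param ontology a [disease_ontology()] or a precomputed disease
#'   semantic [similarity_matrix()].
#' @param config an [hgl_config()].
#' @param seed integer master seed (negative sampling per fold derives
#'   from it).
#' @param max_test_pairs optional cap: evaluate only a seeded subsample
#'   of this many held-out pairs (an approximation of the exhaustive
#'   protocol for large matrices).
#' @param collect_scores if `TRUE`, attach the per-fold held-out and
#'   candidate scores (for ROC export) as `fold_scores`.
#' @return a `"cv_result"`.
#' @export
loocv <- function(A, SM_base, ontology, config = hgl_config(), seed = 1,
                  max_test_pairs = NULL, collect_scores = FALSE) {
  SD_sem <- resolve_sd_sem(A, ontology)
  pos <- pairs_where(A, 1L)
  if (nrow(pos) < 2) stop("need at least 2 known associations for LOOCV")
  test_idx <- seq_len(nrow(pos))
  if (!is.null(max_test_pairs) && max_test_pairs < nrow(pos)) {
    test_idx <- with_seed(sub_seed(seed, 0L),
                          sort(sample.int(nrow(pos), max_test_pairs)))
  }
  candidates <- enumerate_candidates(A)
  folds <- lapply(seq_along(test_idx), function(t) {
    heldout <- pos[test_idx[t], , drop = FALSE]
    cv_fold_eval(A, SM_base, SD_sem, heldout, candidates, config,
                 sub_seed(seed, t))
  })
  aucs <- vapply(folds, `[[`, numeric(1), "auc")
  res <- new_cv_result("loocv", aucs, mean(aucs),
                       if (length(aucs) > 1) stats::sd(aucs) else 0,
                       1L, seed)
  if (collect_scores) res$fold_scores <- folds
  res
}

#' Repeated k-fold cross-validation over known associations
#'
#' Known positives are partitioned into `n_folds` random folds per
#' repeat. Each fold is zeroed in `A` before the GIP kernels and fusion
#' are recomputed, the model is refitted on a balanced training set
#' drawn from the remaining positives, and the fold's positives are
#' scored against all unknown candidate pairs; the fold AUC compares the
#' two score samples. Reported as mean and SD of the repeat-level mean
#' AUCs.
#'
#' @inheritParams loocv
#' @param n_folds number of folds (>= 2); every fold must receive at
#'   least one positive.
#' @param n_repeats number of independent repetitions.
#' @return a `"cv_result"` with `n_folds * n_repeats` per-fold AUCs.
#' @export
kfold_cv <- function(A, SM_base, ontology, config = hgl_config(),
                     n_folds = 5, n_repeats = 1, seed = 1,
                     collect_scores = FALSE) {
  if (n_folds < 2) stop("n_folds must be at least 2")
  SD_sem <- resolve_sd_sem(A, ontology)
  pos <- pairs_where(A, 1L)
  if (nrow(pos) < n_folds) {
    stop("fewer known associations than folds: a fold would be empty")
  }
  candidates <- enumerate_candidates(A)
  all_folds <- list()
  repeat_means <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    assign_f <- with_seed(sub_seed(seed, 1000L + r),
                          sample(rep(seq_len(n_folds),
                                     length.out = nrow(pos))))
    folds <- lapply(seq_len(n_folds), function(f) {
      heldout <- pos[assign_f == f, , drop = FALSE]
      cv_fold_eval(A, SM_base, SD_sem, heldout, candidates, config,
                   sub_seed(seed, 1000000L + r * 1000L + f))
    })
    all_folds <- c(all_folds, folds)
    repeat_means[r] <- mean(vapply(folds, `[[`, numeric(1), "auc"))
  }
  res <- new_cv_result("kfold",
                       vapply(all_folds, `[[`, numeric(1), "auc"),
                       mean(repeat_means),
                       if (n_repeats > 1) stats::sd(repeat_means) else 0,
                       as.integer(n_repeats), seed)
  if (collect_scores) res$fold_scores <- all_folds
  res
}

#' Cross-validated sweep over model hyperparameters
#'
#' Runs one cross-validation per grid point of `(k, lambda, mu)` and
#' tabulates the mean AUCs.
#'
#' @inheritParams kfold_cv
#' @param grid list with numeric vectors `k`, `lambda`, `mu`.
#' @param scheme `"kfold"` or `"loocv"`.
#' @param max_test_pairs passed to [loocv()] when `scheme = "loocv"`.
#' @return data frame with columns `k`, `lambda`, `mu`, `mean_auc`,
#'   `sd_auc`.
#' @export
parameter_sweep <- function(A, SM_base, ontology,
                            grid = list(k = 15, lambda = 10, mu = 1),
                            scheme = c("kfold", "loocv"), n_folds = 5,
                            n_repeats = 1, seed = 1,
                            max_test_pairs = NULL) {
  scheme <- match.arg(scheme)
  if (!all(c("k", "lambda", "mu") %in% names(grid)) ||
      !all(lengths(grid[c("k", "lambda", "mu")]) >= 1)) {
    stop("grid must supply nonempty k, lambda and mu vectors")
  }
  pts <- expand.grid(k = grid$k, lambda = grid$lambda, mu = grid$mu,
                     KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(pts)), function(g) {
    cfg <- hgl_config(pts$k[g], pts$lambda[g], pts$mu[g])
    cv <- if (scheme == "kfold") {
      kfold_cv(A, SM_base, ontology, cfg, n_folds, n_repeats, seed)
    } else {
      loocv(A, SM_base, ontology, cfg, seed, max_test_pairs)
    }
    c(mean_auc = cv$mean_auc, sd_auc = cv$sd_auc)
  })
  cbind(pts, do.call(rbind, res))
}
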