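test_that("GIP kernel matches hand-computed values and identities", {
  # rows (1,0) and (0,1): gamma = 1/((1+1)/2) = 1, K(1,2) = exp(-2)
  res <- gip_kernel(rbind(c(1, 0), c(0, 1)))
  expect_equal(res$gamma, 1)
  expect_equal(unclass(res$K)[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(diag(unclass(res$K)), c(1, 1), ignore_attr = TRUE)

  # identical profiles are maximally similar
  res <- gip_kernel(rbind(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(unclass(res$K)[1, 2], 1)

  expect_error(gip_kernel(matrix(0, 3, 4)), "bandwidth undefined")
  expect_error(gip_kernel(matrix(0.5, 2, 2)), "binary")
})

test_that("GIP kernel is symmetric PSD with unit diagonal on random profiles", {
  for (s in 1:20) {
    P <- rand_profiles(sample(3:12, 1), sample(2:10, 1), seed = s)
    K <- unclass(gip_kernel(P)$K)
    expect_equal(K, t(K))
    expect_equal(diag(K), rep(1, nrow(K)), ignore_attr = TRUE)
    expect_true(all(K > 0 & K <= 1))
    expect_gte(min(eigen(K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("adding a shared association never decreases GIP similarity", {
  # exhaustive over all 3x3 binary profile matrices, all entity pairs and
  # all columns where both entities are 0
  grid <- expand.grid(rep(list(0:1), 9))
  for (r in seq_len(nrow(grid))) {
    P <- matrix(as.integer(grid[r, ]), 3, 3)
    if (sum(P) == 0) next
    K <- unclass(gip_kernel(P)$K)
    for (a in 1:2) for (b in (a + 1):3) for (cc in 1:3) {
      if (P[a, cc] == 0 && P[b, cc] == 0) {
        P2 <- P
        P2[a, cc] <- 1L; P2[b, cc] <- 1L
        K2 <- unclass(gip_kernel(P2)$K)
        expect_gte(K2[a, b], K[a, b] - 1e-12)
      }
    }
  }
})

test_that("semantic values match hand evaluation", {
  ont <- disease_ontology(data.frame(child = "d1", parent = "d2"))
  sv <- semantic_value(ont, "d1")
  expect_equal(sv$DV, log(2), tolerance = 1e-12)
  expect_equal(sort(names(sv$contributions)), c("d1", "d2"))
  expect_equal(unname(sv$contributions["d1"]), log(2), tolerance = 1e-12)
  expect_equal(unname(sv$contributions["d2"]), 0)
  expect_equal(semantic_value(ont, "d2")$DV, 0)
  # single isolated disease: -log(1/1) = 0
  lone <- disease_ontology(data.frame(child = character(),
                                      parent = character()),
                           terms = "d1")
  expect_equal(semantic_value(lone, "d1")$DV, 0)
  expect_error(semantic_value(ont, "nope"), "not a disease")
})

test_that("semantic similarity matches hand evaluation and the DV=0 guard", {
  ont <- disease_ontology(data.frame(child = "d1", parent = "d2"))
  res <- semantic_similarity(ont)
  S <- unclass(res$SD_sem)
  # shared term d2 contributes 0 + 0 over log2 + 0
  expect_equal(S["d1", "d2"], 0)
  expect_equal(S["d1", "d1"], 1)  # 2 DV / 2 DV
  expect_equal(S["d2", "d2"], 1)  # DV = 0 guard
  # disjoint subtrees share nothing
  ont2 <- disease_ontology(data.frame(child = c("a", "b"),
                                      parent = c("ra", "rb")),
                           disease_ids = c("a", "b"))
  expect_equal(unclass(semantic_similarity(ont2)$SD_sem)["a", "b"], 0)
})

test_that("semantic similarity equals the ancestor-enumeration oracle", {
  for (s in 1:50) {
    dag <- bf_random_dag(sample(4:12, 1), seed = 1000 + s)
    ont <- disease_ontology(dag$edges, terms = dag$terms,
                            disease_ids = dag$diseases)
    got <- unclass(semantic_similarity(ont)$SD_sem)
    want <- bf_semantic_similarity(dag$edges, dag$diseases)
    expect_equal(got[dag$diseases, dag$diseases],
                 want[dag$diseases, dag$diseases],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("fusion uses the kernel at structural zeros and averages elsewhere", {
  base <- similarity_matrix(matrix(c(1, 0, 0, 1), 2), c("a", "b"))
  gip <- similarity_matrix(matrix(c(1, .4, .4, 1), 2), c("a", "b"))
  expect_equal(unclass(fuse_similarity(base, gip))[1, 2], 0.4)

  base2 <- similarity_matrix(matrix(c(1, .6, .6, 1), 2), c("a", "b"))
  expect_equal(unclass(fuse_similarity(base2, gip))[1, 2], 0.5)
  expect_equal(unclass(fuse_similarity(gip, gip)), unclass(gip))
  expect_error(fuse_similarity(base, similarity_matrix(diag(3))),
               "mismatch")
})

test_that("fusion preserves symmetry and [0,1] on random inputs", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(3:8, 1)
    mk <- function() {
      M <- matrix(runif(n * n), n, n)
      M[sample(n * n, n)] <- 0
      M <- (M + t(M)) / 2
      diag(M) <- 1
      similarity_matrix(M, paste0("x", 1:n))
    }
    fused <- unclass(fuse_similarity(mk(), mk()))
    expect_equal(fused, t(fused))
    expect_true(all(fused >= 0 & fused <= 1))
  }
})
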