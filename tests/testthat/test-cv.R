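test_that("pairwise identity matches hand alignments and is symmetric", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1.0)
  # no-gap global alignment: 3 identities over alignment length 4
  expect_equal(pairwise_identity("ACDE", "ACDW"), 0.75)
  for (seed in 1:5) {
    a <- rand_seq(40, seed); b <- rand_seq(35, seed + 50)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_gte(pairwise_identity(a, b), 0)
    expect_lte(pairwise_identity(a, b), 1)
  }
})

test_that("homology folds respect single-linkage clusters and balance", {
  # 10 mutually dissimilar proteins, equal counts -> 2 per fold
  seqs <- make_dissimilar_families(10, 1, seed = 2)
  folds <- homology_folds(seqs, k = 5, seed = 1)
  expect_equal(sort(as.numeric(table(folds$fold))), rep(2, 5))

  # two identical sequences always share a fold
  twin <- seqs
  twin$FAM1_1b <- protein_sequence("FAM1_1b", seqs$FAM1_1$residues)
  f2 <- homology_folds(twin, k = 3, seed = 7)
  expect_equal(f2$fold[f2$protein_id == "FAM1_1"],
               f2$fold[f2$protein_id == "FAM1_1b"])

  # chaining: A~B (high), B~C (high), A-C (low) -> all one fold
  base <- strsplit(rand_seq(100, 9), "")[[1]]
  mutate_at <- function(chars, idx) {
    chars[idx] <- vapply(chars[idx], function(a)
      sample(setdiff(c("A","C","D","E","G"), a), 1), "")
    chars
  }
  set.seed(10)
  A <- base
  B <- mutate_at(base, 1:60)            # A-B ~40% identical
  C <- mutate_at(B, 41:100)             # B-C ~40%, A-C low
  chain <- list(A = protein_sequence("A", paste(A, collapse = "")),
                B = protein_sequence("B", paste(B, collapse = "")),
                C = protein_sequence("C", paste(C, collapse = "")))
  dissim <- make_dissimilar_families(4, 1, seed = 33)
  ids_ab <- pairwise_identity(chain$A, chain$B)
  ids_bc <- pairwise_identity(chain$B, chain$C)
  ids_ac <- pairwise_identity(chain$A, chain$C)
  expect_gt(ids_ab, 0.25); expect_gt(ids_bc, 0.25); expect_lt(ids_ac, 0.25)
  f3 <- homology_folds(c(chain, dissim), k = 3, seed = 1)
  expect_equal(length(unique(f3$fold[f3$protein_id %in% c("A", "B", "C")])),
               1L)

  # determinism
  expect_identical(homology_folds(seqs, k = 5, seed = 3),
                   homology_folds(seqs, k = 5, seed = 3))
  # fewer clusters than folds is an error
  expect_error(homology_folds(twin["FAM1_1"], k = 2), "cannot build|cluster")
})

test_that("no cross-fold pair exceeds the identity threshold", {
  seqs <- make_dissimilar_families(6, 3, mut_rate = 0.3, seed = 5)
  folds <- homology_folds(seqs, k = 3, threshold = 0.25, seed = 2)
  ids <- attr(folds, "identities")
  n <- nrow(ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (folds$fold[i] != folds$fold[j])
      expect_lte(ids[i, j], 0.25)
  # families stay together (members share >25% identity)
  fam <- attr(seqs, "family")
  for (f in unique(fam))
    expect_equal(length(unique(folds$fold[fam == f])), 1L)
})

test_that("cross-validation isolates proteins and honours an oracle", {
  task <- make_task(n_proteins = 8, n_variants = 32,
                    length_range = c(30L, 40L),
                    embedder = embedder_mock(d = 8, k = 3, seed = 5),
                    seed = 21)
  # with a perfect oracle predictor injected, every fold is exact
  cv <- stabemb_cv(task$variants, task$sequences, k = 2,
                   embedder = task$embedder,
                   control = stabemb_control(seed = 1),
                   predictor = function(tr, te, seqs) te$ddg)
  expect_equal(nrow(cv$per_fold), 2L)
  expect_equal(cv$per_fold$PCC, c(1, 1))
  expect_equal(cv$per_fold$RMSE, c(0, 0))
  expect_equal(cv$summary$mean[cv$summary$statistic == "PCC"], 1)
  expect_equal(cv$summary$sd[cv$summary$statistic == "RMSE"], 0)

  # split contract: held-out proteins never appear in training
  seen <- new.env()
  cv2 <- stabemb_cv(task$variants, task$sequences, k = 2,
                    embedder = task$embedder,
                    control = stabemb_control(seed = 1),
                    predictor = function(tr, te, seqs) {
                      expect_length(intersect(unique(tr$protein_id),
                                              unique(te$protein_id)), 0)
                      assign(paste(sort(unique(te$protein_id)),
                                   collapse = ","), TRUE, envir = seen)
                      rep(0, nrow(te))
                    })
  expect_equal(length(ls(seen)), 2L)
})
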