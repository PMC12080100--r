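test_that("pairwise identity matches trivial cases and the DP oracle", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_error(pairwise_identity("", "ACD"), "empty")

  # related 50-mers (point mutations, truncations, an internal deletion):
  # instances where the optimal alignment is unique, so the identity is
  # well-defined and must equal the independent DP oracle's value
  alph <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(61)
  for (k in 1:4) {
    a <- paste(sample(alph, 50, replace = TRUE), collapse = "")
    v <- strsplit(a, "")[[1]]
    idx <- sample(50, 12)
    v[idx] <- sample(alph, 12, replace = TRUE)
    b <- paste(v, collapse = "")
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
                 tolerance = 1e-9)
  }
  a <- paste(sample(alph, 40, replace = TRUE), collapse = "")
  b <- paste0(substr(a, 1, 18), substr(a, 22, 40))       # internal deletion
  expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
               tolerance = 1e-9)
  b2 <- substr(a, 6, 40)                                  # truncation
  expect_equal(pairwise_identity(a, b2), oracle_identity(a, b2),
               tolerance = 1e-9)
})

test_that("greedy clustering groups by identity threshold", {
  seqs <- c(s1 = "ACDEFGHIKLMNPQRSTVWY", s2 = "ACDEFGHIKLMNPQRSTVWY",
            s3 = "ACDEFGHIKLMNPQRSTVWY")
  cl <- cluster_sequences(seqs)
  expect_equal(length(cl$representative), 1L)
  expect_equal(unname(cl$cluster_id), rep(1L, 3))

  two <- c(a = "ACDEFGHIKLACDEFGHIKL", b = "WYWYWYWYWYWYWYWYWYWY")
  cl2 <- cluster_sequences(two)
  expect_equal(length(cl2$representative), 2L)

  # a sequence at measured identity > 0.5 to a representative joins it
  base <- paste(rep("ACDEFGHIKL", 4), collapse = "")
  mut <- strsplit(base, "")[[1]]
  mut[seq(1, 15)] <- "W"  # 25/40 identical -> 0.625
  mem <- paste(mut, collapse = "")
  expect_gt(pairwise_identity(base, mem), 0.5)
  cl3 <- cluster_sequences(c(r = base, m = mem))
  expect_equal(unname(cl3$cluster_id["m"]), unname(cl3$cluster_id["r"]))
})

test_that("the similarity predicate needs same cluster, column and type", {
  seqA <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = "")
  seqB <- paste(rep("YVTSRQPNMLKIHGFEDCAW", 2), collapse = "")
  recs <- pka_records(c("P1", "P2", "P3", "P4"), "A",
                      c(3, 3, 3, 4),
                      c("ASP", "ASP", "ASP", "GLU"),
                      c(3.5, 3.6, 3.4, 4.2),
                      c(seqA, seqA, seqB, seqA))
  cl <- cluster_sequences(setNames(recs$sequence, recs$seq_id))
  # same residue of the same sequence under two structure ids
  expect_true(is_similar(recs[1, ], recs[2, ], cl))
  # different clusters
  expect_false(is_similar(recs[1, ], recs[3, ], cl))
  # same cluster + column but different residue type: column 3 ASP vs GLU
  recs2 <- recs; recs2$residue_type[2] <- "GLU"
  expect_false(is_similar(recs2[1, ], recs2[2, ], cl))
  # symmetry
  expect_equal(is_similar(recs[1, ], recs[2, ], cl),
               is_similar(recs[2, ], recs[1, ], cl))
  # different columns
  expect_false(is_similar(recs[1, ], recs[4, ], cl))
})

test_that("records in unshared clusters never trip the test-set filter", {
  toy <- fix_pka_toy()
  only_c <- toy$test[toy$test$structure_id %in% sprintf("TE%02d", 3:10), ]
  sp <- split_dataset(toy$train, ratio = 0.8, test_source = only_c, seed = 1)
  # the disjoint-source records share no cluster with training: all kept
  # except internal duplicates
  expect_equal(nrow(sp$audit$test_vs_trainval_pairs), 0L)
  expect_equal(nrow(sp$audit$verify_train_test), 0L)
})

test_that("the splitter detects planted leaks and ends with a clean audit", {
  toy <- fix_pka_toy()
  cl <- cluster_sequences(
    c(setNames(toy$train$sequence, toy$train$seq_id),
      setNames(toy$test$sequence, toy$test$seq_id))[
        !duplicated(c(toy$train$seq_id, toy$test$seq_id))])
  # the construction plants exactly two cross-set similar pairs
  planted <- pgnn:::similar_pairs(toy$test, toy$train, cl)
  expect_equal(nrow(planted), 2L)
  expect_equal(sort(unname(planted[, "i"])), c(1L, 2L))
  expect_equal(sort(unname(planted[, "j"])), c(1L, 2L))

  sp <- split_dataset(toy$train, ratio = 1.0, test_source = toy$test,
                      clusters = cl, seed = 2)
  expect_equal(nrow(sp$audit$test_vs_trainval_pairs), 2L)
  expect_equal(nrow(sp$audit$verify_train_test), 0L)
  # exhaustive post-hoc scan across train x test finds nothing
  post <- pgnn:::similar_pairs(sp$test, sp$train, cl)
  expect_equal(nrow(post), 0L)
  expect_equal(nrow(sp$test), nrow(toy$test) - 2L)
})

test_that("validation is deduplicated and purged against training", {
  seqA <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = "")
  recs <- pka_records(sprintf("S%d", 1:6), "A",
                      c(3, 3, 5, 7, 9, 11),
                      c("ASP", "ASP", "GLU", "HIS", "LYS", "CYS"),
                      seq(3, 8, by = 1), rep(seqA, 6))
  # force a deterministic split: duplicate residue 3 appears in both halves
  set.seed(3)
  sp <- split_dataset(recs, ratio = 0.5, seed = 3)
  all_pairs <- pgnn:::similar_pairs(sp$validation, sp$train, sp$clusters)
  expect_equal(nrow(all_pairs), 0L)
  internal <- pgnn:::similar_pairs(sp$validation, clusters = sp$clusters)
  expect_equal(nrow(internal), 0L)
})
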