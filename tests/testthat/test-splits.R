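test_that("normalized Smith-Waterman similarity matches the DP oracle exactly", {
  sub <- pepnet:::get_submat("BLOSUM62")

  expect_equal(normalized_sw("ACDEFG", "ACDEFG"), 1)
  expect_equal(normalized_sw("ACDEFG", "ACDKFG"),
               oracle_norm_sw("ACDEFG", "ACDKFG", sub), tolerance = 1e-12)

  set.seed(21)
  for (r in 1:50) {
    a <- random_aa_string(sample(6:20, 1))
    b <- random_aa_string(sample(6:20, 1))
    expect_equal(normalized_sw(a, b), oracle_norm_sw(a, b, sub),
                 tolerance = 1e-12)
    expect_equal(normalized_sw(a, b), normalized_sw(b, a), tolerance = 1e-12)
  }
  expect_error(normalized_sw("", "ACD"), "non-empty")

  # the similarity matrix agrees with the scalar function
  seqs <- c(s1 = "ACDEFGHIK", s2 = "ACDEFGHIR", s3 = "WWYYPPGG")
  sm <- sw_similarity_matrix(seqs)
  expect_equal(diag(sm), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sm["s1", "s2"], normalized_sw(seqs[["s1"]], seqs[["s2"]]),
               tolerance = 1e-12)
  expect_equal(sm, t(sm))
})

test_that("single-linkage clustering equals union-find components", {
  # chain A~B~C merges despite A!~C
  sim <- diag(1, 3)
  dimnames(sim) <- list(c("A", "B", "C"), c("A", "B", "C"))
  sim["A", "B"] <- sim["B", "A"] <- 0.9
  sim["B", "C"] <- sim["C", "B"] <- 0.9
  sim["A", "C"] <- sim["C", "A"] <- 0.2
  cl <- cluster_entities(c(A = "x", B = "x", C = "x"), t = 0.5, sim = sim)
  expect_equal(length(unique(cl)), 1)

  # threshold above every similarity -> all singletons
  cl2 <- cluster_entities(c(A = "x", B = "x", C = "x"), t = 0.95, sim = sim)
  expect_equal(length(unique(cl2)), 3)

  # random instances vs the union-find oracle
  set.seed(31)
  for (r in 1:10) {
    n <- 20
    ids <- sprintf("s%02d", 1:n)
    sim <- matrix(runif(n * n, 0, 0.6), n, n)
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 1
    dimnames(sim) <- list(ids, ids)
    t0 <- 0.45
    cl <- cluster_entities(stats::setNames(rep("x", n), ids), t = t0, sim = sim)
    edges <- which(sim >= t0 & upper.tri(sim), arr.ind = TRUE)
    edge_df <- cbind(ids[edges[, 1]], ids[edges[, 2]])
    want <- oracle_components(ids, edge_df)
    expect_identical(unname(cl[ids]), unname(want[ids]))
  }

  # real sequences: family expansion is recovered at a high threshold
  set.seed(5)
  anc <- stats::setNames(vapply(rep(80, 4), random_aa_string, character(1)),
                         paste0("f", 1:4))
  fam <- family_expand(anc, copies = 4, mutation_rate = 0.05, seed = 8)
  cl <- cluster_entities(fam$sequences, t = 0.8)
  expect_identical(length(unique(cl)), 4L)
  for (f in unique(fam$family)) {
    members <- names(fam$family)[fam$family == f]
    expect_identical(length(unique(cl[members])), 1L)
  }
})

test_that("fold construction honors each setting's disjointness contract", {
  sim <- simulate_interactions(synthetic_config(
    n_positives = 30, ratio = 2, pep_len = c(6L, 15L), pro_len = c(51L, 80L),
    n_families = 4L, n_proteins = 12L, seed = 13))
  tab <- sim$table
  sim_pep <- sw_similarity_matrix(tab$peptides)
  sim_pro <- sw_similarity_matrix(tab$proteins)

  # random: partitions the pair set, deterministic under the seed
  p1 <- make_folds(tab, "random", k = 5, seed = 3)
  p2 <- make_folds(tab, "random", k = 5, seed = 3)
  expect_identical(p1$folds, p2$folds)
  all_test <- sort(unlist(lapply(p1$folds, `[[`, "test")))
  expect_identical(all_test, seq_len(nrow(tab$pairs)))
  expect_true(leakage_check(p1, tab)$ok)

  for (setting in c("novel_protein", "novel_peptide")) {
    plan <- make_folds(tab, setting, t = 0.5, k = 3, seed = 3,
                       sim_pep = sim_pep, sim_pro = sim_pro)
    expect_length(plan$folds, 3)
    lk <- leakage_check(plan, tab)
    expect_true(lk$ok)
    expect_identical(nrow(lk$violations), 0L)
    # defining property, checked directly as well
    clusters <- if (setting == "novel_protein") plan$pro_clusters else plan$pep_clusters
    col <- if (setting == "novel_protein") "protein_id" else "peptide_id"
    for (f in plan$folds) {
      expect_length(intersect(unique(clusters[tab$pairs[[col]][f$train]]),
                              unique(clusters[tab$pairs[[col]][f$test]])), 0)
    }
    # exhaustive: test blocks partition the pairs
    expect_identical(sort(unlist(lapply(plan$folds, `[[`, "test"))),
                     seq_len(nrow(tab$pairs)))
  }

  # novel_pair: 3 x 3 grid -> exactly 9 folds, doubly disjoint
  plan <- make_folds(tab, "novel_pair", t = 0.5, seed = 3,
                     sim_pep = sim_pep, sim_pro = sim_pro)
  expect_length(plan$folds, 9)
  expect_identical(plan$k, 9L)
  expect_true(leakage_check(plan, tab)$ok)

  # a planted violation is caught and named
  bad <- plan
  # move one training pair's index into a test block sharing its protein cluster
  f1 <- bad$folds[[1]]
  victim_cluster <- bad$pro_clusters[tab$pairs$protein_id[f1$test[1]]]
  intruder <- which(bad$pro_clusters[tab$pairs$protein_id] == victim_cluster)
  intruder <- setdiff(intruder, f1$train)[1]
  bad$folds[[1]]$train <- c(f1$train, intruder)
  lk <- leakage_check(bad, tab)
  expect_false(lk$ok)
  expect_true(tab$pairs$protein_id[f1$test[1]] %in% lk$violations$entity_id)
})

test_that("negative sampling hits the exact ratio without collisions or duplicates", {
  sim <- tiny_dataset(seed = 17, n_pos = 10)
  pos <- subset_pairs(sim$table, which(sim$table$pairs$label == 1))

  out <- sample_negatives(pos, ratio = 3, seed = 5)
  expect_identical(nrow(out$pairs), 4L * 10L)
  expect_identical(sum(out$pairs$label == 0), 30L)
  key <- paste(out$pairs$peptide_id, out$pairs$protein_id)
  expect_false(anyDuplicated(key) > 0)
  pos_key <- paste(pos$pairs$peptide_id, pos$pairs$protein_id)
  neg_key <- key[out$pairs$label == 0]
  expect_length(intersect(neg_key, pos_key), 0)

  # ratio 0 leaves the table unchanged
  expect_identical(sample_negatives(pos, ratio = 0)$pairs, pos$pairs)

  # determinism
  out2 <- sample_negatives(pos, ratio = 3, seed = 5)
  expect_identical(out$pairs, out2$pairs)

  # tiny exhaustive case: 3 peptides x 3 proteins, 2 positives, ratio 2
  tp <- pair_table(data.frame(peptide_id = c("a", "b"),
                              protein_id = c("X", "Y"),
                              label = 1L))
  res <- sample_negatives(tp, ratio = 2, seed = 1,
                          peptide_ids = c("a", "b", "c"),
                          protein_ids = c("X", "Y", "Z"))
  negs <- res$pairs[res$pairs$label == 0, ]
  expect_identical(nrow(negs), 4L)
  universe <- candidate_pairs(c("a", "b", "c"), c("X", "Y", "Z"),
                              exclude = tp$pairs)
  expect_identical(nrow(universe), 7L)
  expect_true(all(paste(negs$peptide_id, negs$protein_id) %in%
                    paste(universe$peptide_id, universe$protein_id)))

  # impossible request errors out
  expect_error(sample_negatives(tp, ratio = 5, seed = 1,
                                peptide_ids = c("a", "b"),
                                protein_ids = c("X", "Y")),
               "not enough non-positive combinations")
})

test_that("candidate pairing is the exhaustive cross-product", {
  cp <- candidate_pairs(paste0("p", 1:4), paste0("q", 1:6))
  expect_identical(nrow(cp), 24L)
  expect_identical(anyDuplicated(paste(cp$peptide_id, cp$protein_id)), 0L)
  cp2 <- candidate_pairs(paste0("p", 1:4), paste0("q", 1:6),
                         exclude = data.frame(peptide_id = "p1", protein_id = "q1"))
  expect_identical(nrow(cp2), 23L)
})
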