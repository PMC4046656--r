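test_that("cluster labels follow side, exclusivity and significance", {
  # worked rows from a published two-tissue expression table (RPKMx1000)
  expect_equal(assign_cluster(TRUE, 20742.30, 1196.08), "A1")
  expect_equal(assign_cluster(TRUE, 9684.90, 0.00), "A2")
  expect_equal(assign_cluster(TRUE, 466.67, 39974.19), "B1")
  expect_equal(assign_cluster(TRUE, 0.00, 1349.85), "B2")
  expect_equal(assign_cluster(FALSE, 5, 500), "NS")
  expect_error(assign_cluster(TRUE, 3.3, 3.3), "identical")

  # explicit counts override the RPKM zero-proxy
  expect_equal(assign_cluster(TRUE, 10, 0.2, count1 = 50L, count2 = 1L), "A1")
  expect_equal(assign_cluster(TRUE, 10, 0, count1 = 50L, count2 = 0L), "A2")
})

test_that("vectorized labeling agrees with per-gene labels on simulated data", {
  sim <- simulate_dataset(sim_config(n_genes = 60, seed = 12))
  res <- sim_to_de(sim)
  labels <- assign_clusters(res$de, res$expr)
  expect_named(labels, res$de$unigene_id)
  for (i in seq_len(nrow(res$de))) {
    e <- res$expr[match(res$de$unigene_id[i], res$expr$unigene_id), ]
    expect_identical(
      as.character(labels[i]),
      assign_cluster(res$de$significant[i], e$rpkm_fruit, e$rpkm_az,
                     e$count_fruit, e$count_az))
  }
  # label partition: sides sum to the significant count, A2 really exclusive
  ps <- partition_summary(labels)
  expect_equal(ps$n_significant, sum(res$de$significant))
  a2 <- names(labels)[labels == "A2"]
  expect_true(all(res$expr$count_az[match(a2, res$expr$unigene_id)] == 0))
})

test_that("partition summary tallies labels and the Venn triple", {
  lab <- c(rep("A1", 2), rep("A2", 3), "B1", rep("B2", 4), rep("NS", 5))
  ps <- partition_summary(sample(lab))
  expect_equal(unname(ps$counts[c("A1", "A2", "B1", "B2", "NS")]),
               c(2L, 3L, 1L, 4L, 5L))
  expect_equal(ps$side1, 5L)
  expect_equal(ps$side2, 5L)
  expect_equal(ps$venn, list(only1 = 3L, only2 = 4L, common = 3L))

  ps0 <- partition_summary(rep("NS", 7))
  expect_equal(ps0$n_significant, 0L)
  expect_equal(unlist(ps0$venn), c(only1 = 0L, only2 = 0L, common = 0L))
  expect_error(partition_summary("Q9"), "unknown")

  set.seed(3)
  for (i in 1:20) {
    x <- sample(c("A1", "A2", "B1", "B2", "NS"), 50, replace = TRUE)
    ps <- partition_summary(x)
    expect_equal(unname(ps$counts["B2"]), sum(x == "B2"))
    expect_equal(ps$venn$common, sum(x %in% c("A1", "B1")))
  }
})

test_that("TF lexicon classifies descriptions by family keywords", {
  lex <- read_tf_lexicon()
  expect_equal(length(unique(lex$family)), 20L)
  got <- classify_tf(c("NAC domain protein, SlNAC1 = Solanum lycopersicum",
                       "Transcription factor hy5 = Ricinus communis",
                       "Floral homeotic protein AGAMOUS, TAG1",
                       "WRKY30 protein", "Beta-glucosidase"), lex)
  expect_equal(got, c("NAC", "bZIP", "MADS-box", "WRKY", NA))

  td <- withr::local_tempdir()
  p <- file.path(td, "lex.tsv")
  writeLines(c("pattern\tfamily\tpriority", "MYB\tMYB\t1", "NAC\tNAC\t1"), p)
  expect_error(read_tf_lexicon(p), "equal priority")
})

test_that("TF catalog covers exactly the DE genes with TF descriptions", {
  sim <- simulate_dataset(sim_config(n_genes = 120, tf_fraction = 0.3,
                                     de_fraction = 0.4, seed = 9))
  res <- sim_to_de(sim)
  labels <- assign_clusters(res$de, res$expr)
  tf <- build_tf_catalog(res$de, labels, sim$catalog)
  expect_true(all(tf$unigene_id %in% res$de$unigene_id[res$de$significant]))
  expect_true(all(tf$cluster %in% c("A1", "A2", "B1", "B2")))
  lex <- read_tf_lexicon()
  descr <- sim$catalog$description[match(tf$unigene_id,
                                         sim$catalog$protein_id)]
  expect_identical(tf$family, classify_tf(descr, lex))
  # no non-TF description sneaks in
  sig <- res$de$unigene_id[res$de$significant]
  non_tf <- setdiff(sig, tf$unigene_id)
  dn <- sim$catalog$description[match(non_tf, sim$catalog$protein_id)]
  expect_true(all(is.na(classify_tf(dn, lex))))
})
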