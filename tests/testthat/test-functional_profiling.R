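chain_bundle <- function() {
  edges <- data.frame(child = c("t", "a", "b"),
                      parent = c("a", "b", "root"),
                      relation = c("is_a", "part_of", "is_a"),
                      stringsAsFactors = FALSE)
  terms <- data.frame(term_id = c("t", "a", "b", "root", "island"),
                      name = c("t", "a", "b", "root", "island"),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  parents <- split(edges$parent, factor(edges$child, levels = terms$term_id))
  structure(list(terms = terms, edges = edges, slim = "b",
                 parents = parents),
            class = "ontology_bundle")
}

test_that("slim rollup walks ancestors-or-self and respects components", {
  b <- chain_bundle()
  expect_equal(rollup_to_slim("t", b), "b")        # chain t->a->b->root
  expect_equal(rollup_to_slim("b", b), "b")        # reflexive
  expect_equal(rollup_to_slim("island", b), character(0))  # disjoint
  expect_error(rollup_to_slim("nope", b), "unknown")

  # term itself in slim is always included
  b2 <- b; b2$slim <- c("t", "b")
  expect_setequal(rollup_to_slim("t", b2), c("t", "b"))
  # nearest-only keeps the closest slim level
  expect_equal(rollup_to_slim("t", b2, nearest_only = TRUE), "t")
  expect_equal(rollup_to_slim("a", b2, nearest_only = TRUE), "b")

  # enlarging the slim set never shrinks a rollup
  for (seed in 1:10) {
    d <- random_dag_bundle(40, seed, slim_size = 5)
    bigger <- d
    bigger$slim <- unique(c(d$slim,
                            sample(d$terms$term_id, 5)))
    for (t in sample(d$terms$term_id, 10))
      expect_true(all(rollup_to_slim(t, d) %in% rollup_to_slim(t, bigger)))
  }
})

test_that("rollup equals the transitive-closure oracle on random DAGs", {
  for (seed in 1:10) {
    b <- random_dag_bundle(50, seed)
    R <- closure_oracle(b)
    for (t in b$terms$term_id) {
      expect_setequal(rollup_to_slim(t, b),
                      intersect(colnames(R)[R[t, ]], b$slim))
    }
  }
})

test_that("term frequencies deduplicate per gene and match brute force", {
  b <- chain_bundle()
  ann <- list(g1 = c("t", "t"))   # duplicate annotation counts once
  tf <- term_frequencies("g1", ann, b)
  expect_equal(tf$count_set[tf$term_id == "t"], 1L)

  expect_equal(nrow(term_frequencies(character(), ann, b)), 0L)

  # two sets, slim mode: each gene counts once per slim term
  ann2 <- list(g1 = c("t", "a"), g2 = "b", g3 = "island")
  tf2 <- term_frequencies(list(A = c("g1", "g2"), B = "g3"), ann2, b,
                          use_slim = TRUE)
  expect_equal(tf2$count_A[tf2$term_id == "b"], 2L)
  expect_equal(sum(tf2$count_B), 0L)

  # random tables against a brute-force set tally
  for (seed in 1:10) {
    b3 <- random_dag_bundle(30, seed)
    genes <- sprintf("g%02d", 1:15)
    set.seed(seed + 100)
    ann3 <- lapply(stats::setNames(genes, genes), function(g)
      sample(b3$terms$term_id, sample(1:6, 1), replace = TRUE))
    setA <- sample(genes, 8); setB <- sample(genes, 5)
    got <- term_frequencies(list(A = setA, B = setB), ann3, b3)
    for (i in seq_len(nrow(got))) {
      t <- got$term_id[i]
      expect_equal(got$count_A[i],
                   sum(vapply(setA, function(g) t %in% ann3[[g]], logical(1))))
      expect_equal(got$count_B[i],
                   sum(vapply(setB, function(g) t %in% ann3[[g]], logical(1))))
    }
    # gene-order permutation changes nothing
    got2 <- term_frequencies(list(A = sample(setA), B = sample(setB)),
                             ann3, b3)
    expect_equal(got2, got)
    # adding an annotation never decreases a count
    ann4 <- ann3
    ann4[[setA[1]]] <- c(ann4[[setA[1]]], b3$terms$term_id[1])
    got3 <- term_frequencies(list(A = setA, B = setB), ann4, b3)
    m <- match(got$term_id, got3$term_id)
    expect_true(all(got3$count_A[m] >= got$count_A))
  }
})

test_that("EC pathway profile counts distinct enzymes per pathway", {
  cat <- data.frame(protein_id = c("P1", "P2", "P3"),
                    aa_length = 100L, description = "d",
                    stringsAsFactors = FALSE)
  cat$go_terms <- replicate(3, character(), simplify = FALSE)
  cat$ec_codes <- list("3.2.1.26", "2.4.1.13", character())
  map <- data.frame(ec = c("3.2.1.26", "2.4.1.13"),
                    pathway = "Starch and sucrose metabolism",
                    stringsAsFactors = FALSE)
  prof <- ec_pathway_profile(c("P1", "P2", "P3"), cat, map)
  expect_equal(prof$pathway, "Starch and sucrose metabolism")
  expect_equal(prof$n_enzymes, 2L)

  expect_equal(nrow(ec_pathway_profile(character(), cat, map)), 0L)
  badmap <- data.frame(ec = "x.y", pathway = "p", stringsAsFactors = FALSE)
  expect_error(ec_pathway_profile("P1", cat, badmap), "malformed EC")
  expect_error(ec_pathway_profile("P9", cat, map), "P9")

  # random maps against brute-force join-and-count
  set.seed(11)
  ecs <- c("1.1.1.1", "2.2.2.2", "3.3.3.3", "4.4.4.4", "5.5.5.5")
  for (rep in 1:10) {
    n <- 12
    cat2 <- data.frame(protein_id = sprintf("Q%02d", 1:n),
                       aa_length = 100L, description = "d",
                       stringsAsFactors = FALSE)
    cat2$go_terms <- replicate(n, character(), simplify = FALSE)
    cat2$ec_codes <- replicate(n, sample(ecs, sample(0:2, 1)),
                               simplify = FALSE)
    map2 <- data.frame(ec = sample(ecs, 8, replace = TRUE),
                       pathway = sample(c("pw1", "pw2", "pw3"), 8,
                                        replace = TRUE),
                       stringsAsFactors = FALSE)
    degs <- sample(cat2$protein_id, 6)
    prof2 <- ec_pathway_profile(degs, cat2, map2)
    dec <- unique(unlist(cat2$ec_codes[match(degs, cat2$protein_id)]))
    for (pw in unique(map2$pathway)) {
      want <- length(intersect(dec, unique(map2$ec[map2$pathway == pw])))
      got <- prof2$n_enzymes[prof2$pathway == pw]
      expect_equal(if (length(got)) got else 0L, want)
    }
    expect_false(is.unsorted(rev(prof2$n_enzymes)))
  }
})
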