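test_that("deduplicated counting counts shared contigs once", {
  a <- tiny_assembly()
  expect_equal(dedup_count(c("i1", "i2"), a, "s1"), 15)  # not 22
  expect_equal(dedup_count("i1", a, "s1"), 12)
  expect_equal(dedup_count("i2", a, "s2"), 9)
  a0 <- a
  a0$contigs$reads_s1 <- 0L
  expect_equal(dedup_count(c("i1", "i2"), a0, "s1"), 0)
  expect_error(dedup_count("i1", a, "nope"), "unknown sample")
  expect_error(dedup_count("iX", a, "s1"), "unknown isotig")
})

test_that("protein length and RPKM follow their closed forms", {
  expect_identical(protein_nt_length(1L), 3L)
  expect_identical(protein_nt_length(250L), 750L)
  expect_error(protein_nt_length(0), "positive")
  set.seed(4)
  aa <- sample(1:2000, 200)
  expect_identical(protein_nt_length(aa), as.integer(aa * 3))

  expect_equal(rpkm(0, 1e6, 1000), 0)
  expect_equal(rpkm(1000, 1e6, 1000), 1000)
  expect_equal(round(rpkm(100, 2e5, 750), 2), 666.67)
  expect_error(rpkm(10, 0, 100), "N")
  expect_error(rpkm(10, 100, 0), "L")
  expect_error(rpkm(-1, 100, 100), "non-negative")

  # invariant under joint scaling; monotone in C, antitone in L
  C <- 57; N <- 12345; L <- 321
  expect_equal(rpkm(3 * C, 3 * N, L), rpkm(C, N, L))
  expect_true(rpkm(C + 1, N, L) > rpkm(C, N, L))
  expect_true(rpkm(C, N, L + 1) < rpkm(C, N, L))
})

test_that("expression table equals brute-force recomputation from raw tables", {
  ra <- random_assembly(21)
  a <- ra$assembly
  # one unigene per gene, members from the generator's gene map
  genes <- split(names(ra$gene_of_isotig), ra$gene_of_isotig)
  cat <- data.frame(protein_id = names(genes),
                    aa_length = sample(100:500, length(genes)),
                    description = "d", stringsAsFactors = FALSE)
  cat$go_terms <- replicate(length(genes), character(), simplify = FALSE)
  cat$ec_codes <- replicate(length(genes), character(), simplify = FALSE)
  cl <- structure(genes, class = "unigene_clusters")
  expr <- build_expression_table(cl, a, cat)

  N1 <- sum(a$contigs$reads_s1); N2 <- sum(a$contigs$reads_s2)
  expect_equal(unname(attr(expr, "library_sizes")), c(N1, N2))
  for (i in seq_len(nrow(expr))) {
    u <- expr$unigene_id[i]
    ctg <- unique(unlist(a$isotigs[genes[[u]]], use.names = FALSE))
    rows <- match(ctg, a$contigs$contig_id)
    expect_equal(expr$count_s1[i], sum(a$contigs$reads_s1[rows]))
    expect_equal(expr$count_s2[i], sum(a$contigs$reads_s2[rows]))
    L <- 3L * cat$aa_length[match(u, cat$protein_id)]
    expect_equal(expr$L_nt[i], L)
    expect_equal(expr$rpkm_s1[i], 1e9 * expr$count_s1[i] / (N1 * L))
  }
  # every contig is annotated here, so counts conserve the library exactly
  expect_equal(sum(expr$count_s1), N1)
  expect_equal(sum(expr$count_s2), N2)

  # doubling every count doubles N and C and leaves RPKM unchanged
  a2 <- a
  a2$contigs$reads_s1 <- 2L * a2$contigs$reads_s1
  a2$contigs$reads_s2 <- 2L * a2$contigs$reads_s2
  expr2 <- build_expression_table(cl, a2, cat)
  expect_equal(expr2$rpkm_s1, expr$rpkm_s1)
  expect_equal(expr2$rpkm_s2, expr$rpkm_s2)

  # dropping a unigene leaves its reads outside: sum(C) < N
  cl3 <- structure(genes[-1], class = "unigene_clusters")
  expr3 <- build_expression_table(cl3, a, cat)
  expect_lt(sum(expr3$count_s1), N1)

  # single unigene owning all isotigs absorbs the whole library
  cl1 <- structure(list(g = names(a$isotigs)), class = "unigene_clusters")
  cat1 <- data.frame(protein_id = "g", aa_length = 100L, description = "d",
                     stringsAsFactors = FALSE)
  cat1$go_terms <- list(character()); cat1$ec_codes <- list(character())
  expr1 <- build_expression_table(cl1, a, cat1)
  expect_equal(expr1$count_s1, N1)

  expect_warning(
    e0 <- build_expression_table(structure(stats::setNames(list(), character()),
                                           class = "unigene_clusters"),
                                 a, cat),
    "empty")
  expect_equal(nrow(e0), 0L)
})

test_that("expression tables are written on the x1000 reporting scale", {
  td <- withr::local_tempdir()
  expr <- make_expr("u1", 100L, 0L, 2e5, 1e5, 750L)
  write_expression_table(expr, file.path(td, "e.tsv"))
  lines <- readLines(file.path(td, "e.tsv"))
  expect_match(lines[1], "rpkm1000_s1")
  # rpkm = 1e9*100/(2e5*750) = 666.666..; x1000, 2 dp
  expect_match(lines[2], "666666\\.67")
  expect_match(lines[2], "\t0\\.00")
})
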