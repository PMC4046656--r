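# Fixtures are built in code; nothing here touches the network or ships data.

# hand-assembled assembly_dataset (bypasses the readers)
make_assembly <- function(contigs, isotigs, samples) {
  structure(list(contigs = contigs, isotigs = isotigs, sample_ids = samples),
            class = "assembly_dataset")
}

tiny_assembly <- function() {
  make_assembly(
    data.frame(contig_id = c("c1", "c2", "c3"),
               length_nt = c(300L, 400L, 500L),
               reads_s1 = c(5L, 7L, 3L),
               reads_s2 = c(2L, 0L, 9L),
               stringsAsFactors = FALSE),
    list(i1 = c("c1", "c2"), i2 = c("c2", "c3")),
    c("s1", "s2"))
}

# hand-assembled expression_table
make_expr <- function(ids, y1, y2, N1, N2, L,
                      samples = c("s1", "s2")) {
  out <- data.frame(unigene_id = ids, L_nt = L, stringsAsFactors = FALSE)
  out[[paste0("count_", samples[1L])]] <- as.integer(y1)
  out[[paste0("rpkm_", samples[1L])]] <- rpkm(y1, N1, L)
  out[[paste0("count_", samples[2L])]] <- as.integer(y2)
  out[[paste0("rpkm_", samples[2L])]] <- rpkm(y2, N2, L)
  attr(out, "library_sizes") <- stats::setNames(c(N1, N2), samples)
  class(out) <- c("expression_table", "data.frame")
  out
}

write_tiny_assembly_files <- function(dir) {
  writeLines(c("contig_id\tlength_nt\treads_s1\treads_s2",
               "c1\t300\t5\t2", "c2\t400\t7\t0", "c3\t500\t3\t9"),
             file.path(dir, "contigs.tsv"))
  writeLines(c("isotig_id\tcontigs", "i1\tc1,c2", "i2\tc2,c3"),
             file.path(dir, "isotigs.tsv"))
  dir
}

# random assembly structure with shared contigs, plus the gene map
random_assembly <- function(seed, n_genes = 8) {
  set.seed(seed)
  contigs <- character(); lengths <- integer()
  isotigs <- list(); gene_of_isotig <- character()
  cc <- 0L
  for (g in seq_len(n_genes)) {
    pool <- character()
    for (j in seq_len(sample(1:3, 1))) {
      members <- character()
      for (s in seq_len(sample(1:4, 1))) {
        if (length(pool) && runif(1) < 0.4) {
          cand <- setdiff(pool, members)
          if (length(cand)) {
            members <- c(members, sample(cand, 1))
            next
          }
        }
        cc <- cc + 1L
        id <- sprintf("c%03d", cc)
        contigs <- c(contigs, id)
        lengths <- c(lengths, sample(100:900, 1))
        pool <- c(pool, id)
        members <- c(members, id)
      }
      iso <- sprintf("i%03d", length(isotigs) + 1L)
      isotigs[[iso]] <- members
      gene_of_isotig <- c(gene_of_isotig, sprintf("g%02d", g))
    }
  }
  df <- data.frame(contig_id = contigs, length_nt = lengths,
                   reads_s1 = rpois(length(contigs), 40),
                   reads_s2 = rpois(length(contigs), 40),
                   stringsAsFactors = FALSE)
  list(assembly = make_assembly(df, isotigs, c("s1", "s2")),
       gene_of_isotig = stats::setNames(gene_of_isotig, names(isotigs)))
}

random_hits <- function(n, seed) {
  set.seed(seed)
  data.frame(
    qseqid = sprintf("i%03d", sample(1:40, n, replace = TRUE)),
    sseqid = sprintf("P%02d", sample(1:15, n, replace = TRUE)),
    pident = round(runif(n, 60, 100), 2),
    length = sample(50:500, n, replace = TRUE),
    mismatch = sample(0:40, n, replace = TRUE),
    gapopen = sample(0:5, n, replace = TRUE),
    qstart = sample(1:100, n, replace = TRUE),
    qend = sample(200:900, n, replace = TRUE),
    sstart = sample(1:50, n, replace = TRUE),
    send = sample(100:400, n, replace = TRUE),
    evalue = 10^runif(n, -150, -1),
    bitscore = round(runif(n, 40, 400), 1),
    stringsAsFactors = FALSE)
}

# random DAG on n terms: edges only from lower to higher index, so acyclic
random_dag_bundle <- function(n_terms, seed, slim_size = max(1L, n_terms %/% 5L)) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  child <- character(); parent <- character()
  for (i in seq_len(n_terms - 1L)) {
    np <- sample(0:2, 1, prob = c(0.2, 0.5, 0.3))
    if (np > 0) {
      ps <- sample((i + 1L):n_terms, min(np, n_terms - i))
      child <- c(child, rep(ids[i], length(ps)))
      parent <- c(parent, ids[ps])
    }
  }
  edges <- data.frame(child = child, parent = parent,
                      relation = sample(c("is_a", "part_of"),
                                        length(child), replace = TRUE),
                      stringsAsFactors = FALSE)
  terms <- data.frame(term_id = ids, name = ids,
                      namespace = sample(c("biological_process",
                                           "molecular_function"),
                                         n_terms, replace = TRUE),
                      stringsAsFactors = FALSE)
  slim <- sample(ids, slim_size)
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  structure(list(terms = terms, edges = edges, slim = slim,
                 parents = parents),
            class = "ontology_bundle")
}

# independent reachability oracle: boolean transitive closure by iterated
# matrix multiplication over the child->parent adjacency matrix
closure_oracle <- function(bundle) {
  ids <- bundle$terms$term_id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(bundle$edges))
    A[cbind(bundle$edges$child, bundle$edges$parent)] <- TRUE
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# minimum-likelihood binomial exact test, by full enumeration
binom_minlik <- function(y1, n, q) {
  pr <- stats::dbinom(0:n, n, q)
  min(1, sum(pr[pr <= pr[y1 + 1] * (1 + 1e-10)]))
}

# run annotation->quantification->testing on a simulated dataset
sim_to_de <- function(sim, params = de_params(phi = sim$config$phi)) {
  cl <- cluster_unigenes(assign_best_hit(filter_hits(sim$hits)), sim$catalog)
  expr <- build_expression_table(cl, sim$assembly, sim$catalog)
  list(expr = expr, de = run_de(expr, params))
}
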