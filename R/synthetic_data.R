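# Seeded generator for complete two-sample, no-replicate datasets with the
# statistical structure the downstream analysis assumes, plus a truth
# manifest so accuracy can be scored without any external data.
#
# The emulated design is a two-tissue 454-style experiment (one library per
# tissue): genes with 1-3 isoform isotigs that may share contigs, gene-level
# counts drawn from NB(M_i * p_gi, phi) and split multinomially across the
# gene's contigs in proportion to contig length, one sub-threshold annotation
# hit per isotig plus decoy hits above the E-value threshold, and a small GO
# ontology / EC / TF-family catalog drawn from built-in vocabularies.
#
# Reproducibility discipline: every gene draws from its own seeded substream
# (derived from the master seed and the gene index), in a documented order,
# so enlarging n_genes never reshuffles the draws of earlier genes.

#' Configuration of the synthetic two-sample experiment
#'
#' Defaults describe the emulated study conditions: a two-tissue (fruit
#' pericarp vs abscission zone) experiment with one library per tissue,
#' a few hundred reference genes, moderate overdispersion, a 20% DE fraction
#' with 2-fold (log2) effects, and a quarter of the DE genes expressed in
#' only one tissue.
#'
#' @param n_genes Number of genes / reference proteins (>= 1).
#' @param isoforms_per_gene Inclusive integer range (length 2) of isotigs per
#'   gene.
#' @param contigs_per_isotig Inclusive integer range of contigs per isotig.
#' @param shared_contig_prob Probability that a contig slot of a later
#'   isoform reuses one of the gene's existing contigs instead of creating a
#'   new one.
#' @param library_sizes Named positive vector, one entry per sample (the NB
#'   mean for gene g in sample i is `library_sizes[i] * p_gi`).
#' @param phi NB dispersion (variance = mu + phi mu^2); 0 gives Poisson
#'   counts.
#' @param de_fraction Fraction of genes that are truly DE.
#' @param logfc_effect Absolute base-2 log fold change applied symmetrically
#'   (half the DE genes up in each tissue).
#' @param exclusive_fraction Fraction of DE genes with zero true abundance in
#'   one tissue.
#' @param decoy_hit_rate Probability that an isotig also carries a decoy hit
#'   (to a wrong protein, with an E-value above the annotation threshold).
#' @param evalue_true,evalue_decoy Length-2 ranges (low, high) from which
#'   true / decoy hit E-values are drawn log-uniformly. True hits must stay
#'   strictly below, decoys at or above, the annotation threshold of 1e-20.
#' @param tf_fraction Fraction of proteins given a TF-family description.
#' @param ec_fraction Fraction of proteins annotated with an EC code.
#' @param cross_gene_sharing If `TRUE`, an isotig may additionally absorb a
#'   contig of a previously generated gene (off by default, so unigene
#'   counts have a clean truth value).
#' @param seed Master seed (integer).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       isoforms_per_gene = c(1L, 3L),
                       contigs_per_isotig = c(1L, 4L),
                       shared_contig_prob = 0.3,
                       library_sizes = c(fruit = 1e5, az = 1e5),
                       phi = 0.1,
                       de_fraction = 0.2,
                       logfc_effect = 2,
                       exclusive_fraction = 0.25,
                       decoy_hit_rate = 0.1,
                       evalue_true = c(1e-180, 1e-25),
                       evalue_decoy = c(1e-18, 1e-3),
                       tf_fraction = 0.1,
                       ec_fraction = 0.3,
                       cross_gene_sharing = FALSE,
                       seed = 1L) {
  stopifnot(length(n_genes) == 1L, n_genes >= 1, n_genes == floor(n_genes),
            length(isoforms_per_gene) == 2L,
            isoforms_per_gene[1L] >= 1, diff(isoforms_per_gene) >= 0,
            length(contigs_per_isotig) == 2L,
            contigs_per_isotig[1L] >= 1, diff(contigs_per_isotig) >= 0,
            shared_contig_prob >= 0, shared_contig_prob <= 1,
            length(library_sizes) == 2L, all(library_sizes >= 1),
            !is.null(names(library_sizes)), all(nzchar(names(library_sizes))),
            phi >= 0,
            de_fraction >= 0, de_fraction <= 1,
            exclusive_fraction >= 0, exclusive_fraction <= 1,
            decoy_hit_rate >= 0, decoy_hit_rate <= 1,
            length(evalue_true) == 2L, evalue_true[1L] <= evalue_true[2L],
            evalue_true[2L] < 1e-20,
            length(evalue_decoy) == 2L, evalue_decoy[1L] >= 1e-20,
            tf_fraction >= 0, tf_fraction <= 1,
            ec_fraction >= 0, ec_fraction <= 1,
            length(seed) == 1L, seed == floor(seed))
  structure(list(n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 contigs_per_isotig = as.integer(contigs_per_isotig),
                 shared_contig_prob = shared_contig_prob,
                 library_sizes = library_sizes,
                 phi = phi, de_fraction = de_fraction,
                 logfc_effect = logfc_effect,
                 exclusive_fraction = exclusive_fraction,
                 decoy_hit_rate = decoy_hit_rate,
                 evalue_true = evalue_true, evalue_decoy = evalue_decoy,
                 tf_fraction = tf_fraction, ec_fraction = ec_fraction,
                 cross_gene_sharing = cross_gene_sharing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d genes, %d-%d isoforms/gene, phi = %g, %g%% DE (|logFC| = %g, %g%% exclusive), seed %d\n",
    x$n_genes, x$isoforms_per_gene[1L], x$isoforms_per_gene[2L], x$phi,
    100 * x$de_fraction, x$logfc_effect, 100 * x$exclusive_fraction, x$seed))
  cat("  libraries:", paste(names(x$library_sizes),
                            format(x$library_sizes, big.mark = ","),
                            collapse = ", "), "\n")
  invisible(x)
}

# per-gene substream seed; phase 0 = structure/abundance/uniform/hit draws,
# phase 1 = multinomial contig split (done after global normalization)
#' @noRd
.gene_seed <- function(seed, g, phase) {
  (((abs(seed) %% 1000003L) * 1009L + 2L * g + phase) %% 2147483629L) + 1L
}

# small three-namespace GO-like DAG with a mid-level slim set
#' @noRd
.sim_ontology <- function(seed) {
  set.seed(.gene_seed(seed, 0L, 0L))
  ns <- c("biological_process", "molecular_function", "cellular_component")
  terms <- list(); edges <- list(); slim <- character()
  counter <- 0L
  nid <- function() {
    counter <<- counter + 1L
    sprintf("GO:%07d", counter)
  }
  leaves <- character()
  for (j in seq_along(ns)) {
    root <- nid()
    terms[[length(terms) + 1L]] <- c(root, paste0(ns[j], " root"), ns[j])
    for (m in 1:4) {
      mid <- nid()
      terms[[length(terms) + 1L]] <- c(mid, sprintf("%s slim term %d", ns[j], m), ns[j])
      edges[[length(edges) + 1L]] <- c(mid, root, "is_a")
      slim <- c(slim, mid)
      for (l in 1:4) {
        leaf <- nid()
        terms[[length(terms) + 1L]] <-
          c(leaf, sprintf("%s leaf %d.%d", ns[j], m, l), ns[j])
        rel <- if (stats::runif(1) < 0.25) "part_of" else "is_a"
        edges[[length(edges) + 1L]] <- c(leaf, mid, rel)
        # occasional second parent to make it a genuine DAG
        if (m > 1 && stats::runif(1) < 0.3)
          edges[[length(edges) + 1L]] <- c(leaf, slim[length(slim) - 1L], "is_a")
        leaves <- c(leaves, leaf)
      }
    }
  }
  tdf <- as.data.frame(do.call(rbind, terms), stringsAsFactors = FALSE)
  names(tdf) <- c("term_id", "name", "namespace")
  edf <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  names(edf) <- c("child", "parent", "relation")
  parents <- split(edf$parent, factor(edf$child, levels = tdf$term_id))
  structure(list(terms = tdf, edges = edf, slim = slim, parents = parents,
                 leaves = leaves),
            class = "ontology_bundle")
}

.SIM_DESCRIPTIONS <- c(
  "Uncharacterized protein", "Beta-glucosidase", "Pectinesterase",
  "Chalcone synthase", "Serine-threonine protein kinase",
  "Polygalacturonase", "ACC oxidase", "Thaumatin-like protein",
  "Alpha-expansin", "Cellulose synthase", "Anthocyanidin synthase",
  "Beta-1,3-glucanase", "Sucrose synthase", "Beta-fructofuranosidase",
  "Glutamine synthetase", "Purple acid phosphatase",
  "Lipoxygenase", "Phenylalanine ammonia-lyase", "Catalase",
  "Aquaporin PIP2", "Xyloglucan endotransglucosylase",
  "Abscisic stress ripening-like protein")

.SIM_TF_DESCRIPTIONS <- c(
  "MADS-box protein AGL9", "WRKY transcription factor 30",
  "NAC domain protein", "AP2/ERF domain protein",
  "Heat shock factor protein", "GRAS family protein",
  "Aux/IAA protein IAA1", "CAMTA calmodulin-binding transcription activator",
  "GAGA-binding protein BBR", "EIN3-like protein EIL1",
  "E2F transcription factor", "CCAAT-binding factor subunit",
  "C2H2 zinc finger protein", "bZIP transcription factor",
  "bHLH transcription factor", "MYB transcription factor",
  "Homeobox protein HB-7", "SBP-box protein",
  "TCP transcription factor", "Zinc finger protein")

.SIM_ECS <- c("3.2.1.26", "2.4.1.13", "3.2.1.39", "2.4.1.1", "2.7.7.9",
              "5.3.1.9", "3.2.1.2", "4.1.1.35", "3.2.1.4", "2.7.1.4",
              "3.2.1.15", "2.6.1.1", "2.5.1.6", "3.3.1.1", "1.1.1.27",
              "4.1.1.50", "3.2.1.14", "5.4.2.8", "4.2.1.11", "2.7.1.40")

#' Simulate a complete two-sample dataset with known truth
#'
#' Draws assembly structure, per-contig counts, annotation hits, a protein
#' catalog and a small ontology under one master seed, together with a truth
#' manifest recording each gene's relative abundances, realized true log fold
#' change, and DE/exclusivity status. See [sim_config()] for the generative
#' model.
#'
#' Within a sample, gene relative abundances `p_gj` are log-normal weights
#' normalized to sum to one; the manifest's `true_logFC` is the realized
#' `log2(p_g1 / p_g2)` after that normalization (`+/-Inf` for exclusive
#' genes, exactly 0 for null genes).
#'
#' @param config A [sim_config()] object.
#' @return Object of class `sim_dataset`: list with `assembly`, `hits`,
#'   `catalog`, `ontology`, `truth` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_genes
  samples <- names(cfg$library_sizes)
  M <- cfg$library_sizes

  ontology <- .sim_ontology(cfg$seed)

  n_de <- round(cfg$de_fraction * n)
  n_exc <- round(cfg$exclusive_fraction * n_de)
  is_de <- seq_len(n) <= n_de
  is_exc <- seq_len(n) <= n_exc
  up_in_1 <- (seq_len(n) %% 2L) == 1L   # alternate the favored tissue

  genes <- vector("list", n)
  contig_counter <- 0L
  iso_counter <- 0L
  all_contig_ids <- character()

  for (g in seq_len(n)) {
    set.seed(.gene_seed(cfg$seed, g, 0L))
    # 1. structure
    n_iso <- sample(cfg$isoforms_per_gene[1L]:cfg$isoforms_per_gene[2L], 1L)
    gene_contigs <- character(); gene_lengths <- integer()
    isotigs <- vector("list", n_iso)
    for (j in seq_len(n_iso)) {
      k <- sample(cfg$contigs_per_isotig[1L]:cfg$contigs_per_isotig[2L], 1L)
      members <- character()
      for (slot in seq_len(k)) {
        reuse <- j > 1L && length(gene_contigs) > 0L &&
          stats::runif(1) < cfg$shared_contig_prob
        if (reuse) {
          cand <- setdiff(gene_contigs, members)
          if (length(cand)) {
            members <- c(members, cand[sample.int(length(cand), 1L)])
            next
          }
        }
        contig_counter <- contig_counter + 1L
        cid <- sprintf("CTG%06d", contig_counter)
        len <- max(100L, as.integer(round(stats::rlnorm(1, log(500), 0.5))))
        gene_contigs <- c(gene_contigs, cid)
        gene_lengths <- c(gene_lengths, len)
        members <- c(members, cid)
      }
      if (cfg$cross_gene_sharing && length(all_contig_ids) &&
          stats::runif(1) < cfg$shared_contig_prob / 2) {
        extra <- all_contig_ids[sample.int(length(all_contig_ids), 1L)]
        if (!extra %in% members) members <- c(members, extra)
      }
      iso_counter <- iso_counter + 1L
      isotigs[[j]] <- members
      names(isotigs)[j] <- sprintf("ISO%05d", iso_counter)
    }
    all_contig_ids <- c(all_contig_ids, gene_contigs)
    # 2. abundance weight
    w <- stats::rlnorm(1, 0, 1)
    # 3. count uniforms (one per sample)
    u <- stats::runif(length(samples))
    # 4. catalog attributes
    aa <- sample(100:800, 1L)
    is_tf <- stats::runif(1) < cfg$tf_fraction
    descr <- if (is_tf) {
      sample(.SIM_TF_DESCRIPTIONS, 1L)
    } else {
      sample(.SIM_DESCRIPTIONS, 1L)
    }
    gos <- sample(ontology$leaves, sample(2:5, 1L))
    ecs <- if (stats::runif(1) < cfg$ec_fraction) sample(.SIM_ECS, 1L)
           else character()
    # 5. hit randomness (true hit per isotig + optional decoy)
    hit_ev <- 10^stats::runif(n_iso, log10(cfg$evalue_true[1L]),
                              log10(cfg$evalue_true[2L]))
    hit_pid <- round(stats::runif(n_iso, 85, 99.5), 1)
    decoy <- stats::runif(n_iso) < cfg$decoy_hit_rate
    decoy_ev <- 10^stats::runif(n_iso, log10(cfg$evalue_decoy[1L]),
                                log10(cfg$evalue_decoy[2L]))
    decoy_target <- sample.int(n, n_iso, replace = TRUE)

    genes[[g]] <- list(contigs = gene_contigs, lengths = gene_lengths,
                       isotigs = isotigs, w = w, u = u, aa = aa,
                       descr = descr, gos = gos, ecs = ecs,
                       hit_ev = hit_ev, hit_pid = hit_pid,
                       decoy = decoy, decoy_ev = decoy_ev,
                       decoy_target = decoy_target)
  }

  # --- relative abundances (normalized per sample) and gene-level counts
  w1 <- vapply(genes, `[[`, numeric(1L), "w")
  w2 <- w1
  half <- cfg$logfc_effect / 2
  w1[is_de & up_in_1]  <- w1[is_de & up_in_1] * 2^half
  w2[is_de & up_in_1]  <- w2[is_de & up_in_1] * 2^-half
  w1[is_de & !up_in_1] <- w1[is_de & !up_in_1] * 2^-half
  w2[is_de & !up_in_1] <- w2[is_de & !up_in_1] * 2^half
  w1[is_exc & !up_in_1] <- 0
  w2[is_exc & up_in_1]  <- 0
  p1 <- w1 / sum(w1); p2 <- w2 / sum(w2)
  U <- do.call(rbind, lapply(genes, `[[`, "u"))
  qcount <- function(u, mu) {
    if (cfg$phi == 0) stats::qpois(u, mu)
    else stats::qnbinom(u, size = 1 / cfg$phi, mu = mu)
  }
  Y1 <- qcount(U[, 1L], M[[1L]] * p1)
  Y2 <- qcount(U[, 2L], M[[2L]] * p2)
  Y1[p1 == 0] <- 0L; Y2[p2 == 0] <- 0L

  # --- split gene counts over contigs (phase-1 substream)
  contig_rows <- vector("list", n)
  for (g in seq_len(n)) {
    set.seed(.gene_seed(cfg$seed, g, 1L))
    ge <- genes[[g]]
    k <- length(ge$contigs)
    split1 <- if (k == 1L) Y1[g] else
      drop(stats::rmultinom(1L, Y1[g], ge$lengths))
    split2 <- if (k == 1L) Y2[g] else
      drop(stats::rmultinom(1L, Y2[g], ge$lengths))
    df <- data.frame(contig_id = ge$contigs, length_nt = ge$lengths,
                     stringsAsFactors = FALSE)
    df[[paste0("reads_", samples[1L])]] <- as.integer(split1)
    df[[paste0("reads_", samples[2L])]] <- as.integer(split2)
    contig_rows[[g]] <- df
  }
  contigs <- do.call(rbind, contig_rows)
  row.names(contigs) <- NULL
  isotig_list <- do.call(c, lapply(genes, `[[`, "isotigs"))
  assembly <- structure(list(contigs = contigs, isotigs = isotig_list,
                             sample_ids = samples),
                        class = "assembly_dataset")

  # --- protein catalog
  prot_ids <- sprintf("P%05d", seq_len(n))
  catalog <- data.frame(protein_id = prot_ids,
                        aa_length = vapply(genes, `[[`, integer(1L), "aa"),
                        description = vapply(genes, `[[`, character(1L), "descr"),
                        stringsAsFactors = FALSE)
  catalog$go_terms <- lapply(genes, `[[`, "gos")
  catalog$ec_codes <- lapply(genes, `[[`, "ecs")

  # --- annotation hits (true + decoy)
  hit_rows <- vector("list", n)
  for (g in seq_len(n)) {
    ge <- genes[[g]]
    iso_ids <- names(ge$isotigs)
    n_iso <- length(iso_ids)
    alen <- as.integer(round(ge$aa * 0.8))
    true_hits <- data.frame(
      qseqid = iso_ids, sseqid = prot_ids[g],
      pident = ge$hit_pid, length = alen,
      mismatch = as.integer(round(alen * (1 - ge$hit_pid / 100))),
      gapopen = 0L, qstart = 1L, qend = alen * 3L, sstart = 1L, send = alen,
      evalue = ge$hit_ev,
      bitscore = round(60 - 1.8 * log10(ge$hit_ev), 1),
      stringsAsFactors = FALSE)
    dk <- which(ge$decoy)
    decoy_hits <- if (length(dk)) data.frame(
      qseqid = iso_ids[dk], sseqid = prot_ids[ge$decoy_target[dk]],
      pident = round(ge$hit_pid[dk] * 0.6, 1), length = 60L,
      mismatch = 20L, gapopen = 2L, qstart = 1L, qend = 180L,
      sstart = 1L, send = 60L,
      evalue = ge$decoy_ev[dk],
      bitscore = round(60 - 1.8 * log10(ge$decoy_ev[dk]), 1),
      stringsAsFactors = FALSE) else NULL
    hit_rows[[g]] <- rbind(true_hits, decoy_hits)
  }
  hits <- do.call(rbind, hit_rows)
  row.names(hits) <- NULL

  # --- truth manifest
  truth <- data.frame(
    unigene_id = prot_ids,
    stringsAsFactors = FALSE)
  truth[[paste0("p_", samples[1L])]] <- p1
  truth[[paste0("p_", samples[2L])]] <- p2
  truth$true_logFC <- ifelse(is_de,
                             log2(p1 / p2),
                             0)
  truth$is_de <- is_de
  truth$is_exclusive <- is_exc
  truth[[paste0("y_", samples[1L])]] <- as.integer(Y1)
  truth[[paste0("y_", samples[2L])]] <- as.integer(Y2)
  truth$isotigs <- vapply(genes, function(ge)
    paste(names(ge$isotigs), collapse = ","), character(1L))
  truth$contigs <- vapply(genes, function(ge)
    paste(ge$contigs, collapse = ","), character(1L))

  structure(list(assembly = assembly, hits = hits, catalog = catalog,
                 ontology = ontology, truth = truth, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic dataset (seed ", x$config$seed, "):\n", sep = "")
  print(x$assembly)
  cat("  ", nrow(x$hits), " annotation hits, ", nrow(x$catalog),
      " reference proteins, ", sum(x$truth$is_de), " true DE genes (",
      sum(x$truth$is_exclusive), " exclusive)\n", sep = "")
  invisible(x)
}

#' Write all files of a synthetic dataset
#'
#' Writes `contigs.tsv`, `isotigs.tsv`, `hits.tsv`, `catalog.tsv`,
#' `ontology_edges.tsv`, `slim.txt` and `truth.tsv` into `dir`.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_assembly(sim$assembly, file.path(dir, "contigs.tsv"),
                 file.path(dir, "isotigs.tsv"))
  write_blast_tab(sim$hits, file.path(dir, "hits.tsv"))
  write_protein_catalog(sim$catalog, file.path(dir, "catalog.tsv"))
  write_ontology(sim$ontology, file.path(dir, "ontology_edges.tsv"),
                 file.path(dir, "slim.txt"))
  tr <- sim$truth
  tr$true_logFC <- sprintf("%.6g", tr$true_logFC)
  num <- vapply(tr, is.numeric, logical(1L))
  tr[num] <- lapply(tr[num], function(v)
    if (is.integer(v)) v else sprintf("%.10g", v))
  .write_tsv(tr, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Score DE calls against the truth manifest
#'
#' Confusion summary of a DE caller's output against the generator's truth:
#' true/false positives and negatives at the caller's significance flag, the
#' corresponding rates, and bias / RMSE of the estimated log fold change on
#' the truly DE genes with a finite true value (exclusive genes, whose true
#' log fold change is infinite, are excluded from the bias but counted in
#' detection).
#'
#' @param de A `de_result` (or data frame with `unigene_id`, `significant`,
#'   `logFC`). Every result id must exist in the manifest; manifest genes
#'   missing from the results are treated as not called.
#' @param manifest The `truth` component of a [simulate_dataset()] result.
#' @return Object of class `truth_eval`: list with `confusion` (TP, FP, FN,
#'   TN), `tpr`, `fpr`, `logfc_bias`, `logfc_rmse`, `n_logfc`.
#' @export
truth_eval <- function(de, manifest) {
  stopifnot(is.data.frame(de), is.data.frame(manifest))
  unknown <- setdiff(de$unigene_id, manifest$unigene_id)
  if (length(unknown))
    stop("DE result id '", unknown[1L], "' absent from the truth manifest",
         call. = FALSE)
  m <- match(manifest$unigene_id, de$unigene_id)
  called <- !is.na(m) & de$significant[ifelse(is.na(m), 1L, m)]
  called[is.na(m)] <- FALSE
  est_lfc <- ifelse(is.na(m), NA_real_, de$logFC[ifelse(is.na(m), 1L, m)])
  tp <- sum(called & manifest$is_de)
  fp <- sum(called & !manifest$is_de)
  fn <- sum(!called & manifest$is_de)
  tn <- sum(!called & !manifest$is_de)
  fin <- manifest$is_de & is.finite(manifest$true_logFC) &
    !manifest$is_exclusive & !is.na(est_lfc)
  dlt <- est_lfc[fin] - manifest$true_logFC[fin]
  structure(list(confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 logfc_bias = if (length(dlt)) mean(dlt) else NA_real_,
                 logfc_rmse = if (length(dlt)) sqrt(mean(dlt^2)) else NA_real_,
                 n_logfc = length(dlt)),
            class = "truth_eval")
}

#' @export
print.truth_eval <- function(x, ...) {
  cf <- x$confusion
  cat(sprintf("DE calls vs truth: TP %d, FP %d, FN %d, TN %d (TPR %.3f, FPR %.3f)\n",
              cf["TP"], cf["FP"], cf["FN"], cf["TN"], x$tpr, x$fpr))
  cat(sprintf("logFC on %d finite-truth DE genes: bias %+.4f, RMSE %.4f\n",
              x$n_logfc, x$logfc_bias, x$logfc_rmse))
  invisible(x)
}
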