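# End-to-end orchestration: simulate (or load) -> annotate -> quantify ->
# test -> classify -> profile, with every stage output written as a TSV/JSON
# file and a machine-readable run summary for provenance.

#' Build a pipeline run configuration
#'
#' Either simulates its inputs (`simulate = TRUE`, the packaged demo mode) or
#' reads them from the paths in `inputs`.
#'
#' @param out_dir Output directory for all stage files.
#' @param simulate Generate inputs with [simulate_dataset()]?
#' @param sim A [sim_config()] (used when `simulate = TRUE`).
#' @param params A [de_params()].
#' @param evalue_threshold Annotation E-value cutoff (strict; default 1e-20).
#' @param tf_lexicon Path to the TF lexicon TSV.
#' @param ec_map Path to the EC -> pathway map TSV.
#' @param use_slim Roll GO annotations up to the slim set in the frequency
#'   profile?
#' @param inputs Named list of input paths when `simulate = FALSE`:
#'   `contigs`, `isotigs`, `hits`, `catalog`, `ontology`, `slim`,
#'   `sample_ids`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       simulate = TRUE,
                       sim = sim_config(),
                       params = de_params(),
                       evalue_threshold = 1e-20,
                       tf_lexicon = system.file("extdata", "tf_lexicon.tsv",
                                                package = "estprofiler"),
                       ec_map = system.file("extdata", "ec_pathway_map.tsv",
                                            package = "estprofiler"),
                       use_slim = TRUE,
                       inputs = NULL) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L,
            inherits(params, "de_params"),
            evalue_threshold > 0)
  if (simulate) {
    stopifnot(inherits(sim, "sim_config"))
  } else {
    need <- c("contigs", "isotigs", "hits", "catalog", "ontology", "slim",
              "sample_ids")
    missing <- setdiff(need, names(inputs))
    if (length(missing))
      stop("inputs must provide: ", paste(missing, collapse = ", "),
           call. = FALSE)
    for (f in setdiff(need, "sample_ids"))
      if (!file.exists(inputs[[f]]))
        stop("input file not found: ", inputs[[f]], call. = FALSE)
  }
  for (f in c(tf_lexicon, ec_map))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  structure(list(out_dir = out_dir, simulate = simulate, sim = sim,
                 params = params, evalue_threshold = evalue_threshold,
                 tf_lexicon = tf_lexicon, ec_map = ec_map,
                 use_slim = use_slim, inputs = inputs),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `out_dir`, `simulate`, `use_slim`,
#' `evalue_threshold`, `tf_lexicon`, `ec_map`, plus nested `sim` (fields of
#' [sim_config()]) and `params` (fields of [de_params()]); unset fields take
#' the package defaults. Relative paths are kept as given.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim
  if (!is.null(simargs$library_sizes))
    simargs$library_sizes <- unlist(simargs$library_sizes)
  sim <- do.call(sim_config, if (is.null(simargs)) list() else simargs)
  params <- do.call(de_params, if (is.null(y$params)) list() else y$params)
  args <- list(out_dir = if (is.null(out_dir)) y$out_dir else out_dir,
               sim = sim, params = params)
  for (k in c("simulate", "evalue_threshold", "tf_lexicon", "ec_map",
              "use_slim", "inputs"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

#' @noRd
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full profiling pipeline
#'
#' Executes simulate/load -> annotate -> quantify -> test -> classify ->
#' profile, writing every stage output under `config$out_dir` and a
#' `run_summary.json` with the stage counts, the configuration echo, and the
#' seed. A `RUN_INCOMPLETE` marker file exists while the run is in flight so
#' partial outputs are recognizable; any stage failure aborts with the stage
#' name and cause.
#'
#' Outputs: the dataset files (simulated runs only), `unigenes.tsv`,
#' `expression.tsv`, `de.tsv`, `clusters.tsv`, `venn.json`,
#' `tf_catalog.tsv`, `go_freq.tsv`, `pathway_profile.tsv`,
#' `run_summary.json`.
#'
#' @param config A [run_config()].
#' @return The run summary, invisibly (class `run_summary`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$out_dir, "RUN_INCOMPLETE")
  writeLines("run in progress; outputs may be stale", marker)

  if (config$simulate) {
    sim <- .stage("simulate", {
      s <- simulate_dataset(config$sim)
      write_sim_dataset(s, config$out_dir)
      s
    })
    assembly <- sim$assembly; hits <- sim$hits
    catalog <- sim$catalog; ontology <- sim$ontology
    seed <- config$sim$seed
  } else {
    inp <- config$inputs
    assembly <- .stage("load", read_assembly(inp$contigs, inp$isotigs,
                                             inp$sample_ids))
    hits <- .stage("load", read_blast_tab(inp$hits))
    catalog <- .stage("load", read_protein_catalog(inp$catalog))
    ontology <- .stage("load", read_ontology(inp$ontology, inp$slim))
    seed <- NA_integer_
  }

  clusters <- .stage("annotate", {
    kept <- filter_hits(hits, config$evalue_threshold)
    assignments <- assign_best_hit(kept)
    cl <- cluster_unigenes(assignments, catalog)
    long <- data.frame(
      unigene_id = rep(names(cl), lengths(cl)),
      isotig_id = unlist(cl, use.names = FALSE),
      stringsAsFactors = FALSE)
    .write_tsv(long, file.path(config$out_dir, "unigenes.tsv"))
    cl
  })

  expr <- .stage("quantify", {
    e <- build_expression_table(clusters, assembly, catalog)
    write_expression_table(e, file.path(config$out_dir, "expression.tsv"))
    e
  })

  de <- .stage("detest", {
    d <- run_de(expr, config$params)
    write_de_result(d, file.path(config$out_dir, "de.tsv"))
    d
  })

  cls <- .stage("classify", {
    labels <- assign_clusters(de, expr)
    .write_tsv(data.frame(unigene_id = names(labels),
                          cluster = as.character(labels),
                          stringsAsFactors = FALSE),
               file.path(config$out_dir, "clusters.tsv"))
    summ <- partition_summary(labels)
    jsonlite::write_json(summ, file.path(config$out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    lex <- read_tf_lexicon(config$tf_lexicon)
    tf <- build_tf_catalog(de, labels, catalog, lex)
    .write_tsv(tf, file.path(config$out_dir, "tf_catalog.tsv"))
    list(labels = labels, summary = summ, tf = tf)
  })

  prof <- .stage("profile", {
    labels <- cls$labels
    ann <- stats::setNames(catalog$go_terms, catalog$protein_id)
    sets <- list(
      side1 = names(labels)[labels %in% c("A1", "A2")],
      side2 = names(labels)[labels %in% c("B1", "B2")])
    names(sets) <- attr(de, "samples")
    freq <- term_frequencies(sets, ann, ontology,
                             use_slim = config$use_slim)
    .write_tsv(freq, file.path(config$out_dir, "go_freq.tsv"))
    degs <- de$unigene_id[de$significant]
    ecp <- ec_pathway_profile(degs, catalog, read_ec_pathway_map(config$ec_map))
    .write_tsv(ecp, file.path(config$out_dir, "pathway_profile.tsv"))
    list(freq = freq, pathways = ecp)
  })

  counts <- cls$summary$counts
  summary <- list(
    n_isotigs_annotated = sum(lengths(clusters)),
    n_unigenes = length(clusters),
    n_degs = sum(de$significant),
    cluster_counts = as.list(counts),
    n_tf = nrow(cls$tf),
    n_tf_families = length(unique(cls$tf$family)),
    n_pathways = nrow(prof$pathways),
    seed = seed,
    config = list(
      simulate = config$simulate,
      evalue_threshold = config$evalue_threshold,
      phi = config$params$phi,
      alpha = config$params$alpha,
      pseudocount = config$params$pseudocount,
      two_sided = config$params$two_sided,
      use_slim = config$use_slim,
      sim = if (config$simulate)
        config$sim[setdiff(names(config$sim), "library_sizes")] else NULL,
      library_sizes = if (config$simulate)
        as.list(config$sim$library_sizes) else NULL))
  jsonlite::write_json(summary,
                       file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(marker)
  class(summary) <- "run_summary"
  invisible(summary)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run summary\n")
  cat(sprintf("  annotated isotigs : %d\n", x$n_isotigs_annotated))
  cat(sprintf("  unigenes          : %d\n", x$n_unigenes))
  cat(sprintf("  DEGs (p < %g)     : %d\n", x$config$alpha, x$n_degs))
  cat("  clusters          :",
      paste(names(x$cluster_counts), unlist(x$cluster_counts),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  TF DEGs           : %d in %d families\n",
              x$n_tf, x$n_tf_families))
  cat(sprintf("  pathways hit      : %d\n", x$n_pathways))
  invisible(x)
}

#' Path to the packaged demo configuration
#'
#' A small seeded simulated run (60 genes) exercising every pipeline stage;
#' used by the examples and the end-to-end tests.
#'
#' @return Path to a YAML file.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "estprofiler")
}
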