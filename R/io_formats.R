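# Readers and writers for every external file the pipeline touches.
# All tabular files are TSV, UTF-8, '.' decimal separator, '#' comment lines
# ignored; tables carry a header row except BLAST tabular (outfmt-6, which by
# convention has none). Writers produce byte-stable output so identical inputs
# give identical files.

#' @keywords internal
#' @noRd
.stop_parse <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, ifelse(is.na(line), "?", line), msg),
       call. = FALSE)
}

# Read a TSV into a list of character vectors, one per non-comment line,
# keeping original line numbers so errors can be located.
#' @noRd
.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(fields = strsplit(raw[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' @noRd
.read_tsv_table <- function(path, required_cols) {
  lx <- .read_tsv_lines(path)
  if (length(lx$fields) == 0L) .stop_parse(path, NA, "empty file (no header)")
  header <- lx$fields[[1L]]
  missing <- setdiff(required_cols, header)
  if (length(missing))
    .stop_parse(path, lx$lineno[1L],
                paste0("missing column(s): ", paste(missing, collapse = ", ")))
  body <- lx$fields[-1L]
  nums <- lx$lineno[-1L]
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    .stop_parse(path, nums[bad[1L]],
                sprintf("expected %d fields, found %d",
                        length(header), length(body[[bad[1L]]])))
  mat <- if (length(body)) do.call(rbind, body) else
    matrix(character(), 0L, length(header))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  attr(df, "lineno") <- nums
  df
}

#' @noRd
.as_count <- function(x, path, lineno, what) {
  n <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(n) | n < 0 | n != floor(n))
  if (length(bad))
    .stop_parse(path, lineno[bad[1L]],
                sprintf("%s must be a non-negative integer, got '%s'",
                        what, x[bad[1L]]))
  as.integer(n)
}

#' @noRd
.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cells <- vapply(df, as.character, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an assembly description (contig counts + isotig membership)
#'
#' An assembly dataset is the product of a de novo assembler run: contigs with
#' a length and a read count per sequencing library, plus isotigs (putative
#' transcript isoforms) given as ordered lists of member contigs. Reads attach
#' to contigs; isotigs only reference them.
#'
#' @param contig_path TSV with columns `contig_id`, `length_nt`, and one
#'   `reads_<sample>` column per declared sample.
#' @param isotig_path TSV with columns `isotig_id`, `contigs` (comma-joined
#'   contig ids, in path order).
#' @param sample_ids Character vector of declared sample names; every one must
#'   have a `reads_<sample>` column.
#' @return An object of class `assembly_dataset`: a list with elements
#'   `contigs` (data frame: contig_id, length_nt, one count column per
#'   sample), `isotigs` (named list: isotig_id -> character vector of member
#'   contig ids) and `sample_ids`.
#' @examples
#' d <- simulate_dataset(sim_config(n_genes = 5, seed = 1))
#' td <- tempfile(); dir.create(td)
#' write_assembly(d$assembly, file.path(td, "contigs.tsv"),
#'                file.path(td, "isotigs.tsv"))
#' a <- read_assembly(file.path(td, "contigs.tsv"),
#'                    file.path(td, "isotigs.tsv"), d$assembly$sample_ids)
#' a
#' @seealso [write_assembly()], [simulate_dataset()]
#' @export
read_assembly <- function(contig_path, isotig_path, sample_ids) {
  stopifnot(is.character(sample_ids), length(sample_ids) >= 1L)
  cnt_cols <- paste0("reads_", sample_ids)
  ctg <- .read_tsv_table(contig_path, c("contig_id", "length_nt", cnt_cols))
  lineno <- attr(ctg, "lineno")
  dup <- duplicated(ctg$contig_id)
  if (any(dup))
    .stop_parse(contig_path, lineno[which(dup)[1L]],
                paste0("duplicate contig_id '", ctg$contig_id[dup][1L], "'"))
  len <- suppressWarnings(as.numeric(ctg$length_nt))
  bad <- which(is.na(len) | len < 1 | len != floor(len))
  if (length(bad))
    .stop_parse(contig_path, lineno[bad[1L]],
                sprintf("length_nt must be a positive integer, got '%s'",
                        ctg$length_nt[bad[1L]]))
  contigs <- data.frame(contig_id = ctg$contig_id,
                        length_nt = as.integer(len),
                        stringsAsFactors = FALSE)
  for (cc in cnt_cols)
    contigs[[cc]] <- .as_count(ctg[[cc]], contig_path, lineno, cc)

  iso <- .read_tsv_table(isotig_path, c("isotig_id", "contigs"))
  ilineno <- attr(iso, "lineno")
  dup <- duplicated(iso$isotig_id)
  if (any(dup))
    .stop_parse(isotig_path, ilineno[which(dup)[1L]],
                paste0("duplicate isotig_id '", iso$isotig_id[dup][1L], "'"))
  members <- strsplit(iso$contigs, ",", fixed = TRUE)
  for (i in seq_along(members)) {
    m <- members[[i]]
    if (length(m) == 0L || any(!nzchar(m)))
      .stop_parse(isotig_path, ilineno[i], "isotig has no member contigs")
    if (anyDuplicated(m))
      .stop_parse(isotig_path, ilineno[i],
                  paste0("duplicate contig within isotig '",
                         iso$isotig_id[i], "'"))
    unknown <- setdiff(m, contigs$contig_id)
    if (length(unknown))
      .stop_parse(isotig_path, ilineno[i],
                  paste0("isotig '", iso$isotig_id[i],
                         "' references unknown contig '", unknown[1L], "'"))
  }
  names(members) <- iso$isotig_id
  structure(list(contigs = contigs, isotigs = members,
                 sample_ids = sample_ids),
            class = "assembly_dataset")
}

#' Write an assembly dataset to a pair of TSV files
#'
#' Inverse of [read_assembly()]; `read_assembly(write_assembly(x))` returns a
#' structurally identical dataset.
#'
#' @param assembly An `assembly_dataset`.
#' @param contig_path,isotig_path Output paths.
#' @export
write_assembly <- function(assembly, contig_path, isotig_path) {
  stopifnot(inherits(assembly, "assembly_dataset"))
  .write_tsv(assembly$contigs, contig_path)
  iso <- data.frame(isotig_id = names(assembly$isotigs),
                    contigs = vapply(assembly$isotigs, paste,
                                     character(1L), collapse = ","),
                    stringsAsFactors = FALSE)
  .write_tsv(iso, isotig_path)
  invisible(assembly)
}

#' @export
print.assembly_dataset <- function(x, ...) {
  cat("Assembly dataset:", nrow(x$contigs), "contigs,",
      length(x$isotigs), "isotigs,",
      length(x$sample_ids), "samples\n")
  for (s in x$sample_ids)
    cat(sprintf("  %s: %d reads\n", s, sum(x$contigs[[paste0("reads_", s)]])))
  invisible(x)
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Standard 12-column BLAST tabular layout, no header:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore. E-values are parsed from scientific notation.
#'
#' @param path Path to the hits file.
#' @return Data frame with the 12 standard columns; `qseqid` is the isotig,
#'   `sseqid` the reference protein.
#' @export
read_blast_tab <- function(path) {
  lx <- .read_tsv_lines(path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  bad <- which(lengths(lx$fields) != 12L)
  if (length(bad))
    .stop_parse(path, lx$lineno[bad[1L]],
                sprintf("expected 12 tab-separated columns, found %d",
                        length(lx$fields[[bad[1L]]])))
  if (length(lx$fields) == 0L) {
    df <- as.data.frame(matrix(character(), 0L, 12L),
                        stringsAsFactors = FALSE)
    names(df) <- cols
  } else {
    df <- as.data.frame(do.call(rbind, lx$fields), stringsAsFactors = FALSE)
    names(df) <- cols
  }
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    nb <- which(is.na(v) & nzchar(df[[cc]]))
    if (length(nb) || anyNA(v))
      .stop_parse(path, lx$lineno[if (length(nb)) nb[1L] else which(is.na(v))[1L]],
                  paste0("non-numeric value in column ", cc))
    df[[cc]] <- v
  }
  if (nrow(df)) {
    if (any(df$evalue < 0))
      .stop_parse(path, lx$lineno[which(df$evalue < 0)[1L]],
                  "negative E-value")
    if (any(!is.finite(df$bitscore)))
      .stop_parse(path, lx$lineno[which(!is.finite(df$bitscore))[1L]],
                  "non-finite bitscore")
    if (any(!nzchar(df$qseqid) | !nzchar(df$sseqid)))
      .stop_parse(path,
                  lx$lineno[which(!nzchar(df$qseqid) | !nzchar(df$sseqid))[1L]],
                  "empty query or subject id")
  }
  df
}

#' Write BLAST tabular hits (outfmt 6)
#' @param hits Data frame as returned by [read_blast_tab()].
#' @param path Output path.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(is.data.frame(hits), ncol(hits) == 12L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(hits)) {
    fmt <- function(x) {
      if (is.numeric(x)) vapply(x, format, character(1L), scientific = NA,
                                digits = 15) else as.character(x)
    }
    cells <- vapply(hits, fmt, character(nrow(hits)))
    if (nrow(hits) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(hits)
}

#' Read a reference-protein catalog
#'
#' Columns: `protein_id`, `aa_length` (amino acids), `description`,
#' `go_terms` (semicolon-joined ontology term ids, may be empty),
#' `ec_codes` (semicolon-joined EC numbers, may be empty). EC codes must match
#' `d.d.d.d` with optional trailing `-` levels (e.g. `3.2.1.-`).
#'
#' @param path Path to catalog TSV.
#' @return Data frame with list-columns `go_terms` and `ec_codes`.
#' @export
read_protein_catalog <- function(path) {
  df <- .read_tsv_table(path, c("protein_id", "aa_length", "description",
                                "go_terms", "ec_codes"))
  lineno <- attr(df, "lineno")
  dup <- duplicated(df$protein_id)
  if (any(dup))
    .stop_parse(path, lineno[which(dup)[1L]],
                paste0("duplicate protein_id '", df$protein_id[dup][1L], "'"))
  aa <- suppressWarnings(as.numeric(df$aa_length))
  bad <- which(is.na(aa) | aa < 1 | aa != floor(aa))
  if (length(bad))
    .stop_parse(path, lineno[bad[1L]],
                sprintf("aa_length must be a positive integer, got '%s'",
                        df$aa_length[bad[1L]]))
  split_multi <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  ec <- split_multi(df$ec_codes)
  ec_re <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"
  for (i in seq_along(ec)) {
    badec <- ec[[i]][!grepl(ec_re, ec[[i]])]
    if (length(badec))
      .stop_parse(path, lineno[i],
                  paste0("malformed EC code '", badec[1L], "'"))
  }
  out <- data.frame(protein_id = df$protein_id,
                    aa_length = as.integer(aa),
                    description = df$description,
                    stringsAsFactors = FALSE)
  out$go_terms <- split_multi(df$go_terms)
  out$ec_codes <- ec
  out
}

#' Write a reference-protein catalog
#' @param catalog Data frame as returned by [read_protein_catalog()].
#' @param path Output path.
#' @export
write_protein_catalog <- function(catalog, path) {
  join <- function(col) vapply(col, paste, character(1L), collapse = ";")
  df <- data.frame(protein_id = catalog$protein_id,
                   aa_length = catalog$aa_length,
                   description = catalog$description,
                   go_terms = join(catalog$go_terms),
                   ec_codes = join(catalog$ec_codes),
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(catalog)
}

# ---------------------------------------------------------------------------
# Ontology

#' @noRd
.detect_cycle <- function(term_ids, child, parent) {
  # Kahn's algorithm; returns NULL if acyclic, else one cycle as a vector.
  idx <- seq_along(term_ids)
  names(idx) <- term_ids
  out_edges <- split(idx[parent], idx[child])  # child -> parents (direction of traversal)
  indeg <- integer(length(term_ids))           # in-degree of the parent side
  tab <- table(idx[parent])
  indeg[as.integer(names(tab))] <- as.integer(tab)
  # Kahn removes nodes with zero remaining incoming traversal edges; simplest
  # is to peel leaves of the child->parent graph repeatedly.
  remaining <- rep(TRUE, length(term_ids))
  outdeg <- integer(length(term_ids))
  tab2 <- table(idx[child])
  outdeg[as.integer(names(tab2))] <- as.integer(tab2)
  queue <- which(outdeg == 0L)
  rev_edges <- split(idx[child], idx[parent])  # parent -> children
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    remaining[v] <- FALSE
    for (ch in rev_edges[[as.character(v)]]) {
      outdeg[ch] <- outdeg[ch] - 1L
      if (outdeg[ch] == 0L && remaining[ch]) queue <- c(queue, ch)
    }
  }
  if (!any(remaining)) return(NULL)
  # walk inside the remaining subgraph until a vertex repeats
  v <- which(remaining)[1L]
  path <- integer()
  while (!(v %in% path)) {
    path <- c(path, v)
    nxt <- out_edges[[as.character(v)]]
    nxt <- nxt[remaining[nxt]]
    v <- nxt[1L]
  }
  cyc <- path[which(path == v)[1L]:length(path)]
  term_ids[c(cyc, v)]
}

#' Read an ontology plus a slim-term list
#'
#' Accepts either a restricted OBO 1.2 file (only `id`, `name`, `namespace`,
#' `is_a` and `relationship: part_of` tags of `[Term]` stanzas are used) or a
#' 3-column edge TSV (`child`, `parent`, `relation`). Only `is_a` and
#' `part_of` edges are retained for traversal; the graph restricted to those
#' relations must be acyclic. The slim file lists one term id per line.
#'
#' @param path Ontology file (`.obo`, or an edge-list TSV).
#' @param slim_path Optional slim list; `NULL` for an empty slim set.
#' @return Object of class `ontology_bundle`: list with `terms` (data frame:
#'   term_id, name, namespace), `edges` (data frame: child, parent, relation),
#'   `slim` (character vector) and `parents` (adjacency list used for
#'   traversal).
#' @export
read_ontology <- function(path, slim_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  is_obo <- grepl("\\.obo$", path) ||
    any(grepl("^(format-version:|\\[Term\\])", first))
  if (is_obo) {
    raw <- readLines(path, warn = FALSE)
    terms <- list(); edges <- list()
    cur <- NULL
    flush <- function(cur) {
      if (!is.null(cur$id)) {
        terms[[length(terms) + 1L]] <<- data.frame(
          term_id = cur$id,
          name = if (is.null(cur$name)) cur$id else cur$name,
          namespace = if (is.null(cur$namespace)) "" else cur$namespace,
          stringsAsFactors = FALSE)
        for (p in cur$is_a)
          edges[[length(edges) + 1L]] <<- c(cur$id, p, "is_a")
        for (p in cur$part_of)
          edges[[length(edges) + 1L]] <<- c(cur$id, p, "part_of")
      }
    }
    in_term <- FALSE
    for (ln in raw) {
      ln <- sub("!.*$", "", ln)
      ln <- trimws(ln)
      if (ln == "[Term]") {
        flush(cur); cur <- list(); in_term <- TRUE
      } else if (grepl("^\\[", ln)) {
        flush(cur); cur <- NULL; in_term <- FALSE
      } else if (in_term && nzchar(ln)) {
        if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
        else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
        else if (grepl("^namespace:", ln))
          cur$namespace <- trimws(sub("^namespace:", "", ln))
        else if (grepl("^is_a:", ln))
          cur$is_a <- c(cur$is_a, trimws(sub("^is_a:", "", ln)))
        else if (grepl("^relationship:\\s*part_of\\s", ln))
          cur$part_of <- c(cur$part_of,
                           trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
      }
    }
    flush(cur)
    terms <- if (length(terms)) do.call(rbind, terms) else
      data.frame(term_id = character(), name = character(),
                 namespace = character(), stringsAsFactors = FALSE)
    edges <- if (length(edges)) {
      e <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
      names(e) <- c("child", "parent", "relation")
      e
    } else data.frame(child = character(), parent = character(),
                      relation = character(), stringsAsFactors = FALSE)
  } else {
    e <- .read_tsv_table(path, c("child", "parent", "relation"))
    edges <- data.frame(child = e$child, parent = e$parent,
                        relation = e$relation, stringsAsFactors = FALSE)
    edges <- edges[edges$relation %in% c("is_a", "part_of"), , drop = FALSE]
    ids <- sort(unique(c(e$child, e$parent)))
    terms <- data.frame(term_id = ids, name = ids,
                        namespace = "", stringsAsFactors = FALSE)
  }
  edges <- edges[edges$relation %in% c("is_a", "part_of"), , drop = FALSE]
  unknown <- setdiff(c(edges$child, edges$parent), terms$term_id)
  if (length(unknown))
    stop("ontology edge references unknown term '", unknown[1L], "'",
         call. = FALSE)
  cyc <- .detect_cycle(terms$term_id, edges$child, edges$parent)
  if (!is.null(cyc))
    stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  slim <- character()
  if (!is.null(slim_path)) {
    sl <- readLines(slim_path, warn = FALSE)
    slim <- trimws(sl[!grepl("^\\s*(#|$)", sl)])
    missing <- setdiff(slim, terms$term_id)
    if (length(missing))
      stop("slim term '", missing[1L], "' absent from ontology",
           call. = FALSE)
  }
  parents <- split(edges$parent, factor(edges$child,
                                        levels = terms$term_id))
  structure(list(terms = terms, edges = edges, slim = slim,
                 parents = parents),
            class = "ontology_bundle")
}

#' @export
print.ontology_bundle <- function(x, ...) {
  cat("Ontology bundle:", nrow(x$terms), "terms,", nrow(x$edges),
      "is_a/part_of edges,", length(x$slim), "slim terms\n")
  ns <- table(x$terms$namespace)
  for (n in names(ns)) cat(sprintf("  %s: %d\n", n, ns[[n]]))
  invisible(x)
}

#' Write an ontology bundle as an edge-list TSV plus slim list
#' @param bundle An `ontology_bundle`.
#' @param path Edge TSV output path.
#' @param slim_path Optional output path for the slim list.
#' @export
write_ontology <- function(bundle, path, slim_path = NULL) {
  .write_tsv(bundle$edges, path)
  if (!is.null(slim_path)) {
    con <- file(slim_path, open = "wb")
    writeLines(bundle$slim, con)
    close(con)
  }
  invisible(bundle)
}

#' Read unigene/protein -> ontology term annotations
#' @param path TSV with columns `protein_id`, `term_id`.
#' @return Data frame with those two columns.
#' @export
read_annotations <- function(path) {
  df <- .read_tsv_table(path, c("protein_id", "term_id"))
  data.frame(protein_id = df$protein_id, term_id = df$term_id,
             stringsAsFactors = FALSE)
}

#' Read an EC-to-pathway map
#'
#' @param path TSV with columns `ec`, `pathway`. ECs are validated against the
#'   `d.d.d.d` pattern (trailing `-` levels allowed); a malformed EC is a
#'   fatal load error.
#' @return Data frame with columns `ec`, `pathway`.
#' @export
read_ec_pathway_map <- function(path) {
  df <- .read_tsv_table(path, c("ec", "pathway"))
  lineno <- attr(df, "lineno")
  ec_re <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"
  bad <- which(!grepl(ec_re, df$ec))
  if (length(bad))
    .stop_parse(path, lineno[bad[1L]],
                paste0("malformed EC code '", df$ec[bad[1L]], "'"))
  data.frame(ec = df$ec, pathway = df$pathway, stringsAsFactors = FALSE)
}
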