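# GO term-frequency profiles with GO-slim rollup, and EC -> pathway enzyme
# counting.
#
# A slim set is a curated subset of ontology terms used to summarize
# annotations at coarse granularity: each annotated term is "translated" to
# the slim terms reachable from it by walking is_a/part_of edges upward
# (ancestors-or-self). Term frequencies count, per term and gene set, the
# number of genes carrying the term at least once (a gene never contributes
# twice to the same term).

#' @noRd
.ancestors_or_self <- function(term, parents) {
  seen <- character(); queue <- term
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, parents[[t]])
  }
  seen
}

#' Translate one term to its slim representatives
#'
#' Returns the slim terms that are ancestors-or-self of `term` along
#' is_a/part_of edges. With `nearest_only = TRUE` only the slim terms at the
#' smallest upward distance are returned (the "nearest slim" convention);
#' the default keeps all reachable slim terms.
#'
#' @param term A term id present in the ontology.
#' @param bundle An `ontology_bundle` with a non-empty slim set.
#' @param nearest_only Keep only the closest slim terms (by edge distance).
#' @return Character vector of slim term ids (possibly empty).
#' @export
rollup_to_slim <- function(term, bundle, nearest_only = FALSE) {
  stopifnot(inherits(bundle, "ontology_bundle"), length(term) == 1L)
  if (!term %in% bundle$terms$term_id)
    stop("unknown ontology term '", term, "'", call. = FALSE)
  if (!nearest_only) {
    anc <- .ancestors_or_self(term, bundle$parents)
    return(intersect(anc, bundle$slim))
  }
  # breadth-first by level; stop at the first level containing slim terms
  level <- term; seen <- character()
  while (length(level)) {
    hit <- intersect(level, bundle$slim)
    if (length(hit)) return(sort(unique(hit)))
    seen <- c(seen, level)
    nxt <- unique(unlist(bundle$parents[level], use.names = FALSE))
    level <- setdiff(nxt, seen)
  }
  character()
}

#' @noRd
.annotation_list <- function(annotations) {
  # accept a named list (gene -> terms) or a two-column data frame
  if (is.data.frame(annotations)) {
    split(annotations$term_id, annotations$protein_id)
  } else {
    annotations
  }
}

#' Per-namespace term occurrence counts for one or more gene sets
#'
#' Counts, for every ontology term (or slim term after rollup), how many
#' genes of each set carry it; a gene contributes at most once per term
#' however many of its annotations map there.
#'
#' @param gene_sets Character vector (one set) or named list of character
#'   vectors (several sets, e.g. fruit- and AZ-overexpressed unigenes).
#' @param annotations Gene-to-term map: a named list (gene id -> character
#'   vector of term ids) or a data frame with columns `protein_id`,
#'   `term_id`. Genes without annotations simply contribute nothing.
#' @param bundle An `ontology_bundle` (for namespaces and, with
#'   `use_slim = TRUE`, the slim rollup).
#' @param use_slim Roll every annotated term up to its slim representatives
#'   before counting.
#' @param nearest_only Passed to [rollup_to_slim()] when `use_slim = TRUE`.
#' @return Data frame with columns `namespace`, `term_id`, `name`, and one
#'   `count_<set>` column per gene set, sorted by namespace and descending
#'   first-set count.
#' @export
term_frequencies <- function(gene_sets, annotations, bundle,
                             use_slim = FALSE, nearest_only = FALSE) {
  stopifnot(inherits(bundle, "ontology_bundle"))
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets))))
    stop("gene_sets must be named", call. = FALSE)
  ann <- .annotation_list(annotations)
  gene_terms <- function(gid) {
    terms <- unique(unlist(ann[gid], use.names = FALSE))
    if (use_slim && length(terms)) {
      terms <- unique(unlist(lapply(terms, rollup_to_slim, bundle = bundle,
                                    nearest_only = nearest_only),
                             use.names = FALSE))
    }
    terms
  }
  counts <- lapply(gene_sets, function(set) {
    tally <- unlist(lapply(unique(set), gene_terms), use.names = FALSE)
    table(tally)
  })
  all_terms <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  if (length(all_terms) == 0L) {
    out <- data.frame(namespace = character(), term_id = character(),
                      name = character(), stringsAsFactors = FALSE)
    for (nm in names(gene_sets)) out[[paste0("count_", nm)]] <- integer()
    return(out)
  }
  m <- match(all_terms, bundle$terms$term_id)
  out <- data.frame(namespace = bundle$terms$namespace[m],
                    term_id = all_terms,
                    name = bundle$terms$name[m],
                    stringsAsFactors = FALSE)
  for (nm in names(gene_sets)) {
    v <- integer(length(all_terms))
    tb <- counts[[nm]]
    idx <- match(names(tb), all_terms)
    v[idx] <- as.integer(tb)
    out[[paste0("count_", nm)]] <- v
  }
  first <- paste0("count_", names(gene_sets)[1L])
  out <- out[order(out$namespace, -out[[first]], out$term_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' EC -> pathway enzyme profile of a DEG set
#'
#' For each pathway of the map, the distinct EC codes carried by the given
#' differentially expressed unigenes (via their reference proteins), and the
#' enzyme count `|EC set|`. Sorted by enzyme count, descending (the order of
#' a pathway-enrichment histogram).
#'
#' @param deg_ids Character vector of DEG unigene ids.
#' @param catalog Reference-protein catalog with `ec_codes` list-column.
#' @param ec_map Data frame from [read_ec_pathway_map()].
#' @return Data frame with columns `pathway`, `n_enzymes`, `ec_codes`
#'   (semicolon-joined, sorted).
#' @export
ec_pathway_profile <- function(deg_ids, catalog, ec_map) {
  stopifnot(is.data.frame(ec_map), all(c("ec", "pathway") %in% names(ec_map)))
  ec_re <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"
  bad <- ec_map$ec[!grepl(ec_re, ec_map$ec)]
  if (length(bad))
    stop("malformed EC code '", bad[1L], "' in pathway map", call. = FALSE)
  m <- match(unique(deg_ids), catalog$protein_id)
  if (anyNA(m))
    stop("DEG unigene '", unique(deg_ids)[which(is.na(m))[1L]],
         "' absent from the catalog", call. = FALSE)
  ecs <- unique(unlist(catalog$ec_codes[m], use.names = FALSE))
  hit <- ec_map[ec_map$ec %in% ecs, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(data.frame(pathway = character(), n_enzymes = integer(),
                      ec_codes = character(), stringsAsFactors = FALSE))
  by_pw <- split(hit$ec, hit$pathway)
  by_pw <- lapply(by_pw, function(v) sort(unique(v)))
  out <- data.frame(pathway = names(by_pw),
                    n_enzymes = lengths(by_pw),
                    ec_codes = vapply(by_pw, paste, character(1L),
                                      collapse = ";"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$n_enzymes, out$pathway), , drop = FALSE]
  row.names(out) <- NULL
  out
}
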