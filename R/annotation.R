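# Annotation-hit filtering, best-hit assignment, and unigene clustering.
#
# An isotig is annotated by at most one reference protein; isotigs annotated
# by the same protein form one unigene, named after that protein. Unannotated
# isotigs stay outside every cluster (they are the "new gene" candidates of a
# de novo project).

#' Filter annotation hits at an E-value threshold
#'
#' Keeps exactly the hits whose E-value is strictly below the threshold
#' (a hit at exactly the threshold is removed), preserving input order.
#' The default of 1e-20 is a deliberately restrictive cutoff: the smaller the
#' E-value, the higher the sequence similarity and the more trustworthy the
#' transferred function.
#'
#' @param hits Data frame of BLAST hits ([read_blast_tab()]).
#' @param evalue_threshold Strict upper bound on the E-value; must be > 0.
#' @return The filtered subset of `hits`, original order preserved.
#' @export
filter_hits <- function(hits, evalue_threshold = 1e-20) {
  stopifnot(is.data.frame(hits), is.numeric(evalue_threshold),
            length(evalue_threshold) == 1L, evalue_threshold > 0)
  hits[hits$evalue < evalue_threshold, , drop = FALSE]
}

#' Assign each isotig its single best annotation hit
#'
#' For every isotig (query) the winning hit maximizes the bitscore; ties are
#' broken by the smaller E-value and then by lexicographically smallest
#' protein id, so the assignment is a deterministic function of the hit set
#' and stable under permutation of the input rows.
#'
#' @param hits Data frame of (already filtered) BLAST hits.
#' @return Data frame with one row per annotated isotig: `isotig_id`,
#'   `protein_id`, `evalue`, `bitscore`.
#' @export
assign_best_hit <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L)
    return(data.frame(isotig_id = character(), protein_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  data.frame(isotig_id = h$qseqid[first],
             protein_id = h$sseqid[first],
             evalue = h$evalue[first],
             bitscore = h$bitscore[first],
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Cluster annotated isotigs into unigenes
#'
#' One cluster per distinct assigned reference protein; the clusters partition
#' the annotated isotigs. The unigene takes the protein's id (and, downstream,
#' its name and functional labels).
#'
#' @param assignments Data frame from [assign_best_hit()].
#' @param catalog Reference-protein catalog ([read_protein_catalog()]); every
#'   assigned protein must be present.
#' @return Object of class `unigene_clusters`: a named list mapping
#'   unigene id (= protein id) to the character vector of member isotig ids.
#' @export
cluster_unigenes <- function(assignments, catalog) {
  stopifnot(is.data.frame(assignments))
  if (nrow(assignments) == 0L)
    return(structure(stats::setNames(list(), character()),
                     class = "unigene_clusters"))
  unknown <- setdiff(assignments$protein_id, catalog$protein_id)
  if (length(unknown))
    stop("assignment to protein '", unknown[1L],
         "' absent from the catalog", call. = FALSE)
  cl <- split(assignments$isotig_id,
              factor(assignments$protein_id,
                     levels = sort(unique(assignments$protein_id))))
  structure(lapply(cl, sort), class = "unigene_clusters")
}

#' @export
print.unigene_clusters <- function(x, ...) {
  sizes <- lengths(x)
  cat("Unigene clusters:", length(x), "unigenes over", sum(sizes),
      "annotated isotigs\n")
  if (length(sizes))
    cat("  isotigs per unigene: min", min(sizes), "median",
        stats::median(sizes), "max", max(sizes), "\n")
  invisible(x)
}
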