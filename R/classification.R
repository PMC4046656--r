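# Expression-cluster labels, Venn partition, and TF-family classification.
#
# Significant unigenes split into two clusters by which tissue shows the
# higher normalized abundance (A = higher in sample 1, B = higher in sample
# 2), and each side splits again by exclusivity: A2/B2 hold the genes with a
# raw deduplicated count of exactly zero in the other tissue ("fruit genes" /
# "AZ genes" in a pericarp-vs-abscission-zone design), A1/B1 the remaining
# enriched genes. Non-significant unigenes are labeled NS.

.CLUSTER_LEVELS <- c("A1", "A2", "B1", "B2", "NS")

#' Assign an expression-cluster label to one unigene
#'
#' @param significant Logical: was the unigene significant in the exact test?
#' @param rpkm1,rpkm2 Normalized abundance (RPKM) in sample 1 / sample 2;
#'   decides the side.
#' @param count1,count2 Raw deduplicated counts; decide exclusivity (a gene
#'   is exclusive when its count in the other tissue is exactly zero). If
#'   omitted, a zero RPKM is taken as a zero count — valid because RPKM is
#'   zero if and only if the count is zero, which lets printed RPKM tables be
#'   re-classified directly.
#' @return One of `"A1"`, `"A2"`, `"B1"`, `"B2"`, `"NS"`.
#' @export
assign_cluster <- function(significant, rpkm1, rpkm2,
                           count1 = NULL, count2 = NULL) {
  if (!significant) return("NS")
  if (rpkm1 == rpkm2)
    stop("significant unigene with identical normalized abundance in both ",
         "samples: impossible under the exact-test rule, input data are ",
         "corrupt", call. = FALSE)
  zero1 <- if (is.null(count1)) rpkm1 == 0 else count1 == 0
  zero2 <- if (is.null(count2)) rpkm2 == 0 else count2 == 0
  if (rpkm1 > rpkm2) {
    if (zero2) "A2" else "A1"
  } else {
    if (zero1) "B2" else "B1"
  }
}

#' Assign cluster labels to every tested unigene
#'
#' @param de A `de_result`.
#' @param expr The matching `expression_table` (same unigenes).
#' @return Factor of labels (levels A1, A2, B1, B2, NS), named by unigene id.
#' @export
assign_clusters <- function(de, expr) {
  stopifnot(inherits(de, "de_result"), inherits(expr, "expression_table"))
  m <- match(de$unigene_id, expr$unigene_id)
  if (anyNA(m))
    stop("unigene '", de$unigene_id[which(is.na(m))[1L]],
         "' missing from the expression table", call. = FALSE)
  samples <- attr(de, "samples")
  r1 <- expr[[paste0("rpkm_", samples[1L])]][m]
  r2 <- expr[[paste0("rpkm_", samples[2L])]][m]
  c1 <- expr[[paste0("count_", samples[1L])]][m]
  c2 <- expr[[paste0("count_", samples[2L])]][m]
  lab <- vapply(seq_len(nrow(de)), function(i)
    assign_cluster(de$significant[i], r1[i], r2[i], c1[i], c2[i]),
    character(1L))
  stats::setNames(factor(lab, levels = .CLUSTER_LEVELS), de$unigene_id)
}

#' Summarize a cluster labeling
#'
#' Counts per label plus the two-set Venn partition of the significant genes:
#' genes detected in only one tissue (the exclusive clusters A2 and B2) and
#' genes detected in both but enriched on one side (A1 + B1, the "common"
#' region).
#'
#' @param labels Factor/character vector of labels (A1/A2/B1/B2/NS).
#' @return List with `counts` (named integer vector over the five labels),
#'   `side1` (= A1 + A2), `side2` (= B1 + B2), `n_significant`, and `venn`
#'   (list: `only1` = A2, `only2` = B2, `common` = A1 + B1).
#' @export
partition_summary <- function(labels) {
  labels <- factor(as.character(labels), levels = .CLUSTER_LEVELS)
  if (anyNA(labels)) stop("unknown cluster label", call. = FALSE)
  counts <- table(labels)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       side1 = counts[["A1"]] + counts[["A2"]],
       side2 = counts[["B1"]] + counts[["B2"]],
       n_significant = sum(counts[c("A1", "A2", "B1", "B2")]),
       venn = list(only1 = counts[["A2"]],
                   only2 = counts[["B2"]],
                   common = counts[["A1"]] + counts[["B1"]]))
}

# ---------------------------------------------------------------------------
# Transcription-factor families

#' Read a TF-family keyword lexicon
#'
#' TSV with columns `pattern` (case-insensitive regular expression matched
#' against the annotation description), `family`, `priority` (integer; lower
#' wins). Rules are tried in priority order and the first match decides the
#' family, so priorities must be unique: two rules at the same priority are a
#' configuration error because their overlap would make the result
#' order-dependent.
#'
#' @param path Lexicon TSV; defaults to the lexicon shipped with the package
#'   (20 plant TF families).
#' @return Data frame sorted by priority with columns `pattern`, `family`,
#'   `priority`.
#' @export
read_tf_lexicon <- function(path = system.file("extdata", "tf_lexicon.tsv",
                                               package = "estprofiler")) {
  df <- .read_tsv_table(path, c("pattern", "family", "priority"))
  lineno <- attr(df, "lineno")
  pri <- suppressWarnings(as.integer(df$priority))
  if (anyNA(pri))
    .stop_parse(path, lineno[which(is.na(pri))[1L]],
                "priority must be an integer")
  dup <- duplicated(pri)
  if (any(dup))
    .stop_parse(path, lineno[which(dup)[1L]],
                sprintf("duplicate priority %d: overlapping rules at equal priority",
                        pri[dup][1L]))
  out <- data.frame(pattern = df$pattern, family = df$family,
                    priority = pri, stringsAsFactors = FALSE)
  out[order(out$priority), , drop = FALSE]
}

#' Classify annotation descriptions into TF families
#'
#' @param description Character vector of annotation descriptions.
#' @param lexicon Lexicon from [read_tf_lexicon()].
#' @return Character vector: the first matching family in priority order, or
#'   `NA` where no rule matches (a non-TF gene).
#' @examples
#' lex <- read_tf_lexicon()
#' classify_tf(c("NAC domain protein, SlNAC1", "Beta-glucosidase"), lex)
#' @export
classify_tf <- function(description, lexicon) {
  out <- rep(NA_character_, length(description))
  for (i in seq_len(nrow(lexicon))) {
    hit <- is.na(out) &
      grepl(lexicon$pattern[i], description, ignore.case = TRUE, perl = TRUE)
    out[hit] <- lexicon$family[i]
  }
  out
}

#' Build the TF catalog of differentially expressed genes
#'
#' One entry per significant unigene whose annotation description matches a
#' TF-family rule.
#'
#' @param de A `de_result`.
#' @param labels Cluster labels from [assign_clusters()].
#' @param catalog Reference-protein catalog (for descriptions).
#' @param lexicon TF lexicon from [read_tf_lexicon()].
#' @return Data frame with columns `unigene_id`, `family`, `cluster`.
#' @export
build_tf_catalog <- function(de, labels, catalog,
                             lexicon = read_tf_lexicon()) {
  stopifnot(inherits(de, "de_result"))
  sig <- de$unigene_id[de$significant]
  m <- match(sig, catalog$protein_id)
  if (anyNA(m))
    stop("unigene '", sig[which(is.na(m))[1L]],
         "' absent from the catalog", call. = FALSE)
  fam <- classify_tf(catalog$description[m], lexicon)
  keep <- !is.na(fam)
  data.frame(unigene_id = sig[keep],
             family = fam[keep],
             cluster = as.character(labels[sig[keep]]),
             stringsAsFactors = FALSE, row.names = NULL)
}
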