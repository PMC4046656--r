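# Per-unigene read counting with shared-contig deduplication, and RPKM
# normalization against the reference-protein length.
#
# Isotigs of a unigene are isoforms and commonly share contigs; a shared
# contig's reads are counted once per unigene, i.e. the unigene count is the
# sum over the SET UNION of its member isotigs' contigs. Working without a
# reference genome there are no exon models, so the RPKM length term is the
# annotating protein's length in nucleotides (3 nt per amino acid).

#' Deduplicated read count of one unigene in one sample
#'
#' @param cluster Character vector of member isotig ids (one element of a
#'   [cluster_unigenes()] result).
#' @param assembly An `assembly_dataset`.
#' @param sample_id One of the assembly's declared samples.
#' @return Non-negative integer: the sum of read counts over the distinct
#'   contigs touched by the member isotigs.
#' @examples
#' # two isoforms sharing contig c2: reads of c2 count once
#' a <- structure(list(
#'   contigs = data.frame(contig_id = c("c1", "c2", "c3"),
#'                        length_nt = c(300L, 400L, 500L),
#'                        reads_s1 = c(5L, 7L, 3L)),
#'   isotigs = list(i1 = c("c1", "c2"), i2 = c("c2", "c3")),
#'   sample_ids = "s1"), class = "assembly_dataset")
#' dedup_count(c("i1", "i2"), a, "s1")  # 15, not 22
#' @export
dedup_count <- function(cluster, assembly, sample_id) {
  stopifnot(inherits(assembly, "assembly_dataset"))
  if (!sample_id %in% assembly$sample_ids)
    stop("unknown sample '", sample_id, "'", call. = FALSE)
  unknown <- setdiff(cluster, names(assembly$isotigs))
  if (length(unknown))
    stop("unknown isotig '", unknown[1L], "'", call. = FALSE)
  contigs <- unique(unlist(assembly$isotigs[cluster], use.names = FALSE))
  col <- assembly$contigs[[paste0("reads_", sample_id)]]
  sum(col[match(contigs, assembly$contigs$contig_id)])
}

#' Protein length in nucleotides
#'
#' Coding length of a protein of `aa_length` amino acids: `3 * aa_length`
#' (stop codon excluded).
#'
#' @param aa_length Positive integer vector (amino acids).
#' @return Integer vector of nucleotide lengths.
#' @export
protein_nt_length <- function(aa_length) {
  if (any(!is.finite(aa_length) | aa_length < 1 |
          aa_length != floor(aa_length)))
    stop("aa_length must be a positive integer", call. = FALSE)
  3L * as.integer(aa_length)
}

#' Reads per kilobase of feature length per million mapped reads
#'
#' `rpkm = 1e9 * C / (N * L)` for count `C`, library size `N` (total reads in
#' the sample) and feature length `L` in nucleotides. Vectorized; zero counts
#' give exactly zero.
#'
#' @param C Non-negative read count(s).
#' @param N Positive library size(s).
#' @param L_nt Positive feature length(s) in nucleotides.
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(C, N, L_nt) {
  if (any(N < 1)) stop("library size N must be >= 1", call. = FALSE)
  if (any(L_nt < 1)) stop("feature length L must be >= 1", call. = FALSE)
  if (any(C < 0)) stop("counts must be non-negative", call. = FALSE)
  # in double precision: N * L can overflow integer range
  1e9 * as.numeric(C) / (as.numeric(N) * as.numeric(L_nt))
}

#' Build the per-unigene expression table
#'
#' For every unigene: the deduplicated read count and the protein-length RPKM
#' in each sample. Library sizes are the total read counts per sample over
#' ALL contigs of the assembly (annotated or not), so RPKM values are
#' comparable across unigenes and across samples.
#'
#' @param clusters A `unigene_clusters` object.
#' @param assembly An `assembly_dataset`.
#' @param catalog Reference-protein catalog; must contain every unigene's
#'   protein (for its `aa_length` and `description`).
#' @return Object of class `expression_table`: data frame with columns
#'   `unigene_id`, `L_nt`, and per sample `count_<s>` and `rpkm_<s>`;
#'   attribute `library_sizes` holds the named per-sample totals.
#' @export
build_expression_table <- function(clusters, assembly, catalog) {
  stopifnot(inherits(clusters, "unigene_clusters"),
            inherits(assembly, "assembly_dataset"))
  samples <- assembly$sample_ids
  N <- vapply(samples,
              function(s) sum(assembly$contigs[[paste0("reads_", s)]]),
              numeric(1L))
  if (length(clusters) == 0L) {
    warning("no unigene clusters: expression table is empty")
    out <- data.frame(unigene_id = character(), L_nt = integer(),
                      stringsAsFactors = FALSE)
    for (s in samples) {
      out[[paste0("count_", s)]] <- integer()
      out[[paste0("rpkm_", s)]] <- numeric()
    }
    attr(out, "library_sizes") <- N
    class(out) <- c("expression_table", "data.frame")
    return(out)
  }
  ids <- names(clusters)
  m <- match(ids, catalog$protein_id)
  if (anyNA(m))
    stop("unigene protein '", ids[which(is.na(m))[1L]],
         "' absent from the catalog", call. = FALSE)
  L <- protein_nt_length(catalog$aa_length[m])
  out <- data.frame(unigene_id = ids, L_nt = L,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (s in samples) {
    cnt <- vapply(clusters, dedup_count, numeric(1L),
                  assembly = assembly, sample_id = s)
    out[[paste0("count_", s)]] <- as.integer(cnt)
    out[[paste0("rpkm_", s)]] <- rpkm(cnt, N[[s]], L)
  }
  attr(out, "library_sizes") <- N
  class(out) <- c("expression_table", "data.frame")
  out
}

#' @export
print.expression_table <- function(x, ...) {
  N <- attr(x, "library_sizes")
  cat("Expression table:", nrow(x), "unigenes;",
      "library sizes:", paste(names(N), format(N, big.mark = ","),
                              collapse = ", "), "\n")
  NextMethod()
}

#' Write an expression table
#'
#' Counts are written raw; RPKM columns are written as `rpkm1000_<s>`, the
#' RPKM value multiplied by 1000 and rounded to 2 decimals (the scale used
#' for reported per-gene expression tables).
#'
#' @param expr An `expression_table`.
#' @param path Output TSV path.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  samples <- sub("^count_", "", grep("^count_", names(expr), value = TRUE))
  df <- data.frame(unigene_id = expr$unigene_id, L_nt = expr$L_nt,
                   stringsAsFactors = FALSE)
  for (s in samples) df[[paste0("count_", s)]] <- expr[[paste0("count_", s)]]
  for (s in samples)
    df[[paste0("rpkm1000_", s)]] <-
      sprintf("%.2f", 1000 * expr[[paste0("rpkm_", s)]])
  .write_tsv(df, path)
  invisible(expr)
}
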