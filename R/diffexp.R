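# Two-sample differential expression without replicates, under a
# negative-binomial model with fixed common dispersion.
#
# Counts are modeled as Y_i ~ NB(mu = M_i * p_i, dispersion phi) with
# variance mu + phi * mu^2, where M_i is the library size and p_i the
# relative abundance of the gene in sample i; phi = 0 recovers the Poisson.
# With a single library per condition the dispersion cannot be estimated from
# the data, so it is an explicit model parameter here (see de_params()).
#
# The test conditions on the two-sample total n = y1 + y2: the conditional
# distribution of Y1 given the total is computed by normalizing
# f(k; M1*phat, phi) * f(n-k; M2*phat, phi) over k = 0..n, with the pooled
# abundance phat = n / (M1 + M2). The two-sided p-value sums the conditional
# probabilities of all outcomes no more likely than the observed one
# (minimum-likelihood rule). At phi = 0 this reduces exactly to the binomial
# exact test with success probability M1 / (M1 + M2).

# relative tolerance when comparing outcome probabilities to the observed
# one, so ties are not broken by floating-point noise
.TIE_EPS <- 1e-10

#' Model parameters for the no-replicate NB exact test
#'
#' @param phi Common NB dispersion (variance = mu + phi * mu^2); `phi = 0` is
#'   the Poisson special case. With one library per condition the dispersion
#'   is not estimable from the data, so it is set here; the default 0.1 is a
#'   moderate overdispersion typical of bulk count data.
#' @param alpha Significance level for the raw-p-value DE flag (default 0.01).
#' @param pseudocount Added to both counts in the log fold change so genes
#'   expressed in only one sample get a finite value (default 0.5).
#' @param two_sided Either `"minlik"` (sum all outcomes with conditional
#'   probability <= the observed one; the default, and the rule under which
#'   the phi = 0 case collapses to the classic binomial exact test) or
#'   `"double"` (double the smaller one-sided tail, capped at 1).
#' @return Object of class `de_params`.
#' @export
de_params <- function(phi = 0.1, alpha = 0.01, pseudocount = 0.5,
                      two_sided = c("minlik", "double")) {
  two_sided <- match.arg(two_sided)
  stopifnot(is.numeric(phi), length(phi) == 1L, phi >= 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount > 0)
  structure(list(phi = phi, alpha = alpha, pseudocount = pseudocount,
                 two_sided = two_sided),
            class = "de_params")
}

#' @export
print.de_params <- function(x, ...) {
  cat(sprintf(
    "NB exact-test parameters: phi = %g, alpha = %g, pseudocount = %g, %s rule\n",
    x$phi, x$alpha, x$pseudocount, x$two_sided))
  invisible(x)
}

#' Conditional NB exact test for one gene, two samples, no replicates
#'
#' @param y1,y2 Observed counts (non-negative integers).
#' @param M1,M2 Library sizes (>= 1).
#' @param phi Common dispersion (>= 0; 0 = Poisson).
#' @param two_sided Two-sided summation rule; see [de_params()].
#' @return Two-sided exact p-value in `[0, 1]`. A zero total (`y1 + y2 = 0`)
#'   carries no information and returns 1 by convention.
#' @examples
#' nb_exact_test(5, 5, 1e6, 1e6, 0)    # 1: perfectly balanced
#' nb_exact_test(10, 0, 1e6, 1e6, 0)   # 2/1024: both extreme outcomes
#' @export
nb_exact_test <- function(y1, y2, M1, M2, phi,
                          two_sided = c("minlik", "double")) {
  two_sided <- match.arg(two_sided)
  if (y1 < 0 || y2 < 0 || y1 != floor(y1) || y2 != floor(y2))
    stop("counts must be non-negative integers", call. = FALSE)
  if (M1 < 1 || M2 < 1) stop("library sizes must be >= 1", call. = FALSE)
  if (phi < 0) stop("dispersion phi must be >= 0", call. = FALSE)
  n <- y1 + y2
  if (n == 0) return(1.0)
  phat <- n / (M1 + M2)
  k <- 0:n
  if (phi == 0) {
    logf <- stats::dpois(k, M1 * phat, log = TRUE) +
      stats::dpois(n - k, M2 * phat, log = TRUE)
  } else {
    size <- 1 / phi
    logf <- stats::dnbinom(k, size = size, mu = M1 * phat, log = TRUE) +
      stats::dnbinom(n - k, size = size, mu = M2 * phat, log = TRUE)
  }
  logf <- logf - max(logf)
  pr <- exp(logf)
  pr <- pr / sum(pr)
  p_obs <- pr[y1 + 1L]
  if (two_sided == "minlik") {
    p <- sum(pr[pr <= p_obs * (1 + .TIE_EPS)])
  } else {
    lower <- sum(pr[k <= y1])
    upper <- sum(pr[k >= y1])
    p <- 2 * min(lower, upper)
  }
  min(1.0, p)
}

#' Log2 fold change with pseudocount
#'
#' `log2(((y1 + pc) / M1) / ((y2 + pc) / M2))`; finite for every input,
#' including genes with a zero count in one (or both) samples, so exclusive
#' genes sit at a finite x position in a volcano plot.
#'
#' @param y1,y2 Counts; vectorized.
#' @param M1,M2 Library sizes.
#' @param pseudocount Positive offset (default 0.5).
#' @return Numeric vector of base-2 log fold changes (sample 1 over sample 2).
#' @export
log_fold_change <- function(y1, y2, M1, M2, pseudocount = 0.5) {
  if (any(y1 < 0) || any(y2 < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(M1 < 1) || any(M2 < 1))
    stop("library sizes must be >= 1", call. = FALSE)
  stopifnot(pseudocount > 0)
  log2(((y1 + pseudocount) / M1) / ((y2 + pseudocount) / M2))
}

#' Run the exact test over an expression table
#'
#' Tests every unigene for a difference in read abundance between the two
#' samples. A unigene is flagged differentially expressed when its raw
#' p-value is below `params$alpha` (default 0.01); no multiplicity correction
#' enters the flag, but a Benjamini-Hochberg adjusted column is emitted
#' alongside for reference.
#'
#' @param expr An `expression_table` with exactly two samples.
#' @param params A [de_params()] object.
#' @return Object of class `de_result`: data frame with columns `unigene_id`,
#'   `y1`, `y2`, `logFC`, `pvalue`, `padj_BH`, `significant`; attributes
#'   `samples`, `library_sizes` and `params`.
#' @export
run_de <- function(expr, params = de_params()) {
  stopifnot(inherits(expr, "expression_table"), inherits(params, "de_params"))
  samples <- sub("^count_", "", grep("^count_", names(expr), value = TRUE))
  if (length(samples) != 2L)
    stop("run_de requires an expression table with exactly two samples",
         call. = FALSE)
  if (nrow(expr) == 0L)
    stop("empty expression table", call. = FALSE)
  N <- attr(expr, "library_sizes")
  M1 <- N[[samples[1L]]]; M2 <- N[[samples[2L]]]
  y1 <- expr[[paste0("count_", samples[1L])]]
  y2 <- expr[[paste0("count_", samples[2L])]]
  p <- vapply(seq_along(y1), function(i)
    nb_exact_test(y1[i], y2[i], M1, M2, params$phi, params$two_sided),
    numeric(1L))
  out <- data.frame(
    unigene_id = expr$unigene_id,
    y1 = y1, y2 = y2,
    logFC = log_fold_change(y1, y2, M1, M2, params$pseudocount),
    pvalue = p,
    padj_BH = stats::p.adjust(p, method = "BH"),
    significant = p < params$alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "samples") <- samples
  attr(out, "library_sizes") <- c(M1, M2)
  attr(out, "params") <- params
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  pr <- attr(x, "params")
  cat(sprintf(
    "DE results: %d unigenes tested (%s vs %s), %d significant at p < %g\n",
    nrow(x), attr(x, "samples")[1L], attr(x, "samples")[2L],
    sum(x$significant), pr$alpha))
  NextMethod()
}

#' @export
summary.de_result <- function(object, ...) {
  pr <- attr(object, "params")
  cat("No-replicate NB conditional exact test\n")
  print(pr)
  cat(sprintf("  unigenes tested : %d\n", nrow(object)))
  cat(sprintf("  significant     : %d (raw p < %g)\n",
              sum(object$significant), pr$alpha))
  cat(sprintf("  |logFC| median  : %.3f\n",
              stats::median(abs(object$logFC))))
  invisible(object)
}

#' Volcano plot of a DE result
#'
#' -log10(p) against log2 fold change; p-values are floored at 1e-300 for
#' plotting only. Significant genes are drawn in color.
#'
#' @param x A `de_result`.
#' @param labels Optional cluster labels (from [assign_clusters()]) used to
#'   color points by expression cluster.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.de_result <- function(x, labels = NULL, ...) {
  lp <- -log10(pmax(x$pvalue, 1e-300))
  col <- if (is.null(labels)) {
    ifelse(x$significant, "firebrick", "grey60")
  } else {
    c(A1 = "darkorange", A2 = "firebrick", B1 = "steelblue",
      B2 = "navy", NS = "grey60")[as.character(labels)]
  }
  graphics::plot(x$logFC, lp, col = col, pch = 16, cex = 0.6,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ "p"), ...)
  graphics::abline(h = -log10(attr(x, "params")$alpha), lty = 2,
                   col = "grey40")
  invisible(x)
}

#' Write a DE result table
#' @param de A `de_result`.
#' @param path Output TSV path.
#' @export
write_de_result <- function(de, path) {
  stopifnot(inherits(de, "de_result"))
  df <- data.frame(unigene_id = de$unigene_id, y1 = de$y1, y2 = de$y2,
                   logFC = sprintf("%.6g", de$logFC),
                   pvalue = sprintf("%.6g", de$pvalue),
                   padj_BH = sprintf("%.6g", de$padj_BH),
                   significant = de$significant,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(de)
}
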