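---
title: "Unigene profiling without replicates: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unigene profiling without replicates: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estprofiler)
```

This vignette is the package's own account of the statistical model and the
design decisions behind it: what is assumed, which knobs matter, what the
synthetic-data generator does and does not emulate, and where the method's
limits are.

## The setting

A de novo two-tissue transcriptome experiment produces, per tissue, one
sequencing library assembled into contigs (the unit reads attach to) and
isotigs (putative isoforms, each an ordered list of contigs). There is no
reference genome, no exon model, and — critically — no biological
replication. Annotation against a reference-protein catalog is the only
bridge to gene identity: isotigs annotated by the same reference protein are
collapsed into a *unigene*, and all counting, testing and functional
profiling happens at that level.

## Unigene construction

Hits are filtered at a strict E-value cutoff, by default $10^{-20}$, with a
**strict** inequality: a hit at exactly the threshold is discarded. The
boundary choice is arbitrary in principle but must be fixed for
reproducibility; strictness matches the reading "lower than the threshold".
Each isotig then keeps its best surviving hit — maximum bitscore, ties by
smaller E-value, then lexicographically smallest protein id. The tie-break
chain exists only to make the assignment a total order: without it the
result would depend on input row order. Isotigs with no surviving hit stay
unannotated; in a de novo project they are candidate novel genes, not
errors.

## Counting and normalization

Isoforms of one unigene frequently share contigs. Summing isotig counts
would count shared contigs repeatedly, so the unigene count is taken over
the **set union** of member contigs — each contig contributes once per
unigene. When cross-gene contig sharing is possible (off by default in the
generator), a contig shared by two *different* unigenes contributes once to
each, and the read-conservation bound $\sum_g C_g \le N$ is deliberately
relaxed.

RPKM uses the annotating protein's coding length, $L = 3 \times$ amino-acid
length (stop codon excluded — the catalog records the mature protein), since
no exon models exist. The library size $N$ is the total read count of the
sample over **all** contigs, annotated or not, so the normalization reflects
true sequencing depth rather than annotation coverage. Written tables report
RPKM\(\times\)1000 at two decimals, the conventional reporting scale for
these experiments.

## The exact test

Counts are modeled as $Y_i \sim \mathrm{NB}(\mu_i, \phi)$ with
$\mu_i = M_i p_i$ and $\mathrm{Var}(Y) = \mu + \phi\mu^2$; $\phi = 0$
recovers the Poisson. Testing $p_1 = p_2$ conditions on the total
$n = y_1 + y_2$: the conditional law of $Y_1$ is obtained by normalizing
$f(k;\, M_1\hat p, \phi)\, f(n-k;\, M_2\hat p, \phi)$ over $k = 0..n$, with
the pooled abundance $\hat p = n / (M_1 + M_2)$. The two-sided p-value sums
conditional probabilities of all outcomes **no more likely** than the
observed one (minimum-likelihood rule). Numerical choices:

* probabilities are computed in log space and normalized after subtracting
  the maximum, so extreme counts cannot underflow;
* "no more likely" uses a relative tolerance of $10^{-10}$ so
  floating-point noise cannot split exact ties;
* a zero total carries no information and returns $p = 1$ by convention;
* for volcano plots only, p-values are floored at $10^{-300}$ before taking
  $-\log_{10}$.

At $\phi = 0$ the conditional law is exactly
$\mathrm{Binomial}(n, M_1/(M_1+M_2))$, and the test suite holds the
implementation to that reduction within $10^{-12}$ over an exhaustive grid.
A doubled-smaller-tail rule is available (`two_sided = "double"`) but the
minimum-likelihood rule is the default because it is the one under which the
binomial reduction is the classic exact test.

**Dispersion is a parameter, not an estimate.** With one library per
condition, $\phi$ cannot be estimated from the data; empirical-Bayes
moderation across genes would likewise have nothing to shrink toward.
The package therefore uses a fixed common dispersion, default
$\phi = 0.1$ — moderate overdispersion typical of bulk count data — and
reports it in every run summary. Users should treat DE counts as a function
of $\phi$ and, if in doubt, report results at several values.

**Significance is by raw p-value** at $\alpha = 0.01$, mirroring the
convention of replicate-free catalog studies; a Benjamini–Hochberg column is
emitted alongside but does not drive the flag. The log fold change uses a
pseudocount of 0.5 in both samples so tissue-exclusive genes remain finite.

## Cluster labels

Significant unigenes are split by the tissue with higher RPKM (equivalently,
higher count/library ratio) into sides A and B, and within a side by
exclusivity: label 2 (A2/B2) means the **raw deduplicated count** in the
other tissue is exactly zero, label 1 means enriched but detected in both.
Exclusivity deliberately uses the count, not an RPKM epsilon: a zero RPKM
occurs if and only if the count is zero, so printed RPKM tables can be
re-classified exactly. A significant gene with identical RPKM in both
samples is impossible under the exact-test rule and raises an error — it
indicates corrupted input rather than a boundary case. The Venn partition
reads off the labels: tissue-only DEGs are A2/B2, shared DEGs A1 + B1.

TF-family classification is keyword matching of annotation descriptions
against an editable lexicon of 20 plant TF families (first match in strict
priority order; equal priorities are rejected at load time because their
overlap would make results order-dependent). This is a documented stand-in
for curated TF databases, which a reference-free project typically lacks.

## GO-slim rollup

A slim is a curated subset of ontology terms. The package translates each
annotated term to **all** slim terms reachable upward along is_a and part_of
edges (ancestors-or-self); `nearest_only = TRUE` restricts to the closest
slim level. All-ancestors is the default because it is monotone (enlarging
the slim set never loses information) and independent of path lengths, which
are artifacts of ontology granularity. Other relation types are ignored:
regulatory edges do not express subsumption, and traversing them would count
a regulator as an instance of what it regulates. Term frequencies are
deduplicated per gene per term — a gene with two annotations rolling up to
the same slim term counts once.

## What the generator emulates — and what it does not

`simulate_dataset()` draws, per gene: 1–3 isotigs sharing contigs within the
gene; NB gene-level counts $Y_{gi} \sim \mathrm{NB}(M_i p_{gi}, \phi)$ split
multinomially across contigs by length; one sub-threshold annotation hit per
isotig plus decoy hits above the threshold; and GO/EC/TF labels from
built-in vocabularies. Abundances are log-normal weights normalized per
sample, so the manifest's `true_logFC` is the *realized* $\log_2(p_1/p_2)$
after normalization (exactly 0 for null genes, $\pm\infty$ for exclusive
ones). Default conditions — 200 genes, two libraries of $10^5$ reads,
$\phi = 0.1$, 20% DE at $|\log_2\mathrm{FC}| = 2$, a quarter of DE genes
exclusive, 10% decoy-hit rate — are the study design the package targets: a
small, deep, two-tissue catalog experiment.

Counts are drawn by quantile inversion from per-gene uniforms, and every
gene has its own seeded substream consumed in a documented order; enlarging
`n_genes` therefore never reshuffles earlier genes, and increasing the
effect size moves each gene's counts monotonically.

Deliberately **not** modeled: sequence content and read errors (homopolymer
noise, chimeras), assembly mistakes (mis-joined contigs, fragmented genes),
annotation ambiguity beyond decoys (paralog cross-hits below threshold), and
cross-gene contig sharing unless enabled. Passing tests on synthetic data
therefore demonstrate the correctness of the *computation* — counting,
normalization, testing, classification, rollup — under the stated model,
not robustness to assembly or annotation artifacts in real data.

## Problem sizes and measurement choices in the test suite

The suite verifies the binomial reduction exhaustively for totals up to 50
at three library ratios; type-I control on 10,000 null Poisson genes at
expected count 50; and recovery on the default conditions at library sizes
$10^3$–$10^5$. Because a single 200-gene dataset contains only ~30 DE genes
with finite truth and the per-gene log-fold-change noise at $\phi = 0.1$ has
a standard deviation near 0.65 (in log2), the bias of the estimator is
measured pooled across eight replicate datasets at identical conditions —
a smaller Monte-Carlo error for the same estimand, not a change of
conditions. The dispersion check at $\phi = 0$ uses the statistic
$\sum(Y_1 - Y_2)^2 / \sum(Y_1 + Y_2)$, whose expectation is 1 under
equal-mean Poisson pairs, with a band of four empirical standard errors.

## Known limitations

* One library per condition: $\phi$ is assumed, not estimated, and all
  inference is conditional on that choice.
* Unigene identity is only as good as the best-hit annotation; paralogs
  collapsing onto one reference protein inflate unigene counts.
* Protein-length RPKM mis-scales genes whose transcripts differ greatly
  from 3× protein length (long UTRs, partial hits).
* Raw-p significance at 0.01 controls no family-wise or false-discovery
  rate; the BH column is provided for readers who want one.
* The TF lexicon is keyword-based and will miss families absent from
  descriptions, and the shipped EC→pathway map is a seed table meant to be
  replaced by a project-specific export.
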