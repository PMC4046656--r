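Package: estprofiler
Title: De Novo EST Transcriptome Profiling with Annotation-Defined Unigenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative expression profiling for de novo (reference-free)
    transcriptome projects in which assembled isoforms are annotated against a
    reference-protein catalog and collapsed into unigenes. Implements
    shared-contig read deduplication, protein-length RPKM normalization, a
    two-sample negative-binomial conditional exact test for designs without
    replicates, enriched/exclusive expression-cluster classification with Venn
    partitioning, GO term-frequency profiling with GO-slim rollup over an
    ontology DAG, EC-to-pathway enzyme counting, and transcription-factor
    family classification from an editable keyword lexicon. A seeded synthetic
    dataset generator with a truth manifest makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
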