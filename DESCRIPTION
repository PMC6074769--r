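Package: toxtriage
Title: Toxin Candidate Triage for Venom Gland Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies and characterizes toxin gene candidates in assembled
    venom gland transcriptomes. Starting from a transcriptome, a per-transcript
    expression table, and a tabular homology search of curated toxin proteins
    against the transcriptome, the pipeline groups candidate transcripts into
    toxin groups keyed by the query protein names, predicts open reading
    frames in all six frames, screens candidates with a reciprocal
    toxin-versus-non-toxin E-value rule, splits precursors into signal and
    mature peptides, aligns each group's proteins, builds neighbor-joining
    gene trees, and reports expression across tissues. A deterministic
    synthetic-data generator produces all pipeline inputs with planted ground
    truth so every stage is testable without external downloads or binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    withr,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
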