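Package: pfssnv
Title: Mapping and Prioritization of Single-Nucleotide Variants on Protein
    Functional Sites
Version: 0.1.0
Authors@R: person("pfssnv", "maintainers", email = "devnull@example.org",
    role = c("aut", "cre"))
Description: Joins protein-coordinate somatic and germline single-nucleotide
    variants (SNVs) to annotated post-translational modification, active and
    binding sites and their +/-20 residue neighborhoods; calls loss/retained/
    gain effects using per-modification amino-acid tolerance rules and the
    N-glycosylation N-X(not P)-[S/T] sequon; computes neighborhood fold-change
    profiles with a one-sample t-test, amino-acid-background binomial
    enrichment, patient-level per-cancer binomial enrichment with Bonferroni
    control, pan-cancer observed/expected fold-change matrices with
    deterministic hierarchical clustering, and a two-criterion prioritization
    of key functional-site SNVs. Includes a seeded synthetic-data generator
    (proteome, site table, SNV/patient table) with plantable depletion and
    enrichment effects for end-to-end testing without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
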