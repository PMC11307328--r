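Package: crisprmemory
Title: Longitudinal Dynamics of CRISPR Immune Memory in Gut Metagenomes
Version: 0.1.0
Authors@R: person("crisprmemory", "maintainers",
    email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct and analyse the longitudinal interplay
    between CRISPR-Cas immune memory and mobile genetic elements (MGE) in
    time-series gut metagenomes. The package clusters assembled CRISPR
    arrays into within-host lineages by a strict nesting criterion, matches
    spacers to protospacers in MGE references and local contigs with
    identity/coverage thresholds, classifies spacer targets (lytic or
    non-lysogenic phage, lysogenic phage, plasmid, other MGE), quantifies
    positional bias of locally adapted spacers along oriented arrays,
    measures the effect of spacer acquisition on target abundance and
    prevalence with bootstrap and exact confidence intervals, and clusters
    spacer-target-lineage trajectories encoded as state strings via global
    alignment and network community detection. A synthetic community
    generator with planted ground truth (heavy-tailed array sizes,
    leader-end spacer gain, immunity effects, detection dropout and
    assembly truncation) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
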