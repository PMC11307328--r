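.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", "abundance", "accuracy", "array_id", "base_class", "class",
  "cluster_id", "contig_id", "coverage", "crass_like", "direct", "end",
  "identity", "infant_gut", "integrase", "lineage_id", "mge_id",
  "mismatches", "n_hits", "present", "proto_id", "reason", "sample",
  "spacer_id", "spacer_seq", "start", "strand", "subject", "subject_id",
  "subtype", "target_id", "timepoint", "weight"
))
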