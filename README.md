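# crisprmemory

Longitudinal analysis of CRISPR-Cas immune memory and mobile genetic
elements (MGE) in time-series gut metagenomes.

Microbial hosts record encounters with phages, plasmids and other MGE as
*spacers* in CRISPR arrays, added at the leader end in order of
acquisition. In densely sampled gut metagenomes this record can be read
longitudinally: arrays assembled from the same individual at different
times can be grouped into *lineages*, spacers can be matched to the MGE
they target (*protospacers*), and the abundance of a target can be
compared before and after its cognate spacer first appears. This package
implements that analysis chain for people studying virus–host dynamics in
longitudinal microbiome cohorts, together with a fully synthetic
community generator with planted ground truth for validation.

## What it computes

- **Lineages by strict nesting.** Array *a* is nested in array *b* when
  both share the same or highly similar repeats (> 90% identity and
  coverage) and every spacer of *a* (strand-insensitive) is carried by
  *b*. Representatives are arrays not nested in any other;
  each lineage is a representative plus everything nested within it.
- **Protospacer matching.** Ungapped both-strand scanning of spacers
  against MGE references and same-subject contigs at ≥ 95% identity and
  coverage (hits tiered *identical* vs *highly similar*), with
  CRISPR-region masking (100 bp repeat margin) and promiscuous-spacer
  removal. Spacers with a surviving hit in their own subject's contigs
  are *locally adapted*.
- **Target classes.** Strict consensus over annotated hits:
  lytic/non-lysogenic phage, lysogenic phage (integrase-bearing),
  plasmid, other MGE, *ambiguous* on conflict, *unknown* otherwise; a
  15 kb neighborhood homology search (0.9 bitscore-ratio rule) rescues
  locally adapted unknowns.
- **Positional bias.** Sliding-window density (window 12% of array
  length, step 1.5%) of any spacer flag along oriented arrays, plus
  leading/middle/distal enrichment with exact Clopper–Pearson intervals.
- **Immunity dynamics.** Acquisition episodes (spacer first seen after
  its lineage, present in ≥ 2 samples), phases
  before / acquisition / after-with-spacer / after-no-spacer,
  max-normalized target abundance with bootstrap CIs for the median,
  prevalence with exact CIs, Mann–Whitney and Fisher tests, and an
  active/inactive lineage-diversity and selective-sweep analysis.
- **Trajectory clusters.** Each episode encoded as a state string over
  six letters (presence/absence of lineage, spacer, target; empty states
  trimmed and collapsed), all pairs globally aligned with affine gaps
  (match 1, mismatch −2, gap open −2, gap extend −1), scores normalized
  by the longer string, and the resulting similarity network clustered
  with two-level Infomap (best of 200 trials).
- **Synthetic communities.** Truncated power-law array sizes
  (P(k) ∝ k^−α e^(−k/λ), α = 2, λ = 100 by default), leader-end spacer
  gain from a planted MGE pool (half the protospacers
  reverse-complemented), a multiplicative immunity effect on target
  abundance (default 0.3×), detection dropout and terminal truncation of
  observed arrays — all with a queryable truth object.

## Worked example

```r
library(crisprmemory)

params <- crispr_params(rng_seed = 42L, n_bootstraps = 500L)
res <- run_pipeline("all", params = params,
                    sim_cfg = sim_config(rng_seed = 42L), verbose = TRUE)
#> simulate: 238 observed arrays, 90 acquisitions
#> lineages: 38 lineages over 238 arrays
#> targets: 212 spacers classified, 1678 local hits
#> positions: 0 eligible arrays
#> dynamics: 122 episodes
#> trajectories: 122 strings, 16 clusters

res$dynamics$phase_stats$summary
#>                phase   n median ci_lo ci_hi prevalence
#> 1             before 402  0.423 0.408 0.462      0.918
#> 2        acquisition 122  1.000 1.000 1.000      0.992
#> 3  after_with_spacer 498  0.121 0.110 0.128      0.711
#> 4    after_no_spacer  30  0.164 0.129 0.223      0.933
```

Reading the output: acquisitions coincide with the target's abundance
peak (median normalized abundance 1.0 — spacers are picked up when their
target blooms); once the spacer is present, the target's median
normalized abundance drops from 0.423 to 0.121 — a ratio of ~0.29,
recovering the planted immunity multiplier of 0.3 — and its prevalence
falls from 92% to 71%. The Mann–Whitney p-value for before vs
after-with-spacer in this run is 1.2e-81. With this small default
community no array subtype reaches the 25-oriented-arrays eligibility
bar, so the positional stage reports zero eligible arrays (the
positional operators are exercised directly in the test suite).

The same pipeline runs from the command line:

```sh
Rscript inst/cli/crispr-memory.R all --out out_dir --seed 42
Rscript inst/cli/crispr-memory.R lineages --in out_dir/dataset --out out2
```

## Layout

- `R/` — parameters/IO, synthetic generator, matcher, lineage
  clustering, target classification, positional analysis, immunity
  dynamics, trajectory clustering, pipeline orchestration.
- `vignettes/crispr-memory-methods.Rmd` — model, assumptions, parameter
  choices, numerical decisions, limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (exhaustive scans, enumeration, CDF inversion).
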