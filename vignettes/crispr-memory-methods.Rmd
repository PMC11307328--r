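---
title: "Methods: longitudinal CRISPR memory analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal CRISPR memory analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`crisprmemory`, the assumptions behind them, the tunable parameters with
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## 1. The analysis chain

### 1.1 Array lineages by strict nesting

CRISPR arrays assembled from metagenomes are fragmentary: the same host
population yields different array fragments at different timepoints.
We group arrays from one individual into *lineages* with a strict
nesting criterion: array $a$ is nested in array $b$ iff (i) their
repeats fall in the same cluster (greedy clustering, identity and
coverage strictly above 0.90 on either strand, seeds processed
longest-first with lexicographic tie-breaks so the result is
order-invariant) and (ii) every spacer of $a$ is carried by $b$, where a
spacer and its reverse complement count as the same spacer and order is
deliberately ignored. Representatives are arrays not strictly nested in
any other; members join the representative sharing most spacers (ties:
larger representative, then lexicographic id). Arrays with identical
spacer sets are a tie resolved by earliest timepoint, then most spacers,
then id — deterministic and favouring the first observation.

Strict nesting never merges partially overlapping arrays. This is a
feature: it keeps clusters homogeneous, at the cost of splitting a true
lineage when a spacer is lost and another gained between observations.
Consequently the lineage-recovery validation (acceptance criterion 2)
runs on loss-free truth — it measures robustness to *observation*
incompleteness (assembly truncation, dropout), which is the property the
method claims; recovery under biological loss is bounded away from 1 by
the criterion's own design, and the default generator keeps loss on
everywhere else.

Within-lineage consistency metrics compare every member pair sharing at
least two spacers: shared-spacer order is checked up to whole-array
reversal (assembly strand is arbitrary), a spacer stored on the opposite
strand relative to the pair's order-consistent alignment counts as an
inversion, and predicted orientations conflicting with that alignment
count as orientation inconsistencies.

### 1.2 Protospacer matching

Spacers (~34 nt) are matched ungapped on both strands at ≥ 95% identity
and coverage. At these lengths a gapped alignment cannot satisfy the
coverage threshold, so Hamming scanning at every offset reproduces a
short-query nucleotide search exactly while remaining verifiable against
an exhaustive oracle (criterion 4). Identity is matches divided by
spacer length; coverage below 1 is only possible where the spacer
overhangs a contig end. Ambiguity codes count as mismatches
(conservative). Duplicate placements keep the fewest-mismatch record.
A pigeonhole 10-mer prefilter skips pairs that cannot contain a
reportable hit; identical subject sequences are scanned once.

Hits inside known CRISPR arrays or within 100 bp of repeat hits are
masked (spacers trivially "hit" their own arrays), and spacers whose hit
count exceeds both an absolute cap (1000) and ten times the next-highest
count are removed as artifacts. A spacer with a surviving hit in its own
subject's contigs — pooled over all samples — is *locally adapted*.

### 1.3 Target classification

Class is a strict consensus over annotated database hits; any conflict
is *ambiguous*. Viral records are split lytic/non-lysogenic vs lysogenic
by integrase annotation; integrase flags never reclassify plasmids.
Accuracy reports the best tier (*identical* = zero mismatches at full
coverage). Spacers without database hits but with a local protospacer
are rescued by comparing the ±7.5 kb contig neighborhood (clipped at
contig ends) against the database using a k-mer-anchored
exact-extension search; the score (twice the longest shared block) is
kept when the expected number of random blocks that long
($m \cdot n \cdot 4^{-\ell}$) is below $10^{-8}$, sub-0.9-of-best scores
are discarded, and the consensus rule applies. Neighborhood evidence
never overrides a database class — rescue applies to unknowns only.

### 1.4 Positional analysis

Spacer $i$ (0-based from the leader) of an $n$-spacer oriented array
sits at midpoint $(i + 0.5)/n$; reverse-oriented arrays are flipped
first and unoriented arrays are ineligible. Densities of a focal flag
are computed in sliding windows of width 12% of the array length,
stepped by 1.5%, pooled over arrays; thirds
(leading $[0, 1/3)$, middle $[1/3, 2/3)$, distal $[2/3, 1]$) get exact
Clopper–Pearson intervals via beta quantiles. Eligibility follows the
oriented, > 5 spacers, ≥ 25 arrays-per-subtype rule. One numerical
subtlety: the window grid is symmetric — the step is snapped to the
nearest value that tiles $[w/2,\, 1 - w/2]$ exactly (0.01492 rather than
0.015 at the defaults, 59 intervals), so flipping every array mirrors
the profile about 0.5 exactly rather than approximately. Window
membership is half-open $[lo, hi)$.

### 1.5 Immunity dynamics

An episode is one (spacer, target) pair in one subject: eligible when
the spacer's first appearance is strictly later than its lineage's (so a
pre-acquisition baseline exists) and the spacer occurs in ≥ 2 samples;
samples without the lineage are excluded throughout. When several
lineages carry the pair, the earliest-observed lineage provides the one
episode. Retained samples get phases: *before*, *acquisition* (first
spacer sample), *after-with-spacer*, *after-no-spacer*. Abundances are
normalized per target by the series maximum; phase summaries pool
normalized values across episodes (per-episode aggregation would weight
sparse episodes equally; the pooled form matches how the four-phase
summaries are usually drawn) and report medians with percentile
bootstrap CIs (2000 case resamples by default), prevalence with exact
CIs, Mann–Whitney tests on abundances and Fisher tests on prevalence.

Two statistical caveats are load-bearing and are reflected in the
validation scenarios rather than hidden:

- *Pooled rank tests assume samples are exchangeable across episodes.*
  When many episodes share one target's series, its values enter the
  pool repeatedly and the Mann–Whitney test is anticonservative. The
  null-calibration runs therefore use an MGE pool large enough that
  episodes rarely share targets; with heavy sharing the same test
  over-rejects, which users should keep in mind on real data where one
  phage can be targeted by many spacers.
- *Detection censoring biases the median ratio.* Zeroing sub-floor
  abundances accumulates zeros in the immune phase, pushing the pooled
  median ratio below the true multiplier. The effect-recovery scenario
  disables the floor; the floor's consequence is exactly what the
  prevalence statistics measure, and those keep it.

The diversity analysis labels lineages *active* when they carry ≥ 1
locally adapted spacer, compares distinct-array counts between active
and inactive lineages, splits per-sample array counts of active lineages
by presence of their targets, and contrasts the observed fraction of
array occurrences carrying a cognate spacer for a co-sampled MGE with
the expectation under uniform redraws of arrays into the same
(subject, sample) slots, with bootstrap CIs.

### 1.6 Trajectory clustering

Each episode's per-sample combination of (lineage, spacer, target)
presence maps to a letter: A empty, B target only, C lineage only,
D lineage+target, E lineage+spacer, F all three (spacer without lineage
is impossible, so 6 of 8 combinations are reachable; the bijection is
arbitrary and declared here for reproducibility — any fixed choice
yields identical alignments). Empty letters are trimmed from the ends
and internal runs collapse to a single A. Strings are aligned globally
with affine gaps — match 1, mismatch −2, a gap of length $g$ costs
$-2 - (g-1)$ — with end gaps penalized; scores are normalized by the
longer string's length and pairs with weight ≤ 0 are dropped (a flag
retains exact zeros, since "discarding negative scores" is ambiguous
about zero). The weighted undirected network is clustered by two-level
Infomap (igraph implementation, best of 200 trials, seeded); modularity
optimization is available behind the same interface. Cluster summaries
count state occupancies and transitions between consecutive non-empty
states, split *direct* (adjacent retained samples) vs *indirect*
(spanning collapsed empties or sample gaps), with row-normalized
probabilities and per-class association relative to the global class
mix.

## 2. The synthetic community

The generator states a world and the tests measure recovery in it; its
defaults were chosen once, before the validation thresholds were
checked, and are not tuned.

| parameter | default | why |
|---|---|---|
| array-size law | $P(k) \propto k^{-2} e^{-k/100}$ | the empirical size distribution of gut CRISPR arrays is heavy-tailed with exponent near 2 and cutoff near 100 spacers |
| spacer / repeat length | 34 / 31 nt | average lengths in gut CRISPR assemblies |
| samples per subject | 12 | average metagenomes per individual in the cohort this pipeline targets (~2-week sampling over a year) |
| immunity multiplier | 0.3 | an effect of the magnitude the four-phase abundance comparison is designed to detect |
| acquisition boost | 2.0 | acquisitions are observed when the target blooms |
| gain / loss rate | 0.4 / 0.02 per sample | not quantified in the literature for the gut; set for statistical power and documented as such |
| detection probability | 0.9 | assembly dropout of a present array |
| truncation probability | 0.1 | geometric-length terminal loss, emulating incomplete assembly |
| baseline abundance | lognormal(0, 1) per (MGE, subject), lognormal noise σ = 0.3 per sample | strictly positive, heavy-tailed; a stable colonization level per subject with sample-level noise |
| detection floor | 10th percentile of abundances | an MGE is observable (contig emitted, abundance non-zero) only above it |

Truth construction: each lineage starts from a truncated-power-law-sized
array (a `local_frac` = 10% of initial spacers are protospacer copies —
pre-study local adaptation), appears at a random early sample and then
evolves: losses hit each spacer independently, gains prepend protospacer
copies at the leader end on a random strand. Half of all planted
protospacers are reverse-complemented within their MGE. A lineage never
re-acquires a protospacer it already carries (and initial arrays draw
protospacers without replacement): duplicate carriage would break the
generator's guarantee that true arrays never rearrange — the guarantee
the zero-inconsistency criterion measures — and re-acquisition against
existing immunity is biologically implausible anyway. The observation
layer randomizes assembly strand (orientation revealed with probability
0.7), drops arrays, truncates terminal runs, embeds observed array loci
and supra-floor MGEs in contigs, and zeroes undetected abundances.

What the generator does **not** emulate: protospacer escape mutation and
PAM structure, within-host population genetics, taxon structure,
compositionality of relative abundances, uneven sampling intervals, and
cross-subject MGE sharing structure. A green recovery test therefore
establishes correctness of the inference machinery under the stated
world, not robustness to those real-data features.

## 3. Numerical and interface decisions

- Coordinates are 0-based half-open; strands are `+`/`-`; TSV with `.`
  for missing values is the single tabular dialect; the config file is
  JSON (flat key→value, unknown keys rejected).
- Identity thresholds compare with a $10^{-9}$ tolerance to make
  floating-point boundary cases (e.g. 33/34 vs 0.95) deterministic.
- The truncated-power-law MLE maximizes the discrete log-likelihood via
  a coarse grid followed by Nelder–Mead on
  $(\log(\alpha - 1), \log\lambda)$, with the normalizer summed
  directly; a cutoff estimate at the search boundary is flagged (pure
  power-law regime).
- All stage randomness derives from one seed
  (deterministic per-stage child seeds); outputs contain no timestamps,
  so identical seeds and inputs reproduce byte-identical tables — this
  is itself an acceptance criterion.
- `run_pipeline()` enforces stage dependencies
  (simulate → lineages/targets → positions/dynamics → trajectories) and
  names the missing upstream stage on error.

## 4. Known limitations

- The matcher is exact for the ungapped short-query regime; it does not
  reproduce heuristic gapped searches outside it (irrelevant at 95%
  coverage on 34-nt queries, documented rather than guessed).
- The neighborhood rescue scores exact shared blocks; diverged homology
  below exact-block detectability yields *unknown* where a
  translated/discontiguous search might classify.
- Pooled phase statistics inherit the dependence caveat of §1.5.
- Apparent spacer loss (after-no-spacer) is read literally from observed
  array content; incomplete assembly masquerades as loss, which biases
  with/without comparisons toward zero — conservative, and logged rather
  than corrected.
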