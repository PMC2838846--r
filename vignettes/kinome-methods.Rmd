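---
title: "Methods: kinome identification, classification and comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinome identification, classification and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the scoring conventions, the
parameter defaults and the design decisions behind `kinomeprofiler`. Code
chunks are illustrative and not evaluated at build time.

## 1. The profile HMM

A `profile_hmm` with `L` match states consists of:

- `match_emissions`: an `L × 20` row-stochastic matrix over the standard
  amino-acid alphabet (alphabetical order, `ACDEFGHIKLMNPQRSTVWY`);
- `insert_emissions`: an `(L+1) × 20` matrix for insert states
  `I_0 … I_L` (`I_0` precedes the first match state; `I_L` is carried for
  structural completeness but is unreachable in the scoring modes below);
- `transitions`: an `(L+1) × 7` matrix with columns
  `MM MI MD IM II DM DD`, where row `r` holds the transitions *out of node
  `r − 1`* (node 0 is Begin, so row 1 holds Begin→M₁/I₀/D₁; in the final
  row `MM` and `DM` are the exits M_L→End and D_L→End, and `MD`/`DD` are
  structurally zero);
- `null_model`: a background residue distribution (uniform by default).

All scores are **log2-odds bit scores** against the null model: a score of
0 means "no more likely under the model than under the background", and
each additional bit doubles the odds. The unknown-residue wildcard `X`
(input is normalized so that `B Z U O J .` and any other non-standard
characters become `X`) is scored with zero log-odds everywhere, i.e. it
neither helps nor hurts.

Two alignment modes are supported:

- **glocal** (`mode = "glocal"`): the whole sequence must be generated by
  the model, entering at node 0 and leaving from node `L`. A model whose
  emissions all equal the null scores exactly 0 bits on any sequence.
- **local** (`mode = "local"`, the default for search): a *fragment* of
  the sequence is aligned to a *fragment* of the model. Entry and exit are
  restricted to match states, with the uniform fragment prior used by
  standard profile-HMM search software: every (start node, end node) pair
  is equally likely, contributing a constant entry cost of
  `log2(2 / (L (L + 1)))` bits. Residues outside the fragment are scored
  by the null model, i.e. they contribute exactly 0 bits, so a local score
  is invariant to the flanking sequence (up to the possibility that a
  flank hosts a better fragment).

Both Viterbi (best path) and forward (path sum) scores are available; the
classifier and domain scanner use Viterbi. The dynamic programming kernels
are in C++ (Rcpp) and work entirely in log space — log-sum-exp for
forward — so scores remain finite for sequences of tens of thousands of
residues. Their correctness is pinned in the test suite against a
brute-force enumeration of *all* alignment paths for small models
(`L ≤ 3`, sequences up to length 5), with agreement required to 1e-6 bits.

`build_from_alignment` estimates a model from an aligned block of
sequences: columns with a gap fraction strictly below `match_column_rule`
(default 0.5) become match states, all counts receive a pseudocount
(default 1, Laplace), and the null model is either uniform or the
alignment's residue composition. `read_hmmer3` imports HMMER3 ASCII model
files (negative-log probabilities, `*` = impossible), renormalizing each
distribution block; imported models carry any non-fatal issues in an
`import_warnings` attribute.

## 2. Kinase classification

`extract_kinome` scores every protein against every model of a
`group_library` (local Viterbi), reduces to one score per kinase group by
maximum, and applies the fixed-cutoff / maximum-score rule:

> call the arg-max group iff the best score is **strictly greater** than
> the cutoff (default **20 bits**).

The 20-bit default follows the `log2(n)` rule of thumb for a database of
roughly a million sequences (`recommend_cutoff(2^20) == 20`); the strict
inequality makes the boundary case deterministic. Ties between groups at
the exact same best score are broken toward the smallest group name in the
fixed canonical order (`KINASE_GROUPS`), never by hash or locale order.
There is deliberately **no "Others" category**: a protein that clears the
cutoff is assigned to the best group, everything else is a no-call.

All twelve canonical groups appear in every report, including structural
zeros — a clade systematically lacking, say, RGC kinases is itself a
finding, not missing data.

## 3. Domain annotation

`scan_domains` runs each called kinase against a domain HMM library in
local mode with the same strict 20-bit default threshold. Because one
protein may carry several copies of one domain, each accepted hit's
envelope (the matched fragment, with 1-based inclusive coordinates
recovered from the Viterbi traceback) is masked to `X` and the sequence is
rescanned until the model's score drops to the threshold. Hits from
different models are then reconciled: when two envelopes on one protein
overlap by more than half of the shorter envelope, only the
higher-scoring hit survives (ties broken by name, then position). Hits are
flagged catalytic when the model name is one of the seven
`CATALYTIC_DOMAINS`; everything else is accessory.

Summaries (`summarize_domains`) report raw counts and unrounded means plus
1-decimal display values, the number of distinct types by catalytic
status, and the singleton types (exactly one occurrence corpus-wide).

## 4. Comparative statistics

- **Kinome density** = `100 × kinases / proteome size` (percent). It
  normalizes kinome size for genomes of very different sizes.
- **Normalized frequency** = `100 × group count / total kinases`.
- **Density comparison**: `wilcoxon_rank_sum` is a thin wrapper around
  `stats::wilcox.test` (two-sided, unpaired) with an explicit method
  switch — the exact distribution when the pooled data are untied and both
  samples have at most `exact_limit = 25` observations, otherwise the
  normal approximation with tie-corrected variance and continuity
  correction. We deliberately call the base-R implementation rather than
  re-deriving it — it is the field's standard routine — and the wrapper is
  pinned against a full-enumeration oracle in the tests.
  One edge case is patched: when every observation is tied the statistic
  has zero variance and `wilcox.test` returns `NaN`; such data carry no
  evidence of a shift, so the p-value is reported as 1.

## 5. Domain-frequency PCA

`build_frequency_matrix` forms
`cell(s, d) = 100 × count of domain d in species s / total domain
occurrences in species s`. Two conventions matter:

- **Denominator**: the species' *total* domain occurrences, computed
  *before* the prevalence filter, so each row describes the species' full
  domain budget and rows need not sum to 100 after filtering.
- **Prevalence filter**: only domain types present in *at least half* of
  the species are retained (threshold 0.5, boundary inclusive: a domain in
  exactly half the species stays). Rare domains are informative singly but
  dominate a covariance decomposition as noise.

`pca_domains` delegates the decomposition to `stats::prcomp` (SVD-based;
centered, unscaled by default — the cells share one unit, percent, so
variance weighting is meaningful) and then applies a deterministic sign
convention: each component is flipped, if necessary, so its
largest-magnitude loading is positive. This removes the backend-dependent
sign ambiguity of eigenvectors and makes reports byte-reproducible across
platforms. `project3` returns the first three components per species with
clade labels, padding with zero columns (flagged) when fewer than three
components exist.

Because cluster quality in a 3-D plot is otherwise a visual judgement, the
package adds a numeric surrogate, `cluster_separation`: a silhouette-style
mean of `(b − a) / max(a, b)` per species, where `a` is the mean distance
to the species' own clade and `b` the smallest mean distance to another
clade; values near 1 mean clean separation, near 0 no structure.

## 6. Synthetic fixtures

The generator builds study material whose ground truth is known exactly:

- **Toy models** place weight `w = (19 d + 1) / 20` on a consensus residue
  and spread the rest uniformly, so two models with different consensus
  residues at a column are exactly `d` apart in total variation
  (default divergence `d = 0.9`). Group models (length 40) get mutually
  distinct consensus residues at every column; domain models (length 30)
  draw consensus independently (~5% expected pairwise identity).
- **Proteomes** (`sample_proteome`) embed match-state samples of group
  models in i.i.d. null flanks, alongside pure-null background sequences.
- **Cohorts** (`make_cohort`, `default_cohort_design`) plant a two-clade
  structure: 8 species per clade; kinase counts drawn so kinome density is
  ~0.5% (CladeA) vs ~1.2% (CladeB), SD 0.1, around 2000 background
  proteins; a shared, skewed group profile (CAMK/CMGC-heavy, RGC absent);
  a Pkinase-dominated catalytic profile; clade-specific accessory
  profiles 0.6 apart in total variation over 14 common accessory types; a
  Poisson(2) number of accessory domains per kinase. 21 core domain types
  are guaranteed present in every species while 19 rare types are planted
  in exactly 3 species each, so exactly 21 of the 40 types survive the
  half-prevalence filter — the filter's behavior is part of the planted
  truth.

What the generator *emulates*: group-specific sequence signal on a null
background, density differences between clades, domain architectures with
clade-specific accessory usage, rare-domain sparsity. What it does *not*
emulate: real amino-acid composition, indel structure inside planted
segments (segments are pure match-state walks), homology between groups,
gene families, or proteome-scale sequence length distributions. The
default sizes (16 species, ~2000 proteins each, model lengths 40/30) are
this package's own choice: large enough for the planted effects to be
detectable end to end, small enough to run in minutes on one CPU —
real kinome studies are one to two orders of magnitude larger.

All generators run under an isolated RNG state (`same design + seed` ⇒
byte-identical output, without disturbing the caller's RNG). When creating
*independent* artifacts, use distinct seeds: two generators started from
the same seed consume the same random stream and can produce eerily
correlated output (e.g. a domain library whose consensus recurs inside a
proteome's flanks). `make_cohort` derives its internal seeds as
`seed`, `seed + 1`, `seed + 2` for the group library, domain library and
sequences for exactly this reason.

## 7. Reproducibility and numerical choices

- All scoring is in log2 space; forward uses log-sum-exp; no probability
  is ever multiplied in linear space.
- Reports print floating-point values with fixed decimal formatting
  (4 decimals for bit scores, 6 for derived statistics), so reruns are
  byte-identical; timestamps exist only in `run.log`.
- Group/column orderings are fixed explicitly (canonical group order,
  descending pooled count for PCA columns), never locale-dependent.
- The strict `>` cutoff convention is used everywhere a threshold appears.

## 8. Limitations

- The classifier assigns at most one group per protein; dual-domain
  kinases are represented only by their best-scoring group.
- The domain scanner's greedy overlap resolution is not a full
  probabilistic domain-architecture model (no clan-level grouping, no
  posterior envelopes).
- The Wilcoxon wrapper inherits `stats::wilcox.test`'s normal
  approximation for tied or large samples; exact p-values under ties are
  out of scope.
- `cluster_separation` is a test surrogate for a visual judgement, not a
  clustering method; it is reported, not thresholded, by the pipeline.
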