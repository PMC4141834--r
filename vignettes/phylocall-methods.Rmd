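---
title: "Methods: probe-level presence calling and community comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-level presence calling and community comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocall)
```

# The measurement model

High-density 16S rRNA phylogenetic microarrays interrogate each operational
taxonomic unit (OTU) with a set of probe pairs: a perfectly matching (PM)
25-mer and a mismatching (MM) 25-mer differing at the central base. A probe
set averages about 37 pairs per OTU (s.d. 9.6). When the OTU's amplicon is
present in the hybridization mix, PM probes bind it better than their MM
partners, so PM intensities rise above MM intensities across the set; when
it is absent, the two channels see only background and cross-hybridizing
material and PM beats MM about half the time. `phylocall` turns that
contrast into presence/absence calls, abundance proxies, and community
comparisons.

## Preprocessing

`preprocess_arrays()` works per replicate array:

1. **Background**: the 2nd percentile of all probe intensities on the array
   (PM and MM, controls included) is subtracted from every intensity. The
   2nd percentile is robust to the large fraction of responding probes on a
   rich community sample.
2. **Scaling**: intensities are rescaled so the mean background-subtracted
   spike-in (quantitative standard, probes prefixed `CTRL_SPK`) intensity
   equals `spikein_level` (default 1000 arbitrary units). This makes arrays
   comparable despite labelling/scanning gain differences.
3. **Floor**: intensities are floored at 1 unit, *after* scaling. Two
   reasons: the floor guarantees non-negative `log2` abundance weights for
   UniFrac, and applying it last makes the output exactly invariant to a
   common multiplicative factor on the raw intensities (double every raw
   intensity and the preprocessed array is unchanged).

## Probe-pair scores

For every scored pair, the response score is

$$d = \frac{PM - MM}{PM + MM} \in [-1, 1],$$

with $d = 0$ when the denominator vanishes. A pair is *positive* when PM is
strictly greater than MM — ties do not count, because the evidence of
response is a strictly higher PM.

The *ranked response score* $r \in [0, 1]$ asks how unusual $d$ is relative
to probes that should be seeing only background. Because duplex stability
depends strongly on base composition, the comparison is stratified by the
A+T count of the PM probe: bins of width 5 on the 0–25 scale (`bin_width`
tunable). Within the pair's bin, $r$ is the fraction of background-pool
pairs whose $d$ is *strictly* smaller. The background pool is array-specific
and label-free: all background control probes (`CTRL_BG`) plus the probes of
OTUs that are ineligible for stage 1 on this array (fewer than 7 positive
pairs); a probe shared with any eligible OTU stays out of the pool. Spike-in
standards are excluded — they respond by design and would bias the pool
toward responding pairs. An empty bin that is actually needed is an error
suggesting a wider `bin_width`; a bin with fewer than 50 pool pairs warns.

The exact ranked-score and cross-hybridization equations used by the
original chip software are not public; the forms above reproduce their
stated semantics (background-relative ranking stratified by A/T content, a
penalty for probes shared among closely related OTUs) with deterministic,
testable arithmetic.

## Two-stage presence calling

Stage 1 (per OTU, per array), all four criteria must hold
(`call_thresholds()`):

1. at least 7 probe pairs scored;
2. at least 7 positive pairs;
3. r-score quartiles at least (0.80, 0.93, 0.98);
4. positive fraction at least 0.92.

Quartiles are computed with linear interpolation between order statistics
(`stats::quantile` type 7), pinned for bit-reproducibility. All four
criterion flags are recorded; degenerate probe sets fail criteria rather
than raise errors. Note the criteria are not independent: criterion 2
implies criterion 1, and criteria 1 + 4 imply criterion 2 for integer pair
counts.

Stage 2 guards against cross-hybridization among closely related OTUs that
share probes. For each pair of a stage-1 passer, $rx = r / s$, where $s$
counts the stage-1-passing OTUs on the array whose probe sets contain that
probe ($s \ge 1$, so $rx \le r$ always). A *species* is called present when
the rx quartiles over the pooled pairs of its stage-1-passing OTUs meet
(0.22, 0.40, 0.42); an OTU is present when it passed stage 1 and its species
is present. Pooling at species level (rather than re-testing each OTU) was a
genuinely open choice; pooling is implemented because the stage-2 cutoffs
are defined for species-level calls and sub-species OTUs of one species
share most of their signal.

The trimmed-mean *hybridization score* — the mean PM intensity after
removing exactly one maximum and one minimum occurrence (not all tied
extremes, for determinism under ties) — is the OTU's abundance proxy.

## Consensus and roll-up

With triplicate arrays, an OTU is present in a sample when called on at
least 2 of 3 replicates (`consensus_min_replicates`). When low biomass
forces pooling the replicates onto a single array (`pooled = TRUE`), any
detection counts — the single-array rule trades specificity for coverage
and is reported as such. A taxon at any rank is present when at least one
present species lies in its lineage; `count_taxa()` reports per-rank
richness including the OTU level.

# Community comparison

`build_community_matrix()` keeps every OTU consensus-present in at least one
sample; columns are the individual replicate arrays (group comparisons
treat replicates as group members), and a cell holds the replicate's
hybridization score where that replicate called the OTU, else 0.

The transform chain is enforced by `kind` tags: *general relativization*
(each column divided by its total, exponent 1 — the standard default of the
method family) then *arcsine square root*, which brings bounded
intensity-derived proportions closer to the hybridized amplicon amounts.
Distances reject raw matrices. Heat-plot display uses row z-scores
(constant rows map to zero and are flagged, not errors, because display
semantics should not abort a run).

**Bray–Curtis** distances feed agglomerative clustering with either
group-average (UPGMA) or flexible-beta linkage (Lance–Williams with
$\alpha = (1-\beta)/2$, $\gamma = 0$, default $\beta = -0.25$, the
conventional value). Equal-distance merge candidates are resolved by taking
the earliest pair in index order, so dendrograms are deterministic.
`cut_dendrogram(level)` removes the top `level - 1` merges.

**MRPP** uses the weighted mean within-group distance
$\delta = \sum_g (n_g/N)\,\bar d_g$ (the common $C_g = n_g/N$ weighting;
the source method names a weight without fixing it). The null distribution
comes from permuting group labels: exhaustively when the number of distinct
arrangements is at most 10,000 (exact $p$ and expectation), otherwise Monte
Carlo with the add-one correction $p = (1 + \#\{\delta_\pi \le
\delta_{obs}\})/(1 + B)$, with $\delta_{exp}$ estimated from the same
permutation stream. $A = 1 - \delta_{obs}/\delta_{exp}$.

**Indicator species analysis** follows the Dufrêne–Legendre definition:
specificity $A_{ij}$ (mean abundance share across groups), fidelity
$B_{ij}$ (fraction of group members where the OTU is *called* present — the
calling procedure, not abundance > 0, decides fidelity), and
$INDVAL_{ij} = A_{ij} B_{ij} \times 100$. Abundance input is the
relativized (pre-arcsine) matrix by default. The per-OTU statistic is the
maximum over groups, with the same permutation scheme as MRPP (1,000 Monte
Carlo permutations by default). OTUs with zero total abundance get indicator
value 0 with a flag rather than NaN.

**Weighted UniFrac** uses $\log_2$ hybridization intensities as abundance
weights (amplicon amounts correlate with log-intensity on these chips),
0 for absent OTUs — never the log of a pseudo-intensity — normalized within
each sample *before* tree aggregation ("within-sample normalized weights").
The distance is $u = \sum_b l_b\,|p_A(b) - p_B(b)|$ over branches, divided
by $D = \sum_{leaf} depth(leaf)(p_A + p_B)$ so values live in $[0, 1]$; the
unnormalized branch sum is available behind `normalized = FALSE`. The
unnormalized sum is invariant to pruning leaves that carry no weight; the
normalized form additionally requires root-to-leaf depths to be unchanged.

**PCoA** Gower-centres $-d^2/2$ and eigendecomposes; coordinates are
eigenvectors scaled by $\sqrt{\lambda}$, axes ordered by eigenvalue,
percent variation shares taken over positive eigenvalues only, and each
axis' sign fixed so its first nonzero coordinate is positive (reproducible
plots).

# What the simulator emulates — and what it does not

`simulate_chip_experiment()` generates the complete study with recorded
ground truth:

- probe sets sized by a truncated Normal(37, 9.6) with a floor of 10 pairs;
  A+T counts uniform on 8–17 (no 25-mer sequences are generated — A+T is
  the only sequence property the scoring uses);
- a six-rank taxonomy with OTUs nested in species and a rooted phylogeny
  whose clades follow the taxonomy (binary root, uniform branch lengths);
- within multi-OTU species, 10% of probes are shared between sibling OTUs,
  which is what gives stage 2 something to discount;
- group-structured communities: a core present everywhere (40% of OTUs,
  shared lognormal baseline abundances), per-group $2^{effect}$ abundance
  shifts (default effect 2 on 20 OTUs per group), and per group 5 planted
  indicator OTUs with perfect fidelity and specificity;
- intensities: one background draw shared by the two probes of a pair
  (Normal(50, 10), truncated at 0), small per-channel multiplicative
  fluctuation (cv = `noise_sd`/10), multiplicative signal noise
  (`noise_sd`, default 0.2, also the replicate-level abundance jitter), a
  mismatch leak of 0.3, a gain of 100 intensity units per abundance unit,
  spike-ins at 1000, and 300 background controls;
- cross-hybridization: with probability 0.1 a probe also receives half the
  signal of the tree-nearest other present OTU — tree-targeted, because the
  confusions the stage-2 adjustment exists for are among close relatives.

The default design is 3 groups × 1 sample × 3 replicate arrays over 150
OTUs in 60 species — large enough to exercise every stage, small enough
that the full suite runs in well under a minute.

The simulator does **not** emulate: sequence-level hybridization physics
(probe-specific affinities, position-of-mismatch effects), spatial chip
artefacts, saturation, day/batch effects, or the heavy-tailed abundance
distributions of real activated-sludge communities. Passing recovery tests
therefore demonstrates the *procedure* is implemented correctly and is
well-calibrated under the stated noise model, not that any particular
sensitivity will be attained on field samples.

# Numerical choices

- Quartiles: `stats::quantile` type 7 everywhere.
- PM = MM ties are not positive; trimmed mean removes exactly one extreme
  occurrence each side.
- Permutation p-values use the add-one correction in Monte Carlo mode, the
  exact fraction in exhaustive mode; permutation results are
  bit-reproducible given (seed, n_permutations).
- Comparisons of permuted statistics use a 1e-12 slack so ties are counted
  as "as extreme".
- Dendrogram and eigenvector tie-breaks as described above.
- Degenerate inputs: fewer than 3 PM intensities makes the hybridization
  score undefined (an error when requested directly, NA in bulk call
  tables); zero-sum matrix columns, all-absent samples, single-sample
  clustering, and groups of size 1 in MRPP are errors naming the offender.

# Reproducibility

Every stochastic routine takes an explicit seed. The pipeline runner
records the seed in each statistical output and writes a manifest; two runs
with identical configuration and seed produce byte-identical result trees
(wall-clock timings live only in the in-memory manifest object for exactly
this reason). The test suite validates the distance, clustering, UniFrac
and PCoA implementations against independent brute-force oracles on ~100
random instances of up to 8 samples each, checks MRPP and INDVAL against
exhaustive permutation enumeration on 6-sample designs, and runs the full
default study end to end against the simulator's ground truth.

# Limitations

- The r/rx score forms are reconstructions of the published semantics, not
  the original (unpublished) equations; calls on real chip data will not be
  numerically identical to the vendor pipeline, though the criterion
  structure is the same.
- MRPP and INDVAL results from commercial packages may differ in weighting
  and permutation conventions; no equivalence on the original field data is
  claimed.
- The community matrix treats replicate arrays as columns. Designs with
  many biological samples per group are supported, but the package does not
  model replicate-within-sample nesting in the permutation schemes; labels
  are exchanged at the array level, matching the replicate-as-member usage.
- Intensities are treated as continuous abundances; no count model, no
  rarefaction.
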