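---
title: "correnet: methods and design notes"
author: "correnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{correnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(correnet)
```

This vignette documents the models and procedures implemented in
`correnet`, the assumptions behind them, the tunable parameters and their
defaults, and the design decisions taken where several reasonable choices
existed. It states no empirical result beyond what the package's own test
suite and acceptance script compute.

# Data model

A `FeatureTable` is a `SummarizedExperiment`: one row per detected LC–MS
feature with m/z (Da), retention time (min) and optional annotation in
`rowData`, one `"area"` assay column per sample, and the ionization
polarity in the metadata. Validity enforces unique feature ids, m/z > 0,
RT ≥ 0, non-negative areas and at least one positive area per feature.

Reading (`readFeatureTable()`, CSV/TSV/XLSX) rejects defective rows with
row-indexed diagnostics rather than failing the file; blank area cells are
read as 0, and duplicated (m/z, RT) rows are kept with a warning since they
may be genuine shoulder peaks. No transformation is applied on read:
log-transformation and outlier handling are deliberately left to the user,
whose experimental context decides them. Because the exact header layout of
feature lists varies by vendor, the column names are configurable arguments
with conventional defaults (`mz`, `rt`, `annotation`, remaining columns =
samples).

Throughout the package "the area" of a feature means its **maximum area
across samples**. The alternatives (mean, sum) down-weight metabolites
present in only a subset of conditions — which are often the biologically
decisive ones — so the maximum is used consistently for the minimum-area
filter, base-peak selection and the identification weights. The
minimum-area filter is inclusive (≥ threshold).

# Ion grouping

Ions of one metabolite co-elute and keep a fixed intensity ratio across
samples. `groupIons()` exploits both greedily: the remaining feature with
the largest area becomes a base peak and absorbs every remaining feature
within ±`rtShift` (default 0.02 min, two-sided, inclusive) whose
ratio RSD against it — `sd/mean` of the per-sample area ratios — is at most
`rsdMax` (default 0.25). The clique is removed and the procedure repeats,
which makes the output a partition by construction.

Numerical choices:

* The ratio is computed only over samples where the base area is positive;
  with fewer than 3 usable samples or a zero mean the RSD is undefined and
  the candidate is *not* grouped (fail-safe to singleton). Real tables
  contain zeros, so demanding a ratio "in all samples" literally would
  discard legitimate members.
* The stored threshold is inclusive (RSD ≤ 0.25). The boundary is pinned by
  two-sided probes at 24 % and 26 % in the tests; probing uses area vectors
  `1 + rsd·z` with standardized `z`, whose RSD is exactly `rsd`.
* Ties for "largest area" break towards lower m/z, then input order, making
  the partition deterministic.
* The concentration profile a clique passes downstream is the **base
  peak's** area vector: it carries the strongest signal and hence the best
  measurement precision. (The pseudomolecular ion supplies the node label
  instead.) This is switchable territory in principle; summing clique
  members would mix ions with different ionization efficiencies.

# Pseudomolecular ion identification

Each clique should be represented by its deprotonated ([M−H]⁻) or
protonated ([M+H]⁺) molecule. The cascade implemented in
`identifyPseudomolecular()`:

1. **Singletons** are their own pseudomolecular ion.
2. **Isotope collapse** (`collapseIsotopes()`): sorted by descending m/z,
   adjacent features chain into a subcluster while each gap is ≤
   `isoWindow + er` (defaults 1.008 Da + 0.016 Da); each subcluster is
   replaced by its most abundant member. This removes ¹³C envelopes and
   sub-Da co-elutions before any Δm/z arithmetic.
3. **Mass-difference matching** (`matchMassDifferences()`): every unordered
   pair is tested against the rule table; a match within ±`er` contributes
   `w_r + w_a` to the implied pseudomolecular m/z, with
   `w_a = (A_i + A_j)/A_base`. Contributions supporting the same implied
   ion (within ±`er`) **accumulate** — a deliberate reading of "highest sum
   of weights": multiple consistent pairs are stronger evidence than any
   single one. If the best accumulated total reaches `weightAccept`
   (default 4) the ion is accepted outright; this may name a *virtual* ion
   never detected by the instrument (e.g. implied jointly by an Na⁺ and a
   K⁺ adduct), which is a feature, not an error — the node then carries the
   virtual m/z with the base-peak profile. Immediate acceptance does not
   additionally require the implied m/z to exceed the base peak's: the
   weight evidence stands on its own.
4. **Candidate #1**: the best-weighted implied ion that lies at or above
   the base-peak m/z, has rule support, and was detected (a member within
   ±`er`).
5. **Candidate #2**: the base peak is assumed to be a stable fragment;
   Δm/z from the base peak to each higher-m/z member is searched against
   characteristic neutral losses of the sample type (`plant` default:
   hexose 162.0528, deoxyhexose 146.0579, pentose 132.0423, malonyl
   86.0004, water 18.0106). The highest-m/z match wins; with no higher
   members the base peak itself is candidate #2.
6. **Candidate #3**: the highest-m/z member with m/z above the base peak
   and area strictly greater than `areaFrac` (default 50 %) of the base
   peak; otherwise the base peak. Always exists.
7. Agreement of #1 and #2 decides early; otherwise any two candidates
   identical within ±`er` decide by vote; otherwise the highest-m/z
   candidate is taken. The `source` field of the result records which path
   decided (`single_feature`, `weight_accept`, `candidate_vote`,
   `highest_mz_fallback`).

## The rule system

The default rule tables (`adductRules()`, `neutralLossRules()`) encode
standard ESI chemistry. The monomer/dimer pair carries the maximal weight
w_r = 10 — it is the single most diagnostic pattern and alone suffices for
acceptance. The remaining weights (formate 6, chloride 5, Na⁺ 6, K⁺ 5,
NH₄⁺ 5, water loss 4, CO₂ loss 3) grade the reliability of each pattern
within the 2–8 band; they are package defaults, exposed as editable TSV
config (`writeAdductRules()`/`readAdductRules()`) because the appropriate
chemistry is instrument- and matrix-dependent. Tests pin only the
structural constants (dimer weight 10, acceptance threshold 4, isotope
window 1.008, candidate-#3 cutoff 50 %), not these editable defaults.

The dimer relation is not a fixed Δm/z — the difference between [M−H]⁻ and
[2M−H]⁻ equals M itself — so the rule table distinguishes `fixed` rules
(constant Δ) from the `dimer` rule, which matches H ≈ 2L + 1.007276 in
negative mode and H ≈ 2L − 1.007276 in positive mode.

# Correlation and significance

`pearsonMatrix()` computes Pearson r over metabolite profiles and two-sided
p-values from `t = r√(n−2)/√(1−r²)`. Zero-variance profiles have no defined
correlation and are recorded as r = 0, p = 1 with a warning. Significance
is `p ≤ α` (inclusive); with Bonferroni correction α is divided by the
number of *tested pairs* m = k(k−1)/2 — the standard family for an
all-pairs matrix (dividing by k would under-correct). Pearson rather than
rank correlation is the default because at metabolomics sample sizes
rank-based measures inflate correlations among low-variance background
metabolites and ignore effect magnitude; partial-correlation models need
regularization when n ≪ k and answer a different question.

# Network construction and layout

Raw r values concentrate near ±1 and make poor edge weights.
`rescaleWeight()` maps r into [0, 1] with the preset's central value s
separating the signs: positive correlations land in [0, s), r = 0 at s,
negative ones in [s, 1]. The even exponent x spreads values near ±1. Small
weight means short desired edge, so positively correlated nodes cluster
while anti-correlated nodes repel. The presets (weak s = 0.5/x = 16,
normal 0.3/8, strong 0.1/2) trade cluster tightness against within-cluster
detail.

Only nodes with at least one significant correlation enter the network.
Edge display is thinned to (1) each node's strongest significant
correlation by |r| and (2) each node's strongest opposite-sign significant
correlation, deduplicated to unique pairs, ranked globally by |r|, top
⌈N/3⌉ shown. The quota is applied after deduplication so that exactly that
many opposite-sign *pairs* appear when available; this yields the intended
node/edge ratio slightly above 1. "Strongest" means maximum |r|: sign
balance is the job of rule (2), not of the primary edge.

`layoutNetwork()` realizes weight-as-target-length spatialization by stress
majorization: all-pairs target distances are shortest weighted paths over
the **full** significant edge set (so hiding edges can never move a node),
the start configuration is classical scaling of that distance matrix plus a
small seed-controlled jitter, and `iterations` majorization sweeps (default
`10·⌈N/83⌉`) refine it. Compared with an ad-hoc spring/repulsion
integrator, majorization is parameter-free, monotonically decreases stress
and is bit-reproducible for a given seed, while the jitter reproduces the
organic run-to-run variability expected of force-directed layouts when the
caller varies the seed. Disconnected components are separated by a target
distance of 1.5× the largest finite path length. Degenerate cases (2 nodes,
coincident points) fall back safely: coincident points contribute no
displacement direction.

Layout quality is scored (`qualityMetrics()`) by DBSCAN on the 2-D
coordinates — eps defaults to 0.08× the bounding-box diagonal (scale-free
in the layout's own units), minPts = 3 — with the cluster count excluding
noise, and by the mean silhouette width over non-noise points (undefined
and reported `NA` with fewer than 2 clusters). DBSCAN is implemented in
the package (plain density-reachability expansion; the layouts scored here
are small, so no index structures are needed) and is cross-checked in the
tests against an independent closure-based re-implementation; the
silhouette comes from the `cluster` package.

# Synthetic data

`makeSyntheticDataset()` generates the study conditions the tests run
under: 12 samples by default (three conditions × four replicates is the
typical design scale), metabolites with neutral masses uniform in 150–600
Da emitting their pseudomolecular ion (base peak, relative area 1) plus a
random menu of adducts/dimer at rule-exact m/z and fixed area fractions,
¹³C isotopologues at 10 % of their parent, log-normal concentration
profiles (areas are positive and right-skewed) with base level 1e5, and
multiplicative log-normal area noise with CV 0.05 — comfortably inside the
25 % ratio-RSD grouping criterion, as adduct ratios of a real run are. The
ratio RSD of two independently noised members is ≈ √2·CV, which the tests
verify empirically. Clique RTs sit on a 0.1-min grid so the partition
ground truth is unambiguous at the default 0.02-min window.

"Hexose parent" cliques model glycosides: the parent ion is the true
pseudomolecular ion and the base peak its aglycone fragment; such a clique
cannot also carry monomer-anchored species (dimer, adducts), whose ground
truth would contradict it, and the generator enforces that.

Block correlation is implanted via latent block factors:
`z_i = √w·F_b + √(1−w)·ε_i` gives within-block correlation w and
between-block correlation w·ρ_b where ρ_b correlates the factors. A
mathematical constraint follows: equicorrelation among B blocks is bounded
below by −1/(B−1), so e.g. three mutually anti-correlated blocks at −0.8
are unrealisable by any data; infeasible targets are clamped with a
warning. The layout-separation tests therefore use −0.45 for three blocks,
which still produces decisive separation under the strong preset.

What the generator does **not** emulate: correlated (isotope-pattern-like)
noise between clique members, RT drift across samples, missing peaks,
detector saturation, or in-source reactions linking different RTs. Passing
tests on this suite therefore demonstrate algorithmic correctness under the
stated assumptions, not performance on any particular instrument's data.

# Problem sizes and defaults

The test suite exercises grouping/identification on 200-clique suites per
polarity (~700 features), oracle comparisons on ≤ 12-feature tables,
≤ 8-feature cliques and ≤ 20-point DBSCAN fixtures, and 20 seeded layout
replicates on a 15-node three-block network — sizes at which the
brute-force oracles are exact and the whole suite runs in well under a
minute. Pipeline defaults mirror the reference parameter block: positive
mode, minimum area 9000, α 0.01 unadjusted, normal clustering, grouping on,
RT shift 0.02 min, m/z error 0.016 Da, seed 0.

# Known limitations

* Grouping is single-pass and RT-local: in-source reaction products at
  different RTs, or two metabolites perfectly co-eluting with proportional
  profiles, cannot be separated.
* The identification cascade assumes the rule tables fit the instrument's
  chemistry; with an empty or mismatched table it degrades to the
  candidate-vote heuristics.
* No isotope-pattern fitting, charge-state deconvolution or spectral
  library matching — the tool ends where annotation databases begin.
* DBSCAN quality metrics depend on eps; the bounding-box default is a
  convention, and the scores are comparable between runs of this package,
  not across tools.
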