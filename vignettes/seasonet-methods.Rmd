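---
title: "Correlation-network analysis of seasonal seed metabolomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-network analysis of seasonal seed metabolomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonet)
```

# The analysis problem

Desert-annual grass seeds germinate readily all year round, yet the fraction
of germinated seeds that survives a subsequent slow dehydration follows a
pronounced annual rhythm: essentially none survive in mid-summer, essentially
all in mid-winter. A natural question is which metabolites — measured monthly
in dry seeds, 24-h germinated seeds and re-dehydrated seeds — co-vary with
that rhythm, and with the (much more stable) germination percentage.

`seasonet` implements the complete correlation-network workflow for this
design: monthly relative-abundance profiles of ~70 metabolites plus two
physiological traits are turned into a signed correlation network, the
network is decomposed into communities by a random-walk algorithm, community
cohesiveness is tested, and the direct neighborhoods of the trait nodes are
extracted and summarized by correlation sign and compound class.

The package also ships a synthetic generator for this exact design, with
planted (known) block and trait-coupling structure, so that every stage of
the pipeline can be validated against ground truth; the original study's
replicate-level tables are not publicly deposited in machine-readable form.

# Pipeline

For one seed state (dry, germinated or dehydrated) the stages are:

1. **Preprocessing.** Metabolite monthly means are divided by their own
   mean across the time points (`meanNormalize()`); trait percentages are
   arcsine-transformed, `asin(sqrt(p/100))` (`arcsinTransform()`), the
   standard variance stabilizer for percentages; everything is pareto-scaled,
   `(x - mean)/sqrt(sd)` (`paretoScale()`). The transforms are applied in
   that order. All three are monotone per variable, so they leave Spearman
   rank correlations unchanged — they matter for Pearson analyses, PCA and
   heatmaps (`minmaxScale()` provides the 0–1 heatmap scaling), and we keep
   them so that every downstream matrix has the documented scale.
2. **Normality screen.** `normalityScreen()` runs a Shapiro–Wilk test per
   variable across the time points and reports the fraction violating
   normality at `alpha = 0.05`; when more than half violate it, Spearman
   rank correlation is recommended over Pearson. (In the motivating data
   the violation fractions were 74–92%, hence the pipeline's Spearman
   default; on the Gaussian synthetic data the screen duly reports a low
   fraction — the pipeline still uses Spearman, which costs little
   efficiency there.)
3. **Correlation.** `correlationMatrix()` computes all-pairs Spearman rho
   (Pearson on mid-ranks, pairwise-complete), two-sided p-values, and
   Benjamini–Hochberg q-values over the upper triangle
   (m = n(n−1)/2 tests; each state's network is corrected independently).
4. **Network.** `buildNetwork()` places an edge where `|rho| > r` and
   `p <= p*`, with `p*` derived from the target FDR by `pThresholdForQ()`
   (the largest p(k) with p(k) ≤ q·k/m), so every edge has q ≤ 0.05. Edge
   weight is |rho| and the correlation sign is kept, so strong negative
   trait–metabolite relations survive thresholding. The coefficient
   threshold `r` is either fixed (0.5, the value used for the published
   trait subgraphs) or chosen by `robustnessScan()`.
5. **Communities.** `walktrapCommunities()` — see below. Cohesiveness of
   each community with more than nine nodes is tested by
   `communitySignificance()`.
6. **Traits.** `traitSubgraph()` extracts a trait node's direct
   neighborhood with induced edges; `signSummary()` counts positive and
   negative trait correlations by compound class; `networkOverlap()`
   reports edges shared between two state networks (Jaccard index, sign
   mismatches flagged).

`runPipeline()` drives all stages from one validated configuration and
writes every artifact (CSV tables, GraphML/SIF for Cytoscape, JSON reports);
identical configuration and seed give byte-identical files.

# Statistical choices

## Exact small-sample Spearman p-values

With 12 monthly values per variable, the usual t-approximation for the
Spearman statistic is far too liberal exactly where it matters: the BH
threshold for ~2,500 tests at q = 0.05 sits near p ≈ 10⁻⁵, deep in the
null's tail. In simulation the t-approximation (and also the common
Edgeworth correction) inflates the realized false-discovery rate several
fold. The package therefore computes, for tie-free pairs with n ≤ 12, the
*exact* permutation null of Spearman's S = Σ(rank differences)²: S is an
affine function of T = Σ i·π(i), whose exact distribution over all n!
permutations is obtained by a dynamic program over rank subsets (4,096
states at n = 12, computed once and cached). Pairs with ties or n > 12
fall back to the t-approximation with df = n − 2; a full-enumeration,
tie-aware permutation p-value is available for n ≤ 9. With exact p-values
the realized FDR of the edge rule on null data is at (slightly below) its
nominal level, which the acceptance suite verifies by Monte Carlo.

## Threshold selection by property robustness

The correlation-coefficient cutoff is selected by requiring the network to
be insensitive to the companion p-value cutoff. For each candidate r in a
grid (0.30–0.95 in steps of 0.05) the four standard global properties —
average degree, global clustering coefficient (transitivity), density, and
diameter of the largest component in unweighted hops — are computed at every
p-threshold derived from q = 0.01 … 0.10. The *stability score* of r is the
worst normalized range, `(max − min)/max(|median|, 1e-8)`, across the four
property curves, and the chosen r is the smallest one with score ≤ 0.1
(smallest, to keep as many edges as possible among the stable choices). If
no candidate qualifies the score-minimizing r is returned with a warning and
the driver falls back to the fixed 0.5. Transitivity is used rather than the
mean local clustering coefficient because it needs no 0/0 convention on
sparse graphs; the diameter is taken within the largest component because a
single isolated node would otherwise make the curve infinite everywhere.

## Random-walk communities

`walktrapCommunities()` implements the random-walk agglomeration from its
definition. Short random walks (t = 4 steps by default, the conventional
walk length — longer walks blur small communities, shorter ones see only
immediate neighbors) of a walker moving along edges with probability
proportional to |rho| define node profiles P^t_i·; the distance between
communities is the d-weighted Euclidean distance between their average
profiles, and at each step the two *adjacent* communities whose merge
minimizes the Ward-style increase in mean squared distance are merged, ties
broken toward the lexicographically smallest pair so results are
deterministic. Isolated nodes get a unit self-loop so the walk is defined;
disconnected components are never merged, so the merge count is always
n − #components. The returned partition is the dendrogram cut maximizing
weighted Newman modularity Q = Σ_c (w_c/W − (s_c/2W)²). The implementation
is validated against hand-computed fixtures (the two-triangle barbell
splits into its triangles at Q = 5/14), against brute-force enumeration of
all partitions on small graphs, and against the independent igraph
implementation on clean fixtures.

## Community significance

A community is cohesive if its members are better connected inside it than
to the remainder of the graph. For each community larger than nine nodes,
each member contributes a paired observation: its degree inside the
isolated community subgraph versus its degree in the full network after all
intra-community edges are deleted (the two always sum to the full degree —
an exact invariant the tests check). The paired differences enter a
two-sided Wilcoxon signed-rank test, zeros dropped, mid-ranks for ties.
Because degree differences are integers, ties are the rule rather than the
exception, so the exact null is computed by convolution over the doubled
(hence integer) mid-ranks for up to 25 nonzero pairs — this stays exact
under ties, unlike the classical tabulated distribution — with a
tie-corrected, continuity-corrected normal approximation beyond. Two-sided
testing is the default since the procedure is also used descriptively;
a one-sided "internal exceeds residual" alternative is available.

# The synthetic generator

`simulateDataset()` emulates the study design: 12 months (June through
May), four replicates per month and state, 69 metabolites (71 network nodes
with the two traits), compound classes cycling through the eight classes of
the field's annotation. Abundances follow a block factor model

y = baseline_j + att_state·(A_b·s(m) + L_b·f_b(m,k)) + ε,

with s(m) the summer/winter contrast (+1 Jun–Sep, −1 Nov–Feb, 0 otherwise),
f_b a block factor and ε measurement noise (SD 0.2). Dry seeds get an
attenuated signal (×0.25), mirroring the observation that dry-seed
metabolism barely tracks the season.

Design choices worth recording:

* **Month-level factors, orthogonalized.** f_b(m,k) = g_b(m) + u(m,k) with
  replicate jitter u (SD 0.5; the within-month replicate correlation is a
  free knob — the study does not constrain it). The monthly profiles g_b
  are drawn Gaussian and then orthogonalized against each other, the
  seasonal contrast and the survival sinusoid. With only 12 monthly values,
  independent Gaussian profiles collide by chance alarmingly often (sample
  |r| > 0.7 between two blocks in a few percent of draws), which would fuse
  planted blocks and randomize trait correlations — not a property of the
  pipeline under test but of an under-identified simulation. Orthogonalizing
  the planted factors makes the ground truth actually identifiable at the
  design size while leaving all sampling noise (replicate jitter,
  measurement noise, Binomial trait counts) in place.
* **Trait model.** Survival follows a cosine with peak month January
  (100%) and trough July (0%); germination sits at 90% with a November dip
  to 76.5%. Both are shifted on the *logit* scale by the planted couplings
  to the block scores z_b(m) = A_b·s(m) + L_b·g_b(m) and sampled as
  Binomial(50) counts per replicate — counts, not percentages, so the
  replicate noise is the physically right one, and the logit link keeps
  percentages in range without distorting ranks (Spearman only sees the
  ordering). The coupling gains differ per trait: germination's nearly flat
  baseline needs gain 1 for its coupling to dominate its ranking, while
  survival's dominant sinusoid requires gain 5 for couplings to stay
  visible beside it.
* **Default couplings mirror the reported pattern.** Germination +0.8 and
  survival −0.8 to the first block, which carries a strong summer
  accumulation (A = 0.6); the other blocks are weakly seasonal
  (A = ±0.15) and uncoupled. This reproduces, as recoverable structure,
  the study's qualitative findings: germination positively and survival
  negatively associated with the same summer-accumulating compounds, and a
  negative germination–survival edge. A symmetric alternative — coupling
  one trait to all four blocks at ±0.8 — turns out to be *unrecoverable in
  principle* under the r > 0.5 edge rule: with four independent factors the
  trait's correlation to each dilutes to about 1/√4 of the attainable
  maximum (≈ 0.49). The defaults therefore plant couplings on one block.
* **Nonnegativity.** Relative abundances are truncated at zero; at the
  default baselines (uniform 3–8) truncation is a < 0.1% tail event.

`simulateNullDataset()` zeroes all loadings and amplitudes, yielding
mutually independent metabolites for false-discovery calibration.

What the generator deliberately does **not** emulate: heteroscedastic
measurement error and missingness patterns of real GC-MS/UPLC data,
compound-class-correlated effects (classes are decorative in the
simulation), and any meteorological driver. Passing the planted-recovery
tests therefore shows the pipeline is correct and well calibrated, not that
real data of this size will yield equally clean communities.

# Problem sizes and numerical conventions

The test suite and the acceptance script run at the study's own scale
(12 × 4 × 69 variables; seconds per full pipeline run) with 25–200 Monte
Carlo repetitions for calibration checks, and smaller 20-metabolite
configurations in unit tests. Degenerate inputs are handled explicitly and
loudly: zero-mean metabolites and zero-variance columns are errors naming
the offender, constant variables get missing (never zero) correlations, a
constant heatmap row maps to 0.5 with a warning, a single-node network
reports density 0 with a warning, an edgeless graph has diameter 0, and a
community whose internal and residual degrees coincide everywhere is
reported as degenerate with p = 1. Validity checks on every S4 container
enforce the structural invariants (symmetry, q ≥ p under BH, edge–threshold
consistency, partition coverage, modularity in [−0.5, 1]).

# Known limitations

* The exact Spearman null requires complete, tie-free pairs and n ≤ 12;
  beyond that the t-approximation is used (and flagged in the object).
  Trait series with saturated months (several months at exactly 0% or
  100%) produce ties and hence slightly liberal p-values for those pairs.
* The robustness-scan stability criterion (normalized range ≤ 0.1,
  smallest qualifying r) is one reasonable formalization of "robust
  behavior across a range of p-values"; all its ingredients are arguments
  and logged in the run report.
* Storey-type q-values are not implemented; Benjamini–Hochberg is the only
  multiple-testing procedure offered.
* The walktrap implementation is O(n³) in dense matrix operations —
  comfortable for metabolome-scale networks (≤ a few hundred nodes), not
  meant for omics-scale graphs.
* Community p-values are not corrected across communities; with at most a
  handful of tested communities per network the published analysis did not
  correct either.
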