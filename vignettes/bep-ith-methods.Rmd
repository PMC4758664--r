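---
title: "Branching tumor evolution and multiregional ITH: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branching tumor evolution and multiregional ITH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bepith)
```

This vignette is the package's own account of its models and the design
decisions behind them: the branching-evolutionary-process (BEP) tumor
simulator, the in-silico multiregional sequencing and ABC fit, and the
founder/progressor analysis operators for mutations, copy number, and
methylation.

## The BEP model

A tumor is a population of cellular automata on a two-dimensional square
lattice, one cell per lattice point. Each cell carries a binary genome
of `n_genes` genes; the first `n_drivers` are driver genes. In a unit
time step every cell dies with probability `death_prob` and, if it
survives, divides with probability

$$p = \min\!\left(1,\; p_0 \cdot 10^{f k}\right),$$

where $k$ is the cell's mutated-driver count: each driver mutation
multiplies the division probability by $10^f$. At division, every
wild-type gene of the parent flips to the mutated state independently
with probability `mutation_rate`; mutations never revert, so genomes
grow monotonically along lineages — the property that makes
founder/progressor classification meaningful.

Parameter defaults (units in parentheses):

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 300 | genes per genome |
| `n_drivers` | 6 | driver genes (fitted in the ABC step) |
| `driver_strength` (f) | 0.8 | log10 division-probability gain per driver |
| `mutation_rate` (r) | 0.01 | per-gene per-division mutation probability |
| `base_division_prob` (p0) | 0.001 | per-step division probability, k = 0 |
| `death_prob` (q0) | 1e-7 | per-step death probability |
| `init_cells` (c0) | 10 | initial unmutated cells |
| `max_cells` (cmax) | 1e6 | stopping population |
| `max_steps` (tmax) | 5e6 | stopping step count |
| `lattice_side` | 2048 | lattice points per side |

The raw value $p_0 10^{fk}$ exceeds 1 from $k \ge 4$ at the defaults; it
is capped at 1 because it is used as a Bernoulli probability. The
lattice side default gives roughly a 4x area margin over `max_cells`;
the run stops as soon as the population *exceeds* `max_cells` (one
synchronous doubling of overshoot is possible when most cells are at
$p = 1$), the step budget runs out, or the tumor dies.

### Spatial growth rules

Initialization packs `init_cells` cells around the central lattice point
(sorted by Euclidean distance, ties broken by a fixed spiral index) and
consumes no random numbers. A dividing cell places its daughter on an
empty Moore-neighborhood point chosen uniformly; if all eight neighbors
are occupied, the run length $l_i$ of consecutive occupied points is
measured in each direction, a direction is drawn with probability
$\propto 1/l_i$ among directions whose run reaches an empty point before
the lattice boundary, and the run is shifted outward one point, freeing
the neighbor. A direction that hits the boundary with no empty point is
ineligible; if all eight are ineligible the division is skipped that
step. Marked divisions are applied along an outward square spiral from
the center, flipping the traversal direction of each ring with
probability 1/2 to avoid a systematic rotational bias.

Decisions on points the growth rules leave open:

- **Who carries the pre-division mutations.** Mutation is applied to the
  parent genome immediately before the division and the daughter copies
  it, so both carry the new mutations. This is the literal reading of
  mutating "before the cell division"; the alternative (daughter-only)
  halves the effective per-lineage rate but does not change the
  qualitative behavior.
- **Order within a step.** Death and division marks are decided
  simultaneously from the pre-step state; dead cells are removed before
  any division is applied.
- **Batching of mutation draws.** All dividing parents of a step are
  mutated in one vectorized draw before any placement; placements then
  follow spiral order. Mutation outcomes are independent of placement,
  so this only fixes the random-stream layout (runs remain exactly
  reproducible from the seed; a single global stream is used).
- Cell identifiers are never reused, which keeps genealogies
  well-defined for lineage analyses (`record_lineage = TRUE` stores each
  cell's parent and genome at birth).

## In-silico multiregional sequencing

25 square windows (default 31x31 points) are placed with centers on a
5x5 grid spaced `lattice_side %/% 5` apart, as symmetrically about the
center as integer coordinates allow (exact 90-degree symmetry holds when
the parities are compatible, e.g. side 205). Windows with at least half
their points occupied are eligible; `s` of them are drawn uniformly. Per
window and gene the VAF is the mutated-cell fraction — the simulated
tumor is haploid and contamination-free, so VAF equals the cancer-cell
fraction — and VAFs that do not exceed 0.3 (inclusive) are zeroed,
emulating the failure of bulk regional sequencing to detect
low-frequency variants.

## Summary statistics and the ABC fit

For a profile matrix, φ is the share of mutated rows (rows with a
nonzero entry) that are nonzero in **all** columns, and θ is the mean
over columns of the share of mutated rows nonzero in **only** that
column. The denominator — the number of mutated rows — makes both
"proportions" as the observed data are reported (the counting definition
alone would leave them unnormalized); founder and unique rows are
disjoint so φ + θ ≤ 1.

Observed statistics from real cases are scale-matched by reducing every
case to `s = 5` samples: cases with exactly 5 are computed directly,
larger cases are averaged over 10 uniformly drawn 5-sample subsets; the
mean and SD over cases define the acceptance window. The grid fit runs
`reps` simulations per setting of (d, f, r) over the full
10 x 10 x 5 = 500-point grid and records the fraction of repetitions
with both statistics within one SD of the observed means (closed
interval; repetitions whose profile has no mutated row count as
rejected).

**A scale caveat.** At the reduced problem sizes used throughout the
test suite (`max_cells` 1e4, lattice 200, 15x15 windows — chosen so a
simulation completes in seconds), the sampling windows lie much closer
together relative to tumor radius than at the full 1e6-cell scale.
Profiles are therefore shared-heavy: φ measured over scaled runs at the
fitted setting (r = 0.01, d = 6, f = 0.8) is ~0.2–0.6 and θ ~0.05–0.10,
well below the full-scale observed window (φ ≈ 0.72, θ ≈ 0.14), and the
absolute ABC acceptance fraction against that window is near zero at
every setting. Scaled runs still reproduce the *relative* structure —
the VAF ordering founder > shared > unique, the concentration of driver
genes among founder rows, and the (φ, θ) distance gradient across
mutation rates — which is what the scaled tests assert. Full-scale runs
reproduce the absolute window only with orders of magnitude more
computation than an interpreted implementation can spend.

## Founder/progressor analysis of real profiles

**Mutations.** Variants called anywhere are kept if their position has
depth ≥ 10 in every sample of the case; presence in a sample means
VAF > 0.05 (both thresholds strict, as printed conventions). Founder =
present in all samples, unique = exactly one, shared = in between.
Sample trees are built by a greedy perfect-phylogeny construction over
the binary presence patterns: patterns are accepted as clades in order
of descending sharing count, then descending mutation support, then
lexicographic pattern (fully deterministic); a pattern conflicting with
the accepted laminar family is counted as homoplasy and its mutations
attach to the smallest accepted clade containing its samples. On
conflict-free inputs this recovers the unique maximum-parsimony tree
(validated in the tests against exhaustive topology search); on
conflicting inputs it is a fast approximation whose unresolved regions
may differ from other parsimony programs. The mutation-support tie-break
is what makes the construction minimize homoplasy greedily — a pure
sharing-count/lexicographic order could prefer a weakly supported
pattern over a heavily supported conflicting one.

**Bipartitions.** Every edge below the trunk splits the samples into the
leaves under it and the rest; the trunk split (empty complement) is
dropped and complements are deduplicated. This is a superset of the
"branching points except the first" description: it includes
single-sample splits, which equals the branch-point set on binary trees
and extends it consistently to the two-sample case.

**Cancer cell fraction.** For a mutation in $m$ of $n$ reads at purity
$\alpha$ and allele-specific copy numbers $q_a, q_b$, the expected
allele fraction of a mutation in $p$ copies in a fraction $c$ of cancer
cells is $f = \alpha c p / (2(1-\alpha) + \alpha(q_a + q_b))$ — the
quotient form; the source formula omits the division sign, but only the
quotient keeps $f \le 1$ and matches the cited clonality literature. The
multiplicity prior enumerates the $q_a + q_b$ possible mutated-copy
configurations as equally probable. The posterior is computed over the
inclusive grid $c \in \{0.01, 0.02, \ldots, 1\}$ with a uniform prior,
and the CCF is the discrete median (smallest grid value with cumulative
mass ≥ 0.5). Calls: clonal iff CCF > 0.8 (strict), only in samples with
purity > 0.6 (strict). At depth 2000 the estimator's spread is dominated
by binomial read noise (σ on the c scale ≈ 0.02–0.03, i.e. 2–3 grid
steps); the tests assert calibration against that sampling noise, since
no estimator can beat it.

**Copy number.** Segment LRRs are median-centered per sample and
averaged over predefined recurrent regions with overlap-length weights.
Founder calls require a shared sign with |LRR| > 0.06 in all samples and
> 0.12 in at least one — the sign requirement is this package's
addition, since a direction must be assignable (the magnitude-only
wording would admit mixed gain/loss rows). Progressor calls take the
group-mean difference of largest magnitude over the bipartitions
(|ΔLRR| > 0.06), excluding regions already called founder (the
categories are reported as disjoint), with the altered side taken as the
group deviating more from the centered baseline. A focal call contained
in an arm-level call of the same category is discarded. The recurrent
region list is user-supplied input (BED-like TSV with scale and
containment columns); a toy set ships with the fixture generator.

**Methylation.** Δβ = tumor β − matched normal β, autosomal probes only.
Founder hyper/hypomethylation requires Δβ > 0.3 / Δβ < −0.3 in all
samples of the case — the hypo threshold is read as −0.3; the printed
"< 0.3" would call nearly everything and cannot be meant. Progressor
calls use Δ′β (max |group-mean difference| over bipartitions) with the
threshold θ chosen as the smallest value on the grid 0.05–0.60 (step
0.01) whose permutation FDR — mean permuted exceedance count over
observed count, default 100 sample-label permutations — is ≤ 0.1;
neither the permutation count nor the grid is prescribed by the source,
so both are package defaults sized for array-scale data. Called probes
split hyper/hypo by the sign of the mean Δβ. Label permutation with very
few samples cannot destroy a strong effect (with 4 samples a 3-vs-1
split recurs in 1/4 of permutations), so FDR control is only meaningful
from ~6 samples per case; the study design this emulates had 5–21.
Variance is decomposed per probe as in one-way ANOVA,
$SS_T = SS_w + SS_b$, with $SS_w$ (within-case) measuring intratumor and
$SS_b$ (between-case) intertumor heterogeneity — the formulas' standard
meaning is followed where the source prose transposes the two labels.
Enrichment of a probe category among the top-n probes by either
component is its top-n fraction over its overall fraction.

## Synthetic fixtures

The generators produce data whose founder/progressor structure is
planted on a known sample tree (default: a caterpillar topology), so
every operator can be validated against returned truth labels:

- mutation profiles with founder/shared/unique variants at VAF 0.3 plus
  truncated-Gaussian noise and Poisson depths floored at 10;
- segment tables with arm/focal events of ±0.3–0.4 LRR on chosen
  branches over Gaussian segment noise, plus neutral filler segments
  that pin the per-sample median near 0;
- β matrices over 4 cases x 8 samples with case-level baseline shifts
  (capped at ±0.25, below the founder threshold, and largest for
  CpG-island probes so intertumor variance concentrates there) and
  planted founder/progressor events of Δβ = ±0.4 in case 1.

What the fixtures do **not** emulate: read-level sequencing noise and
error rates, purity/copy-number estimation error, array normalization
artifacts, and correlated probe structure. Passing the planted-truth
tests therefore shows the operators implement their definitions
correctly, not that the thresholds are optimal for any particular real
data set.

## Numerical choices and degenerate inputs

- Probabilities are capped at 1; the CCF grid includes both endpoints;
  the VAF floor and the presence/clonality thresholds follow the
  strict/inclusive conventions listed above.
- All-zero profile matrices make φ/θ undefined and raise an error (the
  ABC loop counts such repetitions as rejected).
- Zero-variance profiles map all samples to one neutral RGB color;
  fewer than three informative principal components pad the remaining
  channels with the neutral value 128.
- Regions without segment coverage become `NA` and are excluded from
  copy-number calls with a warning; a zero observed exceedance count
  makes the permutation FDR undefined at that θ (no call).
- Tie-breaks (tree characters, spiral order, color scaling) are all
  deterministic; every stochastic entry point takes an explicit seed.

## Problem sizes used by the test suite

Simulator-based tests run at `max_cells` 1e4 (lattice 200, 15x15
windows, 20 repetitions) for the pooled category properties and the ABC
gradient, and at a few hundred to a few thousand cells for step-level
unit tests and the summary-distance check; fixture-based tests use
500–600 probes, 5–8 samples and 25–50 replicates. These sizes keep the full suite under
a few minutes while leaving every assertion statistically comfortable at
fixed seeds.

## Known limitations

- Two-dimensional growth only; no migration, stem-cell hierarchy,
  back-mutation, or fitness costs.
- The in-silico sequencing is noiseless apart from the 0.3 floor.
- The greedy parsimony tree is not guaranteed optimal on conflicting
  (homoplasic) inputs.
- Absolute φ/θ levels are scale-dependent (see the scale caveat above);
  comparisons across tumor sizes should use matched simulation scales.
- The permutation FDR is unreliable below ~6 samples per case.
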