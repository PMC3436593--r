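---
title: "Models and methods: genetic distances, saturation, barcode gaps and GMYC delimitation"
author: "BarcodeDelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where the methods literature leaves the design
open.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Substitution models and pairwise distances

### The model family

`substitutionModel()` builds reversible nucleotide models from the nested
family JC69 ⊂ K80 ⊂ HKY85 ⊂ TIM2 ⊂ GTR (plus F81), parameterised by base
frequencies π (A, C, G, T), six exchangeabilities
(r_AC, r_AG, r_AT, r_CG, r_CT, r_GT), a proportion of invariable sites
p_inv ∈ [0, 1), and a gamma shape α > 0 discretised into `nCat` (default 4)
equal-probability categories.  Family constraints are enforced by the class
validity: K80/HKY85 share one transition rate κ; TIM2 constrains
r_AC = r_AT and r_CG = r_GT with free AG and CT transition rates; JC69 and
K80 fix uniform frequencies.

The rate matrix Q has Q_ij = r_ij π_j off the diagonal and is normalised so
that −Σ_i π_i Q_ii = 1: one unit of branch length is one expected
substitution per site.  With invariable sites, the discrete-gamma category
rates (mean of each quantile slice, rescaled to mean one) are divided by
(1 − p_inv), so branch lengths keep counting substitutions averaged over
*all* sites.  This is the convention used by phangorn and PAUP-style
software; it was verified against phangorn numerically and is used
consistently by the likelihood engine, the pairwise-distance optimiser and
the sequence simulator, so simulated branch lengths and estimated distances
live on the same scale.

### Distances

* `pDistance()` implements two counting conventions.  The
  `paper_total_length` mode counts mismatches plus single-gapped sites over
  the total masked length — the convention under which divergences
  "including gaps" are expressed.  The default `pairwise_deletion` mode
  drops every column with a gap/N in either row, which is what mainstream
  distance software does and what all corrected distances here use.
* `k2pDistance()` is the closed form
  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q).  When an argument of a logarithm is
  ≤ 0 the correction is undefined — the pair is *saturated* — and the
  function returns `NA` flagged `saturated`, never an exception and never a
  clipped number.
* `mlPairwiseDistance()` maximises the two-sequence likelihood
  Σ_sites log[p_inv π_x 1{x=y} + (1 − p_inv) (1/n_cat) Σ_c π_x P_xy(t ρ_c)]
  over t ∈ [0, 10] by golden-section search (tolerance 1e−8), using a
  symmetric eigendecomposition of Q for P(t) = exp(Qt).  An optimum at the
  upper bound is reported as saturated rather than returned as 10; the
  bound of 10 substitutions/site is far beyond any usable signal.

A useful identity exploited by the test suite: under K80 the K2P closed
form is the *joint* maximum-likelihood estimate of (t, κ).  The numeric
optimiser therefore reproduces the closed form to 1e−4 only when the
model's κ is set to its pair-specific MLE,
κ̂ = [−½ln(1−2P−Q) + ¼ln(1−2Q)] / [−¼ln(1−2Q)]; with a fixed global κ the
two estimators differ by sampling noise, which is expected and not a
defect.

### Estimation and model ranking

`estimateModelParameters()` follows the classical distance-workflow recipe:
a JC69 distance matrix → neighbor-joining guide tree → joint optimisation
of branch lengths and the free model parameters by maximising the pruning
likelihood.  The heavy optimisation is delegated to
`phangorn::optim.pml()` with the family's rate-sharing pattern; base
frequencies default to empirical values (ML estimation is opt-in via
`mlFreq`), which stabilises small data sets.  The optimisation has fixed
starting values and is deterministic given the data.

`rankModelsAIC()` fits every requested family × {plain, +I, +Γ, +I+Γ}
combination on the same guide topology and ranks by AIC = 2k − 2 log L.
The parameter count k includes the branch lengths (2n − 3) and counts base
frequencies as three parameters even when set empirically (the jModelTest
convention), so: JC69 0, K80 1, F81 3, HKY85 4, TIM2 6, GTR 8, +1 each for
I and Γ.  Ties break toward the smaller k; candidates that fail to
optimise are excluded and reported, not fatal.

### Degenerate inputs

An alignment whose rows are all identical has its likelihood maximised at
zero branch lengths with p_inv at its upper boundary; the estimator
short-circuits this case and returns a model with p_inv → 1 rather than
running an optimiser on a flat surface.

## 2. Tree utilities and the strict-clock test

Newick I/O is a validated wrapper around ape (unique labels, finite
non-negative branch lengths; internal node labels kept as annotations).
`neighborJoining()` wraps `ape::nj` and clamps negative branch lengths to
zero, recording the clamped deficit; saturated (NA) distances are a hard
error with the advice to use a different model.

`treeLogLik()` is an in-package Felsenstein pruning implementation (+I+Γ
mixtures, site-pattern compression, per-node rescaling, gaps/N as missing
data).  It exists so that the package's likelihood conventions are pinned
by an exhaustive-enumeration oracle in the tests (all internal state
assignments for n ≤ 5, ≤ 4 sites) and cross-checked against phangorn; the
tests also verify the pulley principle (re-rooting invariance) and that an
all-gap taxon contributes a factor of one.

`strictClockTest()` compares free branch lengths (2n − 3 parameters,
unrooted) against a strict clock (n − 1 node heights, rooted, optimised
with `optRooted = TRUE`), with model parameters held fixed.
LR = 2(logL_free − logL_clock) is referred to χ²(n − 2).  Rooting defaults
to midpoint (user-overridable outgroup) since the original rooting of any
given published tree is generally not recoverable.  The test's nominal
size and its power against a 5× rate-accelerated branch are checked by
simulation in the test suite.

## 3. The substitution-saturation test

`issTest()` implements the entropy-based index: per ungapped column the
Shannon entropy H_j of its base composition (bits); the index is
Iss = mean(H_j) / H_full with H_full the entropy of the global base
frequencies (2 bits when uniform).  A fully saturated alignment (rows
i.i.d. from the global composition) has Iss → 1; an invariant alignment
has Iss = 0.  The externally estimated invariable fraction is removed
before averaging, allocated over the constant-column base types
proportionally to their abundance — the test expects p_inv from a
maximum-likelihood model fit, mirroring the practice of feeding
ML-estimated proportions into the test when the test program cannot
estimate them itself.

Iss is compared against critical values Iss.c for symmetric and asymmetric
true topologies by a two-sided t-test with the standard error of the
sitewise entropies (the sidedness is not fixed by the methods literature;
two-sided is the conservative choice and is logged).  The verdict follows
the four-way decision table: below the critical value and significant →
low saturation; below but not significant → substantial saturation; above
and not significant → poor; above and significant → useless.  Data sets
larger than 32 taxa are evaluated on `nResamples` (default 100) random
32-taxon subsamples, because published critical values stop at 32 OTUs;
the seed is mandatory.

**Critical values.**  The published simulation tables behind Iss.c are not
redistributable here, so the shipped lookup table
(`inst/extdata/issc_table.tsv`) is a clearly-labelled synthetic stand-in
re-derived with `regenerateIssCritical()`: sequences are evolved under
JC69 on balanced (symmetric) and pectinate (asymmetric) model trees over a
log-spaced grid of depths; performance at a depth is the mean fraction of
true bipartitions recovered by neighbor joining; the critical index is the
mean Iss at the deepest depth retaining ≥ 95 % of the best performance
across the grid.  The regenerated values (≈0.52–0.83) reproduce the
qualitative structure of the published tables — asymmetric below
symmetric, increasing with OTU count and length — but are not numerically
identical to them, and verdicts near the boundary should be read
accordingly.  Lookups use the nearest tabulated length and interpolate
linearly in log2(OTU count).

## 4. Barcode-gap frequency distributions

`binDistances()` sorts distances into half-open classes
[w(k−1), wk[ — closed lower, open upper, 1-based indices, exact multiples
go up, width 0.005 by default to match how barcode-gap figures are drawn.
No means or standard deviations are ever computed for these distributions:
summarising them that way biases the shape, which is precisely the failure
mode the frequency-distribution approach avoids.  `partitionDistances()`
splits the C(n,2) pairs by a species partition; the identities
|intra| = Σ_s C(size_s, 2) and |intra| + |inter| = C(n,2) hold by
construction and are verified against brute-force pair enumeration in the
tests.  `findGaps()` reports interior empty classes and interior local
minima with flanking counts, never extrapolating beyond the occupied
range; whether a reported gap has the "clear and stable slopes" of a
usable barcode gap is left to the investigator, and no automatic
threshold-based species assignment is offered (the point of the analysis
is that such thresholds are unsafe).

`duplicateAndRecode()` implements the taxon-sampling experiment: designated
sequences are duplicated (copies `taxon__dup1`, …, with distances equal to
their source) and designated taxa recoded to new species.
`makeDuplicationFixture()` builds a 64-taxon surrogate world whose
species-size profile {10, 8, 6, 5, 4, 3, 3, 2, 2, 2, 2} + 17 singletons
gives exactly 114 intraspecific pairs; duplicating the two designated
singletons four times each and recoding the 3-member species as 2 + 1
yields 72 taxa, 2556 distances, 132 intra- and 2424 interspecific — the
printed arithmetic of the published experiment.  (The published "1092
interspecific" for the 64-taxon baseline is inconsistent with
C(64,2) = 2016; the package enforces the count identity, under which the
baseline has 1902 interspecific pairs.)

## 5. The general mixed Yule–coalescent model

### Waiting times and likelihood

On a rooted, strictly bifurcating ultrametric tree with n tips, the n − 1
branching events define n − 1 inter-event intervals from the root to the
present (their lengths sum to the root height).  Each interval carries a
diversification-class lineage count k_i and within-species counts n_{i,j};
the hazard is

b_i = λ_div k_i^p_div + λ_coal (Σ_j n_{i,j}(n_{i,j} − 1))^p_coal,

with a zero-lineage class contributing 0.  The log-likelihood sums
log b_i − b_i x_i over the n − 2 intervals that end in an event and adds
only the survival term −b_i x_i for the final interval (youngest event →
present).  Censoring that last interval is what makes the pure-Yule
maximum-likelihood rate come out as λ̂ = (n − 2)/Σ_i k_i x_i — the closed
form the tests assert — and keeps Σ x_i equal to the root height.  The
coalescent-only null uses the single-class hazard b_i = λ (N_i(N_i−1))^p
and is fitted by profiling λ (closed form given p) and a 1-D search over
p.

The scaling exponents p are searched in [0, 10] (the convention of the
reference implementation family); rates are optimised on the log scale by
box-constrained quasi-Newton from two fixed starting points, so fits are
deterministic.  `waitingTimeLogLik()` also exposes the per-species-exponent
variant (λ_coal Σ_j (n_{i,j}(n_{i,j}−1))^p_coal) behind `pooled = FALSE`;
the pooled form is the default throughout because it is the behaviour of
the reference software family.

### Single threshold

The likelihood is piecewise constant in the threshold between branching
events, so candidate thresholds are the distinct branching times, each
evaluated just rootward of its node, plus the all-diversification
candidate.  Below the threshold *every* lineage is in the coalescent class
(singletons count as one-lineage coalescents: they contribute nothing to
the pair sum but leave the diversification class empty); above it every
lineage diversifies.  Two consistency facts follow and are asserted in the
tests: the oldest candidate reproduces the coalescent-only null exactly,
and the entity count is monotone non-increasing as the threshold moves
rootward.  The fit reports the LR against the null on χ²(3), clusters
(maximal subtrees below the switch with ≥ 2 tips), singletons, entities,
and a confidence range: the cluster counts of all candidates within 2
log-likelihood units of the optimum.  Threshold times are reported
negative (before the present), matching the axis convention of LTT plots.

### Multiple thresholds

The exact algorithm of the original multiple-threshold implementation is
unpublished ("beta") detail; the package uses a documented greedy
stand-in.  A solution is a set of *domains* — an antichain of subtree
roots covering all tips, each with its own switch level chosen among the
node heights inside the domain.  Starting from the single-threshold
optimum (one domain), proposals either move a domain's switch to another
local node height, split a domain into its two children (one child's
switch moved, the other inheriting), or merge sibling domains; the best
proposal is accepted while it improves the log-likelihood by more than
1e−4, with ties broken toward fewer distinct thresholds.  Pure-Yule
"no-switch" levels are excluded from the search: every lineage must end in
the coalescent class, exactly as in the single-threshold model.  Without
that exclusion the search shaves cluster members into Yule singletons for
small spurious gains and over-splits — a pathology we observed directly.

The number of *distinct thresholds* reported is the minimum number of cut
times that can realise the solution (a minimum piercing of the per-species
[root age, stem age) intervals); the LR of multiple vs single uses the
number of extra thresholds as its degrees of freedom.  Both conventions
are assumptions, flagged here, since the original test is not specified to
that level of detail.

**Known limitation.**  Because the two classes share one (λ, p) pair each,
a clade whose within-species coalescent depths are, say, 10–30× deeper
than another's is usually *absorbed into the Yule class* (its coalescences
counted as speciation waiting times) rather than resolved as a second
threshold: the Yule hazard λ k^p is flexible enough to accommodate the
extra events, while a pooled coalescent class spanning both depth scales
fits poorly.  On hand-built two-regime trees the "correct" two-threshold
delimitation can score many log-units below the absorbing solution.  The
greedy search is therefore most useful near the single-threshold optimum;
the test suite asserts a two-regime world in which the multiple model does
open ≥ 2 switch levels and improves the fit, and the nesting
logL(null) ≤ logL(single) ≤ logL(multiple) holds on every input by
construction.

### Numerical robustness

Tip heights are snapped to zero within the ultrametricity tolerance
(1e−6 × root height), and near-zero but distinct node heights (the
jittered polytomies that arise when identical sequences are forced into a
binary clock tree) are handled stably: cluster membership is invariant
under jitter of order 1e−9 × root height (regression-tested), although —
as the published analyses themselves observed — clades of *identical*
sequences whose branch lengths were inflated upstream by the clock model
can still be split spuriously; that artifact originates in the input tree,
not in the delimitation.

## 6. The synthetic-data generator

The generator realises the generative assumptions the delimitation model
itself makes — and only those:

* `simulateYuleTree()`: constant per-lineage speciation rate, no
  extinction; waiting time from k lineages ~ Exponential(kλ).
* `simulateSpeciesCoalescents()`: one panmictic, constant-size population
  per species (Kingman coalescent, pairwise rate n(n−1)/2 per θ, so a
  sample pair coalesces at expected depth θ); genealogies must complete
  before the species' origin, otherwise θ is halved with a warning —
  incomplete lineage sorting across species boundaries is deliberately not
  modelled.
* `simulateAlignment()`: root states from π; per site, invariable with
  probability p_inv, otherwise a gamma category whose rate uses the same
  discretisation (and the same 1/(1 − p_inv) scaling) as the likelihood
  engine, so estimator and simulator are exactly consistent.
* `simulateDataset()`: the "separation" of a world is the ratio of the
  *youngest species divergence* to the mean pairwise coalescent depth θ.
  Tying θ to the root height instead would leave the youngest split
  comparable to within-species depths under a Yule prior, which is not
  what "strongly separated species" means; at separation 100 every
  interspecific divergence is ≥ 100× the expected intraspecific
  coalescence.

What a green test on this world does *not* establish: robustness to
migration, hybridisation, recombination, extinction, population growth,
rate heterogeneity across lineages, alignment error, or the
identical-sequence clock artifacts mentioned above.  Real barcode data
violate several of these routinely; the generator's purpose is to verify
the machinery against its own stated model, not to certify field
performance.

## 7. Tolerances and acceptance-test design

* Closed-form oracles (K2P vs ML under K80 with profile κ; JC vs ML;
  pruning vs exhaustive enumeration) are asserted at 1e−4 or tighter —
  they test optimiser and algebra, not sampling noise.
* Parameter recovery for GTR+I+Γ (8 taxa, 5000 sites, 10 seeds) is
  asserted as: median α̂ within [α/2, 2α] and median p̂_inv within ±0.15
  of truth.  These bands were fixed a priori: α and p_inv are strongly
  confounded in joint estimation (a well-known ridge — more invariable
  sites with a larger shape fit almost as well as fewer with a smaller
  one), so point recovery of each parameter separately is realistic only
  to within these factors at this design size.
* GMYC recovery is asserted at the stated-world level: ≥ 90 % exact
  species-count recovery over 20 strongly separated 5-species worlds, and
  ≥ 80 % non-rejection of the null over 50 single-population coalescent
  worlds (the single-threshold LR test is anticonservative because the
  threshold is maximised over; the 80 % band acknowledges that).
* Saturation limits: Iss < 1e−12 on invariant data, within ±0.05 of 1 on
  i.i.d. uniform 32 × 2000 alignments, and strictly monotone in simulated
  depth over tree scalings ×{0.1, 1, 10}.

## 8. Known limitations

* Critical saturation values are re-derived, not the published ones;
  verdicts near Iss ≈ Iss.c are less trustworthy than the index itself.
* The multiple-threshold GMYC search is a greedy stand-in for an
  unpublished algorithm; its threshold-count degrees of freedom are an
  assumption, and heterogeneous coalescent scales are often absorbed
  rather than resolved (see §5).
* Distances, saturation and delimitation all assume a fixed, correct
  masked alignment; alignment construction and curation are out of scope.
* The clock test fixes the substitution-model parameters at their
  estimates rather than re-optimising them under each hypothesis; with
  realistic data sizes the effect on the LR is second-order.
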