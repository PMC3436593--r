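# BarcodeDelim

DNA-barcoding practice rests on two operations: identifying known species
from short, variable marker sequences (e.g. COI-5P, 5′-partial LSU rDNA),
and delimiting species automatically from the same data.  Both are fragile
in protists, where morphology gives little feedback and taxon sampling is
sparse.  `BarcodeDelim` implements the computational toolkit needed to
*evaluate* that practice on a given marker and data set:

* **Model-based pairwise genetic distances.**  Uncorrected p-distances (two
  counting conventions), the Kimura two-parameter closed form
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`, and maximum-likelihood
  distances under JC69, K80, F81, HKY85, TIM2 or GTR, each optionally with a
  proportion of invariable sites (+I) and discrete-gamma rate variation
  (+Γ, shape α).  Model parameters are estimated on a Jukes–Cantor
  neighbor-joining guide tree by maximising the pruning likelihood, and
  candidate models are ranked by AIC = 2k − 2 log L.
* **Substitution-saturation testing.**  The entropy-based index
  `Iss = mean(H_j) / H_full` (mean sitewise entropy over the full-saturation
  entropy from global base frequencies), with invariable-site removal,
  critical values `Iss.c` for symmetric and asymmetric topologies, OTU
  resampling for data sets larger than 32 taxa, and the four-way verdict
  table (low / substantial saturation, poor, useless).
* **Barcode-gap frequency distributions.**  Distances binned into half-open
  classes `[w(k-1), wk[` (default width 0.005), split into intra- versus
  interspecific sets, interior empty classes and local minima reported —
  deliberately without means or standard deviations — plus the
  taxon-sampling *duplication experiment* (duplicate under-sampled
  sequences, recode species) that shows how apparent gaps fill in.
* **GMYC species delimitation.**  The general mixed Yule–coalescent model on
  rooted ultrametric trees: inter-event waiting times x_i with hazard
  `b_i = λ_div k_i^p_div + λ_coal (Σ_j n_ij(n_ij−1))^p_coal`, a
  coalescent-only null, single- and multiple-threshold fits, likelihood-ratio
  tests, clusters / singletons / entities with 2-log-likelihood-unit
  confidence ranges, and lineage-through-time curves.
* **Synthetic data.**  Yule species trees, within-species Kingman
  coalescents grafted at the tips, sequence evolution under the implemented
  models (the same discrete-gamma machinery as the likelihood engine), and a
  64-taxon surrogate of the published duplication experiment — so the whole
  pipeline runs and is verified without downloading sequences.

## Worked example

A five-species world with five samples per species, strong separation
(every species divergence ≈100× the mean intraspecific coalescent depth),
and sequences evolved under GTR+I+Γ:

```r
library(BarcodeDelim)

world <- simulateDataset(nSpecies = 5, lambda = 1, samplesPerSpecies = 5,
                         separation = 100,
                         model = substitutionModel("GTR",
                           pi = c(0.27, 0.22, 0.26, 0.25),
                           rates = c(1.2, 3.5, 0.8, 1.1, 4.2, 1),
                           pInv = 0.1, alpha = 0.7),
                         nSites = 800, seed = 7)

model <- estimateModelParameters(world$alignment, "GTR",
                                 withInv = TRUE, withGamma = TRUE)
model
#> SubstitutionModel: GTR+I+G
#>   pi:    A=0.2871 C=0.2216 G=0.2665 T=0.2248
#>   rates: rAC=1.6698 rAG=2.9310 rAT=0.7710 rCG=1.0165 rCT=4.8918 rGT=1.0000
#>   pInv:  0.1410704
#>   alpha: 0.9622791  ( 4 categories )

dm <- distanceMatrix(world$alignment, method = "ml", model = model)
sp <- partitionDistances(dm, world$partition)
#> intraspecific: 50 distances, max 0.0101
#> interspecific: 250 distances, min 0.1765

fit <- fitGmyc(world$tree, "single")
fit
#> GMYC fit (single threshold model )
#>   logLik = 161.1757  (null 149.0600)
#>   LR vs null = 24.231, df = 3, p = 2.235e-05
#>   threshold time(s): -0.002132
#>   5 cluster(s), 0 singleton(s), 5 entities  [cluster-count confidence 5-5]

issTest(world$alignment, pInv = model@pInv, nOtu = 16, seed = 1)
#> Substitution-saturation test
#>   Iss = 0.4569 (se 0.0105; 687 sites, 16 OTUs, 100 resamples)
#>   Iss.c symmetric  = 0.8229  (p = 1.312e-153)
#>   Iss.c asymmetric = 0.7375  (p = 4.376e-108)
#>   verdict: low saturation
```

Reading the output: the recovered model parameters sit near the generating
values; all 50 intraspecific distances fall below 0.0101 while the smallest
interspecific distance is 0.1765, so the frequency distribution
(`binDistances`, `findGaps`) shows a genuine barcode gap here; the GMYC
likelihood-ratio test rejects the coalescent-only null (p ≈ 2×10⁻⁵) and the
single-threshold model delimits exactly the five generating species at a
switch ≈0.002 relative time units before the present; the marker is far
from substitution saturation (Iss ≪ Iss.c, verdict "low saturation").

The workflow wrappers `runDistFreq()`, `runGmyc()` and `runSaturation()`
chain these stages and write frequency tables, gap reports, entity tables,
LTT curves and key=value summaries with a provenance block.

## Acceptance script

`scripts/acceptance.R` re-runs the main pipeline from scratch against the
installed package — it builds the 64-taxon duplication fixture, estimates a
GTR+I+Γ model, computes the maximum-likelihood distance matrix, applies the
duplication/recoding experiment, bins the distances and reports gaps, runs
the substitution-saturation test, and fits the single- and
multiple-threshold GMYC models on the fixture's clock tree — then writes
its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
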