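---
title: "Target-centric epistasis detection: models, estimators and design choices"
author: "epiTarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-centric epistasis detection: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Exhaustive pairwise interaction scans in genome-wide association studies
pay a heavy multiple-testing price. epiTarget instead fixes one *target*
SNP `A` — typically a variant with an established effect, e.g. a top hit
from a previous scan — and asks which of the remaining SNPs
`X = (X(1), ..., X(p))` interact with it. The target is binarized to
`A ∈ {-1, +1}` under a dominant rule (dosage `{1, 2} → +1`) or a
recessive rule (`{2} → +1`), with the companion coding
`Ã = (A + 1)/2 ∈ {0, 1}`.

Because `A` is binary and symmetric, the phenotype always decomposes as

    Y = μ(X) + δ(X)·A + ε,
    μ(X) = ½[E(Y | A = +1, X) + E(Y | A = -1, X)],
    δ(X) = ½[E(Y | A = +1, X) - E(Y | A = -1, X)],

so SNPs in epistasis with the target are exactly the support of the
synergy function `δ` (after removing its constant part `δ₀`, the main
effect of `A`). The analogy with randomized trials is deliberate: `A`
plays the treatment, `X` the covariates, and the complication relative to
a trial is that `A` is *not* independent of `X` — linkage disequilibrium
(LD) ties the target to its chromosomal neighbourhood. The propensity
score `e(x) = P(A = +1 | X = x)` carries exactly that dependence.

## Estimators

### Modified outcomes

Since `E[YÃ | X] = E[Y | X, Ã = 1]·e(X)` and symmetrically for the other
arm, the *modified outcome*

    Ỹ = Y · (Ã/e(X) - (1 - Ã)/(1 - e(X)))

satisfies `δ(X) = ½·E[Ỹ | X]`: a sparse linear regression of `Ỹ` on `X`
recovers the support of `δ` without ever estimating `μ`. When
`e ≡ 1/2` (target independent of the rest), `Ỹ = 2YA`, the classical
independent-treatment construction. Inverse-propensity weighting is
numerically fragile near `e ∈ {0, 1}`, so four standard variants are
implemented (`plainModifiedOutcome`, `shiftedModifiedOutcome`,
`normalizedModifiedOutcome`, `robustModifiedOutcome`):

* **plain** — the definition above with the estimated `ê`;
* **shifted** — adds `ξ = 0.1` to both denominators, capping every
  individual weight at `1/ξ`;
* **normalized** — rescales each arm so its weights sum to one;
* **robust** — the low-variance estimator of Lunceford & Davidian, with
  arm corrections `C_t` built from `(Ã_j - ê_j)` residuals; when `ê` is
  constant and equal to `mean(Ã)` the corrections vanish and the robust
  and normalized variants coincide exactly (a tested identity).

The robust formulas are transcribed so that every propensity inside a sum
over samples `j` is `ê_j` and the denominators read
`t·ê_j + (1 - t)(1 - ê_j)`. This is a deliberate normalisation of
inconsistent index usage in common write-ups of the estimator; the
reduction identity above and an independently coded direct-sum oracle in
the test suite pin the intended form.

### Outcome-weighted learning

`owlWeights` implements the case-only alternative: predict `A` from `X`
by weighted logistic classification with weights `W = Y / P(A | X)`.
With `Y ∈ {0, 1}` controls get weight exactly zero, yet remain present
through `P(A | X)`, which is estimated on the whole population. The
minimizer of the weighted logistic risk at a genotype `x` is
`ln(E[Y | A = +1, x] / E[Y | A = -1, x])`, which shares its sign with
`δ(x)`; OWL therefore estimates a sign surrogate of the synergy function
and is expected (and observed) to trail the modified-outcome family.

### Support estimation

Both families reduce to sparse regression: squared loss for modified
outcomes, weighted logistic loss for OWL. `enetSupport` fits an elastic
net with mixing `s = 1e-6` — essentially a lasso with a vanishing ridge
for numerical stability — with an unpenalized intercept, on
zero-mean/unit-variance columns. Model selection avoids choosing a single
penalty: `stabilitySelection` draws `N = 50` subsamples of size
`⌊n/2⌋` without replacement, records which variables enter the support at
each penalty on a log-spaced grid of 200 values spanning
`[λ_max/100, λ_max]` truncated to its upper half (100 values), and
`areaScore` ranks SNPs by the mean selection frequency over grid
*positions*. Using positions rather than `λ` values makes scores
comparable across methods whose paths live on different scales; keeping
only the top half of the path discards the noise regime where irrelevant
covariates flood the support. Arm normalizers (`w_t`, `C_t`) are
recomputed inside every subsample, since they are sample statistics.

## Propensity estimation

A logistic regression of `A` on half a million SNPs would overfit;
instead the package models LD directly with a haplotype-cluster hidden
Markov model (`fitGenotypeHMM`), the generative model family behind
fastPHASE and HAPGEN. Each individual carries two latent haplotype paths
over `K` clusters; paths jump between adjacent sites with probability
`ρ_s` (landing on a cluster drawn from `α_s`) and emit a minor allele
with cluster frequency `θ_{s,k}`; the observed dosage is the sum over the
two paths. Fitting is plain EM over the ordered-cluster-pair chain
(`K²` states); the structured transition (identity plus rank-one) keeps
every sweep at `O(nK²)` per site. The observed-data log-likelihood is
non-decreasing across iterations (tested to 1e-8), fits are seeded and
deterministic, and the best of several random restarts is kept.

Only SNPs on the target's chromosome are used (`X_A`), since dependence
is chromosome-wise. Because SNPs in tight LD with the target would push
`e` towards 0 or 1, the chromosome is first clustered with
adjacency-constrained hierarchical clustering (`adjacencyCluster`,
maximum-correlation threshold 0.5) and a window of the target's cluster
plus three clusters per side is discarded (`exclusionWindow`) — from the
conditioning set *and* from every downstream interaction design.
`propensityScores` then runs the forward algorithm three times per
sample (target dosage fixed at 0, 1, 2, excluded sites marginalized) and
applies Bayes' theorem:
`e = P(A = +1, X_A) / (P(A = +1, X_A) + P(A = -1, X_A))`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rule` | dominant | target binarization; recessive maps only dosage 2 to +1 |
| `K` | 12 | HMM haplotype clusters (fastPHASE convention); fewer suffice for simulated panels |
| `nRestarts` | 3 | EM restarts, best likelihood kept |
| θ floor | 1e-3 | keeps emissions away from 0/1 |
| `clip` | 1e-6 | numerical clamp on `e` (distinct from the shifted estimator's ξ) |
| `xi` | 0.1 | shifted-variant denominator shift; caps weights at 10 |
| `s` | 1e-6 | elastic-net mixing |
| `N` | 50 | stability-selection subsamples of size ⌊n/2⌋ |
| grid | 200 → 100 | log-spaced penalties over a 100-fold range, top half kept |
| `corrThreshold` | 0.5 | adjacency-clustering merge threshold |
| `exclusionWidth` | 3 | clusters removed on each side of the target |
| QC | MAF > 0.01, HWE p ≥ 1e-6 | retained-SNP filters |

## Baselines

`gboostScan` is a per-pair likelihood-ratio test in the BOOST/GBOOST
family restricted to pairs involving the target (the sure-screening
stage is deliberately absent): both SNPs enter a logistic model as
factors, the full model adds their saturated interaction (4 columns when
all nine genotype cells are populated; unestimable columns are dropped
and the chi-square degrees of freedom reduced), and the statistic is the
deviance difference. The iterative logistic LRT is used rather than a
closed-form log-linear fit; the two agree at convergence. Under
quasi-separation both models are refit with a tiny ridge (1e-6).
`productLassoScores` fits an L1-penalized logistic regression of `Y` on
the products `A·x_k` and is scored by the same stability-path area as
the main methods, to keep rankings comparable; the LRT baseline is
ranked by its statistic directly.

## The synthetic cohort generator

`simulateGenotypes` samples genotypes from a haplotype-cluster HMM with
uniform cluster weights, constant jump probability `ldJump` (default
0.05) and per-site cluster allele frequencies Beta-distributed
(concentration 1.5) around a site-level MAF drawn uniformly from
`[0.2, 0.5]`. Cluster persistence along the chromosome is what creates
LD: adjacent-site correlations average ≈ 0.14 and decay towards zero by
lag 50, and Hardy-Weinberg equilibrium holds at every site by
construction (two independent haplotype draws). The concentration value
was chosen once so that clusters are differentiated enough to give
realistic local LD while keeping the realized MAF spectrum broad.

`sampleDiseaseModel` + `simulatePhenotypes` implement a logit
case-control model with four causal sets of size 8 — `V` (synergistic
with the target, two effect vectors `β_0V`, `β_1V` for the two target
arms), `W` (marginal), `Z1`/`Z2` (paired quadratic products) — all
sampled among SNPs with MAF ≥ 0.2 outside the exclusion window, effects
i.i.d. N(0, 1). Four scenarios fix the overlaps `|V∩W|`/`|V∩Z1|` at
(0,0), (4,0), (0,4) and (2,2); the cardinalities hold exactly for every
seed (hard assertion in the tests). Since the overlap constraints leave
the choice free, the sub-selections of `V` used for the `W` and `Z1`
overlaps are drawn disjoint, and `Z2` is drawn disjoint from
`V ∪ W ∪ Z1`, so truth labels for ranking (membership of `V`) are
unambiguous. `trueEffects` returns closed-form `δ` and `μ` from the two
logit arms; the centering constant `δ₀ = E[δ(X)]` is computed by Monte
Carlo under the generating HMM (model-based centering — the natural
measure under the generator, chosen over empirical centering).

What the generator does *not* emulate: fine-scale recombination maps,
population structure and admixture, rare variants, array marker density,
genotyping error. Passing benchmarks therefore demonstrate that the
estimators recover planted synergies under realistic block-LD and
common-variant architectures, not that any absolute AUC transfers to
panels resampled from real reference haplotypes — benchmark levels are
tied to the genotype source.

## Numerical choices

* Penalty conventions follow glmnet exactly (`α = 1 - s`, loss scaled by
  `1/(2n)` for squared error), so `λ_max` is the max absolute null-model
  score coordinate divided by `1 - s`; for the weighted logistic loss
  (not pinned by any standard reference) the same null-gradient bound is
  used with weights normalized to sum to `n`.
* Supports are coefficients exceeding 1e-12 on the standardized scale;
  solver threshold 1e-10 with warm starts along the grid.
* Modal imputation breaks ties towards the smaller dosage; clustering
  merges the leftmost maximal pair on ties; both make reruns bit-identical.
* Monomorphic SNPs get HWE p = 1 by convention (the MAF filter removes
  them anyway); zero-variance columns are treated as correlation 0 in
  clustering (with a warning) and are rejected in regression designs.
* Degenerate robust denominators (all `Ã_j = ê_j`) fall back to
  `C_t = 0` with a warning; propensities are clamped to
  `[1e-6, 1 - 1e-6]` if the exclusion window ever fails to prevent
  degeneracy.
* Logistic-loss subsamples containing a single response class are
  redrawn once, then error.

## Benchmark problem sizes

`runBenchmark` mirrors the replicate-grid design of a full simulation
study at package scale. The shipped acceptance study uses scenario 4
(the hardest overlap configuration), `n = 500`, `p = 500`, 10 replicate
cohorts, generator `K = 4`, `ldJump = 0.05`, and an analysis HMM with
`K = 5` and 12 EM iterations — sizes chosen so the whole seven-method
study runs in minutes on one core while leaving each method's mean ROC
AUC clearly estimable. The sample-size study uses an easy scenario-1
design at `p = 100` with 20 replicates at `n ∈ {200, 1000}`. Full-scale
studies (e.g. `p = 5000`, 125 replicates) are a matter of passing larger
values; runtime scales roughly as `n·p` for the HMM and `N·n·p` for
stability selection.

## Known limitations

* The propensity model assumes the HMM family is adequate for the local
  LD around the target; model misspecification biases `e`, which the
  robust and shifted variants partially absorb (that is their purpose).
* OWL estimates only a sign surrogate of `δ`; its common-effects term is
  not fully filtered, and it is consistently the weakest method — kept
  for completeness and comparison.
* Scores are rankings, not calibrated tests: no per-family error control
  is attached to the stability-path areas.
* Continuous phenotypes are supported by all outcome constructions
  (non-negative for OWL), but the shipped benchmark exercises the
  case-control path.
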