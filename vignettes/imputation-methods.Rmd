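---
title: "Models, simulation protocols and design choices in ProteoImpute"
author: "ProteoImpute authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation protocols and design choices in ProteoImpute}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoImpute)
```

ProteoImpute imputes missing values in protein-level abundance matrices
(rows = samples, columns = proteins) and benchmarks imputers under
controlled missingness. This vignette explains the underlying models, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical and design choices made where the problem is
genuinely open.

## Data model and preprocessing

An `AbundanceMatrix` stores intensities (strictly positive) or log2
intensities, with `NA` as the missing mask. The standard pipeline removes
proteins with missing rates above 80% (`filterByMissingRate()`, with the
boundary retained: a protein missing exactly 80% of its entries stays),
log2-transforms, and then applies per-method scaling:

* `min2`, `mean`, `swknn` run on the log2 matrix directly;
* `pwknn` and all factorization methods (`ppca`, `nipals`, `svdimpute`,
  `svt`, `rmf`, `frmf_*`) run on the protein-standardized matrix and are
  de-standardized before evaluation;
* the CAM family runs in the original intensity space (the mixture model is
  linear in intensities; the log transform would break it).

Standardization (`standardizeProteins()`) centers each protein on its
observed mean and divides by the observed *population* (divide-by-`n`)
standard deviation. The population convention was chosen deliberately: the
NRMSE measure (below) normalizes by the population variance of the held-out
values, and using one convention throughout makes "impute every held-out
entry with their mean" give NRMSE = 1 exactly — a useful calibration point
for tests. Proteins with zero observed variance get their scale clamped to
1 with a warning rather than an error, since constant proteins are common
after aggressive filtering. Sample-wise normalization
(`normalizeSamples()`) is median centering: robust to missingness and
sufficient for the location shifts it is meant to absorb.

The half-minimum imputer deserves a note. Its classical definition halves
the minimum observed *intensity*; on log2 data that is `min − 1`. A variant
sometimes seen halves whatever value is stored, which on log2 data with
typical magnitudes around 20 produces fills ten units below the detection
limit and essentially destroys the method under MNAR. `imputeMin2()`
defaults to intensity-scale halving (`halfIn = "intensity"`), with the
stored-value rule available as `halfIn = "stored"`.

## Error measures

With Omega the set of held-out entries, `rmse()` is
`sqrt(sum((Xhat - X)^2) / |Omega|)` and `nrmse()` divides the RMSE by the
population standard deviation of the true values at Omega. `proteinNRMSE()`
computes the same quantity protein by protein (proteins with fewer than two
held-out entries or zero variance are excluded); `sor()` ranks the methods
on each protein (ascending NRMSE, average ranks on ties) and sums the ranks.
The rank sum is conserved — `sum over methods = P * M * (M+1) / 2` — which
every report is checked against. Proteins unevaluable for *any* method are
dropped for *all* methods, so the conservation law survives alignment. SOR
grows mechanically with the number of missing-bearing proteins, so SOR
values are comparable only within one missing rate, never across rates.

## Low-rank imputers

All four assume the centered data matrix is approximately low-rank.

* **`imputeSVDImpute()`** fills missing entries with protein means and
  alternates truncated SVD reconstruction with refilling until the imputed
  entries change by less than `tol` (relative Frobenius norm). Convergence
  is measured on the imputed entries only — they are the quantity of
  interest.
* **`imputeNIPALS()`** extracts components one at a time by alternating
  regressions of scores and loadings over observed entries, deflating the
  observed residual. A single sequential pass leaves a deflation bias at
  the missing positions, so after extraction the components are cyclically
  re-fitted against the residual of the others (the same alternating
  regressions, used as block coordinate descent) until the reconstruction
  at the missing entries stabilizes. On complete data the first component
  reproduces the leading SVD direction.
* **`imputePPCA()`** fits the probabilistic PCA model
  `x = W z + mu + eps`, `eps ~ N(0, sigma2 I)`, by EM on the observed
  entries. The M-step solves, per protein, a joint regression for
  `(mu_d, W_d)` on `[1, E(z)]` over the samples observing that protein;
  updating the mean *jointly* matters, because a mean fixed at the observed
  column averages lies slightly off the low-rank row space and leaves an
  irreducible noise floor. The observed-data log-likelihood is evaluated
  with the Woodbury identity, recorded per iteration, and is monotone; on
  noiseless data `sigma2` collapses, and the iteration stops at a floor of
  1e-12 where the EM guarantee would otherwise degrade.
* **`imputeSVT()`** is singular value thresholding for nuclear-norm
  matrix completion: from `Y = 0`, soft-threshold the singular values of
  `Y` by `tau`, then step `Y <- Y + delta * P_Omega(X - Xhat)`. Defaults
  `tau = 5 * sqrt(m n)` and `delta = 1.2 / observed fraction` are the
  standard heuristics; with a large `tau` the residual stays at 1 for a few
  iterations until the accumulated singular values cross the threshold,
  then decreases geometrically.

Rank is an explicit argument everywhere; the benchmark harness sweeps it
(`sweepParameters()`) rather than guessing.

## Fused regularization matrix factorization

`fitRMF()` minimizes the observed-entry squared error plus Frobenius
penalties `lambdaA ||A||^2 + lambdaS ||S||^2` by plain gradient descent;
`fitFRMF()` adds `alphaFused * sum_i sum_{k in F(i)} ||A_i - A_k||^2`. Three
choices are worth recording:

* **Exact gradients.** The implementation differentiates the stated
  objective exactly — including the `-2 * residual * S_j` factor of the
  squared-error term and the reverse edges of the (directed) neighborhood
  graph in the fused term, which enters through the Laplacian
  `L = D_out + D_in - B - B'`. Analytic gradients are verified against
  central finite differences in the test suite; a descent direction that
  drops these terms does not decrease the objective.
* **Pairwise fused penalty.** The penalty is the pairwise sum over
  neighbors, not an average over the neighborhood: since the neighborhoods
  are already size-capped at `t`, averaging only rescales `alphaFused`. The
  pairwise form is what the gradient check and the alpha = 0 degeneracy
  test pin down.
* **Step size.** Fixed step, defaulting to `0.25 / L` where `L` is a local
  Lipschitz estimate from the initialization (`2 * (2 * d1 + penalties)`,
  `d1` the leading singular value of the mean-filled matrix). If the
  objective rises five iterations in a row the step is halved, at most ten
  times. Initialization is a scaled truncated SVD of the mean-filled matrix
  plus small seed-controlled noise, so runs are reproducible and
  `fitFRMF(alpha = 0)` follows the RMF optimization path bitwise.

Neighborhoods come from cosine similarity over mutually observed entries
(`buildSimilaritySelf()`) or over complete external score vectors
(`buildSimilarityExternal()`), keeping the `t` most similar samples
(default `t = 5`); ties prefer the smaller index, isolated samples get
empty neighborhoods with a warning.

Fusion helps when dropout is structured along sample groups: if a protein
is unobserved in most of one cluster, that cluster's latent vectors are
weakly constrained and shrinking them toward their neighbors transfers
information. Under purely unstructured MCAR the fused term has little to
add and, at fixed `alpha`, RMF and FRMF perform comparably — which is why
the package's comparison runs under cluster-consistent dropout
(`injectClusterDropout()`).

## Convex analysis of mixtures

`camFit()` implements the geometric deconvolution pipeline: protein vectors
are normalized to unit sum (points on the scatter simplex in sample space),
clustered by seeded k-means (`nClusters`, default 50), and for each
candidate archetype count `k` the `k` cluster centers minimizing the
convex-reconstruction residual of *all* centers are selected by greedy
forward search plus single-swap refinement. The greedy order is nested, so
it is computed once up to `max(kCandidates)` and each `k` refines its
prefix. Convex weights (nonnegative, summing to one) are computed by
nonnegative least squares on a sum-constraint-augmented system; the
Lawson–Hanson solver is implemented in the package and returns its best
iterate on degenerate systems instead of failing. Marker proteins are the
cluster members within the `marginQuantile` (default 0.1) distance quantile
of a selected vertex. The mixing matrix `A` is estimated from marker means
on the original intensity scale, column-rescaled (again by NNLS) so rows
sum to one; profiles `S` follow by per-protein NNLS.

The archetype count is the argmin of a description-length score
(`computeMDL()`), whose two penalty terms charge `((k-1) m / 2) log(nMG)`
for the mixing proportions (estimated from the `nMG` markers) and
`(k n / 2) log(m)` for the profiles. Two fit terms are offered. The default
`"scaled"` form is the Gaussian description length
`(m n / 2) log(RSS / (m n))`, commensurate with the penalties: better fit
can pay for more archetypes, and on noiseless three-archetype data the
score reliably selects `k = 3`. The `"unscaled"` form, `(1/2) log(RSS)`, is
provided for reference: its fit term is bounded by a few dozen nats while
the penalties grow like `n * m`, so as an order selector it is monotone in
`k` and degenerate — it is kept because it is cheap to evaluate and useful
as a diagnostic of the penalty structure, but `camFit()` never selects with
it. `nMG` is the *total* marker count across archetypes.

Imputation variants: `camImputeComplete()` fits the model on the fully
observed proteins only and re-estimates every incomplete protein's profile
by NNLS over its observed samples (requiring at least
`10 * max(kCandidates)` complete proteins; proteins observed in fewer
samples than archetypes fall back to a mean fill). `camImputeHybrid()`
first completes the matrix with SVT or NIPALS on the standardized log2
scale, inverts to intensities, fits CAM on the completed matrix, and
replaces only the originally missing entries with `A S`. Reconstructed
fills that are nonpositive (possible when NNLS zeroes a profile) are
floored at half the protein's observed minimum, with a message, keeping
every imputed intensity strictly positive.

## Simulation protocols

`generateSynthetic()` draws the mixing matrix rows from a flat Dirichlet,
gives each archetype an exclusive block of marker proteins
(`markerFraction` per archetype, log-normal expression bounded away from
zero) and the remaining proteins gamma-distributed expression in all
archetypes, and multiplies `A S * intensityScale` by log-normal noise
(`exp(N(0, noiseSigma^2))`). Defaults — `noiseSigma = 0.3`,
`intensityScale = 1e6` — give intensity distributions with the order of
magnitude and multiplicative-noise character of label-free LC–MS protein
output. The optional `clusterAssignments` argument concentrates each
sample's Dirichlet weight (`clusterStrength = 8`) on an assigned archetype,
producing distinct sample groups for the fused-regularization studies.

What the generator does *not* emulate: peptide-to-protein roll-up noise,
batch effects, heteroscedasticity that depends on abundance, correlated
protein blocks beyond the archetype structure, and authentic MNAR whose
censoring threshold varies by run. Passing benchmarks on this generator
demonstrates correctness of the machinery and the direction of
method-ranking effects, not field performance on any particular instrument.

Two hiding protocols mirror the two standard evaluation settings:

* **Setting 1** (artificial missingness on complete data): `injectMCAR()`
  hides exactly `round(alpha m n)` uniform entries (redrawing, at most 100
  times, if a protein would lose all observations); `injectMNAR()` hides
  the lowest `floor(alpha m n)` values by a *global* quantile cut-off —
  deterministic, with ties broken by (row, column) order — so every hidden
  value is at most every surviving value; `injectMix()` applies the MNAR
  cut-off first (the quantile then refers to the full dataset) and MCAR on
  the survivors. The harness sweeps rates over
  `{0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5}`.
* **Setting 2** (masking on authentically incomplete data):
  `maskSetting2()` hides observed entries of each protein in proportion to
  that protein's authentic missing rate, `round(c * r_p * obs_p)` per
  protein, with the single constant `c` calibrated by bisection — plus a
  largest-remainder ±1 adjustment, since ties at rounding boundaries make
  the count a step function — so the global total equals
  `round(globalFraction * total observed)` exactly. Only formerly observed
  entries enter the ground truth (a mask landing on an already missing cell
  would contribute nothing evaluable); proteins with no authentic
  missingness receive no mask, and no protein loses its last observed
  entry. The protocol runs on the already-filtered matrix, so heavily
  missing proteins never enter.

All hiding operations return the held-out `GroundTruth` bit-exactly.

## Numerical choices and degenerate inputs

* KNN distances are Euclidean over mutually observed features, divided by
  the square root of the overlap size, so pairs with different overlaps are
  comparable; weights are `1 / (distance + 1e-9)`; equidistant neighbors
  prefer the smaller index; entries with no candidate neighbor fall back to
  the protein mean, with a message. Correlation distance was considered and
  left out: on standardized data it ranks neighbors nearly identically.
* Convergence tolerances: 1e-6 (relative) for the EM/alternating methods,
  1e-4 relative observed residual for SVT, matching each method's
  convergence speed; all caps (`maxIter`) return the last iterate with a
  warning rather than erroring.
* Read/write round-trips are bit-exact: values are printed with 17
  significant digits; `"NA"`, `"NaN"` and empty cells parse as missing;
  duplicate ids and nonpositive intensities are validation errors that name
  the offending cell.
* Test and example problem sizes (50 × 300 recovery fixtures, 40 × 200
  benchmark matrices, 10-seed Monte-Carlo loops) were chosen as the
  smallest sizes at which the compared methods separate cleanly; all suite
  fixtures are generated in code at run time.

## Limitations

Imputation accuracy is always assessed on artificial or masked values,
never on authentic missing values, whose mechanism is unknowable from the
observed data; rankings obtained here transfer to real data only insofar as
the assumed mechanism does. The CAM pipeline assumes enough fully observed
(or well-completed) proteins to expose the simplex geometry and degrades
when markers themselves are missing. FRMF's benefit depends on real sample
structure in the similarity source; with uninformative neighborhoods the
fused term is a mild shrinkage. The benchmark harness evaluates one space
per run (log2, or intensity for CAM comparisons) and never mixes spaces
within a ranking.
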