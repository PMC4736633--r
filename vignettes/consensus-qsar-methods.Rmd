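---
title: "Methods: consensus QSAR modelling of acute oral toxicity with relevance vector machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus QSAR modelling of acute oral toxicity with relevance vector machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvmtox)
```

## The modelling problem

rvmtox predicts a continuous molecular toxicity endpoint — an acute oral
toxicity potency on the pLD50 scale, log[1/(mol/kg)], where higher means
more toxic — from chemical structure alone. The approach is a consensus
QSAR workflow: molecules are encoded as descriptor and fingerprint
vectors, several regression models are trained on the same selected
feature set, their predictions are averaged with equal weights, and the
spread of the ensemble predictions for each molecule delimits the
applicability domain of the consensus. A final interpretation stage mines
the fingerprint bits and ring scaffolds for structural alerts.

The package's core estimator is the relevance vector machine; the other
learners (inverse-distance kNN, random forest, RBF support vector
regression, gradient boosting) are baselines riding on established
implementations behind one uniform interface.

## The relevance vector machine

`rvm()` fits sparse Bayesian kernel regression. The regression function is
a kernel expansion over the training inputs plus a bias,

$$y(x) = w_0 + \sum_{n=1}^{N} w_n K(x, x_n),$$

with Gaussian noise of precision $\beta$ and independent zero-mean
Gaussian priors $w_i \sim N(0, \alpha_i^{-1})$. For fixed hyperparameters
the weight posterior is Gaussian,

$$\Sigma = (\beta \Phi^\top \Phi + A)^{-1}, \qquad
  \mu = \beta\, \Sigma\, \Phi^\top t, \qquad A = \mathrm{diag}(\alpha),$$

where $\Phi$ is the $N \times (N+1)$ design matrix with a leading column
of ones. Hyperparameters are re-estimated by the type-II
maximum-likelihood fixed point

$$\gamma_i = 1 - \alpha_i \Sigma_{ii}, \qquad
  \alpha_i \leftarrow \gamma_i / \mu_i^2, \qquad
  \beta \leftarrow \frac{N - \sum_i \gamma_i}{\|t - \Phi\mu\|^2},$$

and the two steps alternate until the largest $|\Delta \log \alpha_i|$
falls below `tol`. Bases whose precision diverges are pruned; the kernel
centers that survive are the relevance vectors. Predictions carry error
bars: the predictive variance is $1/\beta + \phi(x_*)^\top \Sigma\,
\phi(x_*)$, never below the noise floor.

Numerical choices:

* The normal-equation solve uses a Cholesky factorization with jitter
  escalation ($0 \to 10^{-10} \to 10^{-8} \to 10^{-6}$) because
  $\beta\Phi^\top\Phi + A$ becomes ill-conditioned near convergence; an
  unsalvageable system raises an error carrying a condition-number
  estimate.
* `prune_threshold = 1e9` on $\alpha$ operationalizes "$\alpha_i$
  increasing toward infinity"; `tol = 1e-3`; `max_iter = 1000`.
* $\beta$ is clamped at $10^{12}$ so noiseless (interpolable) targets do
  not divide by a zero residual; a basis with $\mu_i = 0$ exactly is
  assigned the prune threshold and dies.
* Initialization is $\alpha_i = 1/N^2$ and $\beta = 1/(0.1\,
  \mathrm{var}(t))$, a common weakly-informative starting point; the
  fixed point is insensitive to it on all benchmarks in the test suite.
* The algorithm is fully deterministic; two fits on the same data are
  bit-identical.

Kernels: Laplacian $\exp(-\sigma\|x-y\|)$ (default width 0.044), RBF on
the squared distance, and linear. Exponential-kernel widths are quoted in
two conventions in the QSAR literature — dividing by $\sigma$ or
multiplying by it. Both are implemented (`parameterization = "divide"` /
`"multiply"`); multiply is the default because a width of 0.044 only
makes sense in that form on standardized descriptors: $\exp(-d/0.044)$
would zero out every off-diagonal kernel entry. For the same reason the
kernel always operates on the standardized feature space — `rvm()`
standardizes internally by default and stores the constants in the model,
so serialized models are self-contained (`write_rvm()`/`read_rvm()`
round-trip bit-exactly via hex-float encoding).

## Feature engineering

* **Descriptors.** The registry (`descriptor_registry()`) holds 27
  two-dimensional/topological descriptors computed from OpenBabel
  properties and the hydrogen-suppressed connection table: mass, logP,
  TPSA, molar refractivity, H-bond counts, element counts, ring counts,
  connectivity and Kier shape/flexibility indices, an ESOL-style
  intrinsic solubility estimate, and a Zhao-type atomic-contribution van
  der Waals volume. Commercial-toolkit descriptor names common in the
  toxicity QSAR literature map onto these analogues via
  `moe_descriptor_map()`; no numeric parity with commercial
  implementations is claimed. 3-D descriptors (principal moments,
  force-field energies) are deliberately absent: they would require an
  embedding step whose determinism cannot be guaranteed across toolkit
  builds, and the modelling method is descriptor-agnostic.
* **Fingerprints.** Dictionary-based substructure bits: bit $i$ is 1 iff
  a SMARTS pattern matches or an element-count rule holds. Two curated
  dictionaries ship with the package — a PubChem-style subset (50 bits)
  and a substructure-key subset (70 bits) — covering the published
  toxicity-alert bits under their original identifiers (e.g. the
  trifluoromethyl key SubFP294, printed-SMARTS verbatim) plus generic
  functional-group chemistry. A full 881-bit dictionary can be supplied
  as a plain-text file in the same format.
* **Cleaning.** `parse_and_clean()` keeps molecules that parse, are
  unique by canonical SMILES (first occurrence wins, a deterministic
  choice) and lie inside the activity band [0, 7] — values outside that
  band sit far from the bulk of oral acute toxicity data and are treated
  as data errors. Every rejection is logged with a reason code
  (`parse_fail`, `duplicate`, `activity_range`, `descriptor_fail`).
* **Redundancy filter.** `filter_features()` removes zero-variance
  columns, then scans in descending variance order and drops any column
  with |Pearson r| > 0.95 to an already-kept column. Ties in variance
  break on C-locale byte order of the names, making the result invariant
  to input column order. In `run_workflow()` this filter applies to the
  descriptor block only: fingerprints are a separate representation that
  joins at feature selection, and only constant bits are dropped there.

## Feature selection

`rank_and_select()` ranks features by Cramér's V between the binned
feature and the binned activity: the activity is cut into 5
equal-frequency classes and continuous features into 10 equal-frequency
bins (binary bits keep their native levels), the chi-squared statistic
$\chi^2 = \sum_{ij}(O_{ij}-E_{ij})^2/E_{ij}$ is computed without
continuity correction, and

$$V = \sqrt{\frac{\chi^2/n}{\min(r-1,\,c-1)}} \in [0, 1].$$

The denominator uses the standard $\min(r-1, c-1)$; a printed form with
an ambiguous $\min(k-1)$ can exceed 1 and is not used. The top-k features
by V are selected (ties break lexicographically). Expected counts below 5
are recorded as a diagnostic, not an error: the statistic serves as a
ranking heuristic, not inference, so no p-values are attached. Bin counts
are exposed in the configuration (`target_bins`, `feature_bins`).

## Baseline learners and consensus

All learners sit behind `learner_spec()`/`fit_learner()`/`predict()`.
Default hyperparameters follow the published consensus-toxicity settings:
RF with 230 trees and 105 candidate predictors per split, RBF SVM with
width 0.03125, cost 2, $\varepsilon$ = 0.05, gradient boosting with
shrinkage 0.1, depth 7, 69 rounds, kNN with k in 1–10 (default 5) and
inverse-distance weighting (ties at the k-th distance include all tied
neighbors; zero-distance queries return the mean of their exact matches).
Stochastic learners are seeded and refit bit-identically. Learners that
would add bulk without method coverage (local approximate GP, perceptron
ensembles) are not re-implemented; `register_learner()` lets external
implementations join the roster and hence the consensus.

`consensus_predict()` averages the per-model predictions with equal
weights. `std_dm()` is the per-molecule sample standard deviation (over
the $M$ models, divisor $M-1$) of those predictions — the
ensemble-disagreement distance-to-model. The applicability domain
(`ad_assess()`) calibrates a reference level as the mean training-set
STD-DM and flags a molecule in-domain when its STD-DM is at most
`multiplier` (default 3) times that reference; coverage is the percentage
of test molecules inside. Basing the reference on the training population
is the simplest consistent reading of a "margin of three times the
STD-DM value"; both the reference statistic and the multiplier are
config-exposed.

## Evaluation

`metrics_report()` collects $R^2$ (squared Pearson correlation),
$R^2_{adj} = 1 - (1-R^2)(n-1)/(n-p-1)$, tenfold cross-validated
$q^2 = (SST - PRESS)/SST$ with target-stratified folds, external
$q^2_{ext} = 1 - SSE/SST$ on the held-out set, RMSE and MAE. A model is
flagged over-fitted when $R^2_{adj} - q^2_{ext} > 0.3$, and acceptable
when $q^2 \ge 0.5$ and $q^2_{ext} \ge 0.5$. The parameter count $p$ in
$R^2_{adj}$ is not well defined for kernel and ensemble learners, so the
workflow charges the number of selected features (capped at $n-2$); this
is conservative and configurable. Paired model comparisons use the
two-sided Wilcoxon signed-rank test on absolute errors — exact
distribution up to 25 informative pairs, normal approximation with
continuity correction above.

## Interpretation

* `sensitivity_1d()`: vary one feature over an equally spaced grid of 7
  values spanning its observed range, hold the others at their median
  (medians resist the skew typical of molecular descriptors), score by
  the variance of the model response, normalize scores to sum to 1.
* `fragment_contribution()`: among molecules carrying a fingerprint bit,
  count activities at or above the alert threshold (default pLD50 = 3)
  versus below; a strict majority above marks a positive alert, below a
  negative one, a tie is flagged undetermined.
* `stepwise_r2adj_delta()`: the adjusted-$R^2$ change when adding one
  candidate column to an OLS base model, with a collinearity flag from
  the rank of the augmented fit. The base set is the currently selected
  feature set minus the candidate.
* `error_scaffold_table()`: molecules whose absolute error exceeds 1.0
  are reduced to Murcko frameworks (ring systems plus linkers; computed
  by iterative terminal-atom pruning to the 2-core, re-attaching atoms
  double- or triple-bonded to the core, then canonicalizing). Frameworks
  shared by at least two large-error molecules are tabulated with their
  training/test memberships — scaffolds that are rare in training data
  flag coverage gaps rather than model defects.

## Synthetic data: what it emulates and what it does not

All tests run on seeded generators (`gen_sinc`, `gen_feature_table`,
`gen_toy_molecules`); no external dataset is bundled or downloaded.

* `gen_sinc(n, noise_sd, seed)` is the standard sparse-regression
  benchmark for the RVM machinery.
* `gen_feature_table()` plants a known number of informative features in
  an iid feature matrix (half binarized, mimicking fingerprint bits) with
  a signed linear activity — ground truth for selection and metrics.
* `gen_toy_molecules(n, seed)` assembles real, parseable SMILES from a
  fragment grammar: seven mono-/bicyclic cores carrying 0–3 substituents
  from a 12-fragment vocabulary, with activity
  $2.5 + 1.5\,[\mathrm{CF_3}] + 0.6\,[\mathrm{alkyl F}] -
  0.8\,[\mathrm{C{=}N}] + 0.3\,\mathrm{rings} + N(0, 0.3)$.
  The CF3 boost is the planted positive alert; the effect sizes were
  chosen once so that recovery at n = 400 is reliable but not trivial
  against the 0.3 noise, and activities stay inside the [0, 7] cleaning
  band. The grammar is broad enough that a 400-molecule request yields
  roughly 250–280 unique structures after canonical-SMILES
  deduplication; the cleaning stage removes the repeats, exactly as it
  would on a real library.

What passing on these generators shows: the machinery — equations,
filters, ranking, averaging, domain logic, alert mining — does what it
claims on data whose truth is known. What it does not show: performance
on real chemistry. Real descriptor blocks are strongly collinear in ways
the iid generator is not; real structure–activity landscapes have
activity cliffs, assay noise far from Gaussian, and scaffold clusters
that violate the exchangeability the stratified split relies on.
Benchmark statistics on the published 7314-compound rat LD50 set are
therefore out of scope here; the workflow accepts such a set as a plain
CSV and reproduces the computation when the data are available.

## Problem sizes and reproducibility

The shipped test-suite and acceptance sizes are: 50 random instances for
the posterior-oracle check, the sinc benchmark at n = 100 over 10 seeds,
feature-selection recovery at n = 2000, p = 100 over 20 seeds with 1000
brute-force contingency checks, 100 random prediction matrices for the
consensus bound, 20 seeds for domain coverage, and 20 end-to-end runs of
the full workflow on 400-molecule toy sets. The end-to-end runs skip the
tenfold cross-validation loop (`cv_folds = 0`) — $q^2_{ext}$, the
quantity under test, does not depend on it — while single-run examples
keep `cv_folds = 10`.

Every stochastic stage derives its seed from one master seed via
`derive_seed(master, stage)`, a documented mixing rule; reruns with the
same configuration are numerically identical, and generators restore the
caller's RNG state.

## Known limitations

* Descriptors are open-toolkit analogues; models trained on them are not
  numerically transferable to descriptor sets from commercial software.
* The bundled dictionaries are curated subsets (120 bits in total), not
  the full 881/307-bit sets; alert mining can only fire on bits that are
  in the dictionary.
* Murcko frameworks are the only scaffold representation; ring-assembly,
  bridge-assembly and side-chain decompositions are not implemented.
* Single-learner applicability domains are not provided; STD-DM needs an
  ensemble, and the package keeps that requirement explicit.
* The RVM solves a dense $(N+1)$-basis system per sweep; training is
  comfortable to a few thousand molecules but is not engineered for very
  large libraries.
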