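---
title: "Deep kernel and kernel mixed models for multi-environment genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep kernel and kernel mixed models for multi-environment genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepkernGP)
```

## The prediction problem

Genomic selection predicts the genetic merit of breeding lines that have been
genotyped but not (fully) phenotyped. In multi-environment trials the
difficulty is compounded by genotype-by-environment (G×E) interaction: the
ranking of lines changes across irrigation regimes, planting systems and
years. `deepkernGP` implements kernel mixed models for this setting, with
three exchangeable notions of genomic similarity:

* **GB** — the linear GBLUP relationship matrix \(G = XX'/p\), where \(X\) is
  the column-standardized \(n \times p\) marker matrix. GB captures additive
  signal only.
* **GK** — the Gaussian kernel \(\exp(-h\, d_{ii'}^2 / q)\), where
  \(d_{ii'}^2 = \sum_k (x_{ik} - x_{i'k})^2\), \(q\) is the median
  off-diagonal squared distance and \(h > 0\) a bandwidth. Dividing by \(q\)
  standardizes the distance scale, so one bandwidth grid transfers across
  data sets.
* **AK** — the arc-cosine kernel
  \(AK^{(1)}(x_i, x_{i'}) = \tfrac{1}{\pi}\lVert x_i\rVert\,\lVert x_{i'}\rVert\,
  J(\theta_{ii'})\), with \(\theta_{ii'}\) the angle between the two marker
  vectors and \(J(\theta) = \sin\theta + (\pi - \theta)\cos\theta\). This is
  exactly the covariance function of an infinitely wide one-hidden-layer
  ramp (ReLU) network: \(2\,E[\max(0, w\!\cdot\!x_i)\max(0, w\!\cdot\!x_{i'})]\)
  over standard normal weights \(w\) — a property the test suite verifies by
  Monte Carlo. A recursion re-normalizes the kernel to correlation form and
  re-applies \(J\), emulating one additional hidden layer per step
  (`ak_recurse()`); the diagonal is invariant under this recursion, and
  unlike GK the AK diagonal is heterogeneous (lines have unequal prior
  genetic variances).

All three constructors consume the same standardized marker matrix. For AK
the literature does not pin down the input scaling, and the kernel is
norm-dependent, so sharing one \(X\) across GB/GK/AK was chosen to keep the
methods comparable; this is a package convention, not a mathematical
necessity.

## The mixed models

For a single environment,
\(y = \mu 1 + u + \varepsilon\), with \(u \sim N(0, \sigma_u^2 K)\),
\(\varepsilon \sim N(0, \sigma_\varepsilon^2 I)\), and \(K = Z_g G Z_g'\)
the chosen kernel expanded to observation level. For the multi-environment
model,
\[
y = Z_E \beta_E + u_1 + u_2 + \varepsilon, \qquad
u_1 \sim N(0, \sigma_{u_1}^2 K_1), \quad
u_2 \sim N(0, \sigma_{u_2}^2 K_2),
\]
where \(K_1 = Z_g G Z_g'\) carries genomic main effects across all
environments and \(K_2 = K_1 \circ Z_E Z_E'\) (Hadamard product) confines
genomic covariance to pairs of observations in the same environment — the
standard G×E interaction kernel, PSD by the Schur product theorem.

### Estimation

Everything is estimated by maximum marginal likelihood, which is
deterministic and directly comparable across kernels and layer counts — the
reason model selection below can use a single likelihood number per
candidate. Design choices that matter numerically:

* **Single-kernel fits** eigendecompose \(K\) once and profile the
  likelihood over \(\lambda = \sigma_u^2/\sigma_\varepsilon^2\); \(\mu\) and
  \(\sigma_\varepsilon^2\) have closed forms at each \(\lambda\). The
  profile can be **bimodal** — an interior mode plus a slowly rising tail
  toward the \(\sigma_\varepsilon^2 \to 0\) boundary — so the optimizer
  scans a 61-point grid of \(\log\lambda \in [-25, 25]\) first and then
  refines the best bracket with golden-section search. A plain unimodal
  search can silently return the boundary and badly inflate
  \(\hat\sigma_u^2\).
* **Multi-kernel fits** profile the fixed effects by GLS inside each
  likelihood evaluation and optimize the log-variances by L-BFGS-B with the
  analytic gradient of the profiled likelihood,
  \(\partial \ell / \partial \sigma_r^2 =
  -\tfrac12\{\mathrm{tr}(\Sigma^{-1} K_r) - \hat r' \Sigma^{-1} K_r
  \Sigma^{-1} \hat r\}\). Three starting points (balanced, mostly residual,
  mostly genetic) guard against local optima; the best final likelihood is
  kept. Variances are floored at `1e-10`, which also acts as the boundary
  representation of a zero component.
* Fixed effects use one intercept per environment (cell means); the reported
  `mu` is their average. Additional fixed effects are out of scope.
* The reported `logML` is always recomputed exactly (dense Cholesky form) at
  the returned parameters, so it matches a dense multivariate-normal density
  evaluation to numerical precision regardless of optimizer tolerances.

### Heritability

The literature this package follows reports narrow-sense heritabilities from
the full model without printing a formula. The convention adopted here is
\(h^2 = \sigma_{u_1}^2 / (\sigma_{u_1}^2 + \sigma_{u_2}^2 +
\sigma_\varepsilon^2)\) for the multi-environment model and
\(\sigma_u^2/(\sigma_u^2 + \sigma_\varepsilon^2)\) for the single-kernel
model; `heritability()` documents it as a package convention.

### Prediction

`predict_cells()` uses the conditional-Gaussian (BLUP) identity
\(\hat y_U = f_U + C_{UT}(C_{TT} + \sigma_\varepsilon^2 I)^{-1}(y_T - f_T)\)
at the fitted variance components, with the joint covariance rebuilt from
the line-level kernel, so any genotyped line can be predicted in any
environment without retraining.

## Model selection

The arc-cosine depth \(l\) and the Gaussian bandwidth \(h\) are selected by
maximizing the marginal likelihood over candidates
(`select_ak_layers()`, `select_gk_bandwidth()`); exact ties break toward the
simpler candidate (fewer layers, smaller bandwidth). Defaults are
\(l \in 1..8\) and \(h \in \{0.1, 0.25, 0.5, 0.75, 1, 1.5, 2.5, 5\}\); the
bandwidth grid is a package default chosen to span two orders of magnitude
around the \(q\)-standardized scale, and both are configurable. Inside
cross-validation, selection runs once per training portion of each fold
(not nested CV), and under the same model that is being evaluated — when
the G model is scored, \(l\) and \(h\) are selected under the G model for
that environment's training lines. Whether selection should instead be done
under a fixed reference model is genuinely open; selecting under the model
being evaluated is the self-consistent choice and is what the benchmark
implements.

## Sparse-testing cross-validation (CV2)

`make_cv2_plan()` partitions the lines of **each environment
independently** into \(k = 5\) folds per replicate. A line masked in one
environment therefore remains observed in most others — exactly the sparse
testing situation breeders face in incomplete trial networks. Masking
applies to phenotypes only; genomic kernels are built once from all
genotyped lines, which is standard genomic-prediction practice and leaks no
phenotypic information. `run_benchmark()` evaluates every requested method
and model on **identical masks**, scores masked cells by MSEP per
environment, and reports means and standard deviations across partitions
(SD is this package's convention for the spread statistic; per-partition
records are retained so any other summary can be recomputed). A
perturbation test in the suite verifies that modifying a masked phenotype
changes no trained model.

## The neural-network baseline

The comparison baseline is a feed-forward network with ReLU hidden layers,
dropout, a linear output, mean-squared-error loss and RMSprop
(\(\rho = 0.9\), \(\epsilon = 10^{-7}\), step size 0.001), batch size 56.
The canonical tuning grid is 1–4 hidden layers × {80, 160, 240, 320, 400}
units × dropout {0, 0.05, 0.10, 0.20, 0.25, 0.35} — 120 configurations —
scored by inner fivefold CV and refit on the full training data; ties break
toward the simpler network. The engine is implemented in base R matrix code
(forward/backward passes with inverted dropout), which keeps the package
dependency-free and is entirely adequate at the data sizes kernel methods
target. Two numerical choices:

* the response is centered on its training mean during optimization (added
  back at prediction), because with a step size of 0.001 the output bias
  would otherwise need thousands of updates just to reach a yield-scale
  mean;
* epochs (default 1000) and the grid are reducible through
  `benchmark_control()`; the full grid at 1000 epochs is the faithful
  profile and is deliberately slow.

For multi-environment fits the markers are concatenated with one-hot
environment indicators (`build_feature_matrix()`); per-environment networks
are the alternative the single-environment model uses. Either encoding is a
convention — the source literature does not specify one.

## The synthetic generator

`simulate_genotypes()` draws allele frequencies uniformly on
\([0.05, 0.5]\), dosages Binomial(2, freq) independently per line, and
masks calls at a configurable missing rate. `simulate_phenotypes()` builds

* a genomic main effect \(u_1\): additive marker effects plus, optionally, a
  pairwise-epistatic component formed from products of randomly paired
  standardized markers — the kind of non-additive signal nonlinear kernels
  are claimed to exploit; \(u_1\) is rescaled to exactly its target
  variance so recovery tests have a sharp truth;
* an independent G×E deviation per environment,
  \(u_2^{(e)} \sim N(0, \sigma_{u_2}^2 G)\) — independence across
  environments is the simplest structure consistent with the block pattern
  of \(K_2\);
* i.i.d. residual noise, and per-environment intercepts defaulting to
  (6, 5.5, 3.5, 4) ton/ha, emulating two irrigated and two drought-stressed
  management regimes.

Default variances (1, 0.3, 0.4) put per-environment heritability near 0.59,
inside the 0.45–0.75 band typical of elite yield trials. What the generator
does **not** emulate: linkage disequilibrium between markers (draws are
independent), allele-frequency spectra shaped by selection, pedigree
structure, and spatial field trends. Consequently, passing tests demonstrate
the correctness and the qualitative behavior of the machinery — not field
predictive accuracy on real trials.

One practical consequence of i.i.d. markers is worth recording: with
\(p \gg n\) the simulated relationship matrix has an over-regular
(Marchenko–Pastur) spectrum with no near-zero eigenvalues, which genuinely
weakens the identifiability of \(\sigma_\varepsilon^2\) against
\(\sigma_u^2\) and can push maximum likelihood to the
\(\sigma_\varepsilon^2 = 0\) boundary. Real genomic relationship matrices,
with LD-induced low effective dimension, do not behave this way. The
variance-recovery studies therefore use \(p \le 2n\), where the simulated
spectrum (some near-zero eigenvalues) resembles real kernels.

## Problem sizes used by the test suite

All stochastic checks run at desk scale, chosen so the full suite completes
in minutes while leaving each effect clearly detectable: kernel identity and
likelihood-oracle fixtures use 2–25 lines; variance-component recovery uses
n = 500 lines (single kernel, 100 replicates) and n = 200 lines × 4
environments (null-G×E check, 100 replicates); the benchmark-ordering
studies use 100 lines × 300 markers × 4 environments with 20 paired CV2
partitions, arc-cosine depth up to 3 and a 3-point bandwidth grid. The
acceptance script uses the same scale with 15 partitions and a reduced
4-configuration network grid at 200 epochs.

## Known limitations

* Maximum likelihood, not REML: variance estimates carry the usual small
  downward bias from estimated fixed effects (negligible here with at most
  one intercept per environment).
* Marginal-likelihood values are comparable across kernels within this
  package, but their absolute level depends on the ML convention; other
  implementations may differ by constants while agreeing on the argmax.
* CV1 (never-phenotyped lines), leave-one-environment-out and
  forward-in-time validation schemes are not implemented.
* Multi-trait models, Bayesian uncertainty intervals and pedigree kernels
  are out of scope.
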