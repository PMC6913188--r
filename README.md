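# deepkernGP

Kernel mixed models for genome-based prediction of quantitative traits in
multi-environment breeding trials — for breeders and quantitative
geneticists who want to predict the performance of genotyped lines in
environments where they were never phenotyped (sparse testing), and to
compare additive, nonlinear-kernel and neural-network prediction machinery
on identical cross-validation partitions.

## What it implements

Three genomic similarity kernels over a standardized marker matrix
*X* (n lines × p markers):

* **GB** (GBLUP): the linear relationship matrix *G = XX′/p* — additive
  signal only;
* **GK** (Gaussian kernel): *exp(−h·d²ᵢᵢ′/q)* with squared Euclidean marker
  distances *d²*, the median off-diagonal distance *q* as normalizer and a
  bandwidth *h* chosen by marginal likelihood over a standardized grid;
* **AK** (arc-cosine "deep" kernel):
  *AK¹(xᵢ, xᵢ′) = (1/π)·‖xᵢ‖‖xᵢ′‖·[sin θ + (π − θ)cos θ]* — exactly the
  covariance of an infinitely wide one-hidden-layer ReLU network — deepened
  one emulated hidden layer at a time by a recursion, with the layer count
  chosen by marginal likelihood.

These kernels enter Gaussian-process mixed models: the single-environment
model *y = μ1 + u + ε* with *u ~ N(0, σ²ᵤK)*, and the G×E model
*y = Z_E β_E + u₁ + u₂ + ε* with main-effect covariance *K₁ = Z_g G Z_g′*
and interaction covariance *K₂ = K₁ ∘ Z_E Z_E′* (Hadamard product). All
fits are exact maximum marginal likelihood; predictions for unobserved
line × environment cells use the conditional-Gaussian (BLUP) formula.
A CV2 sparse-testing harness partitions each environment's lines into
five folds, masks test cells for all methods identically, and reports
MSEP per environment. A tunable feed-forward neural network (ReLU,
dropout, RMSprop, batch 56) serves as the deep-learning baseline, and a
synthetic genotype/phenotype generator makes the whole stack testable
without any external data.

## Worked example

```r
library(deepkernGP)

cfg  <- sim_config(n_lines = 120, n_markers = 400, missing_rate = 0.1,
                   n_envs = 4, var_gxe = 0.4, var_error = 0.5, seed = 11)
geno <- simulate_genotypes(cfg)
qc   <- qc_filter(geno, maf_min = 0.05, max_missing_marker = 0.60,
                  min_called_per_line = 100)
#> QC: dropped 2 markers (MAF < 0.05), 0 markers (missing > 0.6),
#>     0 lines (<= 100 called); kept 120 lines x 398 markers
X    <- impute_and_scale(qc, "standardized")
sim  <- simulate_phenotypes(qc, cfg)

G   <- linear_kernel(X)
inc <- build_incidence(sim$pheno, X$line_ids)
K1  <- expand_main_kernel(G, inc)
K2  <- gxe_kernel(K1, inc)
fit <- fit_multi_kernel(sim$pheno$value, list(u1 = K1, u2 = K2), ZE = inc$ZE)
fit
#> kernel_fit (multi model): logML = -726.4215, converged = TRUE
#> variance components:
#>       u1       u2 residual
#> 1.153481 0.275003 0.511269
heritability(fit)
#> [1] 0.595
```

The fitted components sit close to the simulated truth (1, 0.4, 0.5), and
the heritability estimate 0.595 matches the generator's target
1/(1 + 0.4 + 0.5) ≈ 0.53 up to sampling noise. Selecting the arc-cosine
depth for one environment:

```r
env1 <- sim$pheno$env == "ENV1"
y1 <- sim$pheno$value[env1][match(X$line_ids, sim$pheno$line[env1])]
select_ak_layers(y1, X, model = "g", l_max = 4)
#> selection_trace (AK layers): chosen = 1
#>   candidate     logML converged chosen
#> 1         1 -206.0833      TRUE   TRUE
#> 2         2 -206.7474      TRUE  FALSE
#> 3         3 -207.3366      TRUE  FALSE
#> 4         4 -207.8295      TRUE  FALSE
```

On this additive-plus-G×E simulation one layer suffices — deeper layers
lower the marginal likelihood. Benchmarking all kernels on identical CV2
partitions:

```r
plan <- make_cv2_plan(X$line_ids, pheno_envs(sim$pheno), k = 5,
                      replicates = 2, seed = 12)
res <- run_benchmark(sim$pheno, X, plan, methods = c("GB", "GK", "AK"),
                     models = c("G", "E+G+GE"),
                     control = benchmark_control(ak_l_max = 3,
                                                 gk_grid = c(0.5, 1, 2.5)))
res
#> cv_result: 5 folds x 2 replicates
#>  method  model environment msep_mean   msep_sd n_partitions
#>      AK E+G+GE        ENV1  1.114675 0.3143753           10
#>      GB E+G+GE        ENV1  1.106869 0.3162819           10
#>      GK E+G+GE        ENV1  1.104377 0.3079240           10
#>      AK      G        ENV1  1.728800 0.2847893           10
#>      GB      G        ENV1  1.736862 0.2628703           10
#>      GK      G        ENV1  1.751333 0.2895063           10
#>  ... (remaining environments omitted)
```

The G×E model (`E+G+GE`) beats the per-environment model (`G`) by a wide
margin in every environment — held-out cells borrow information from the
same line's records in other environments. MSEP is on the squared trait
scale (here (ton/ha)²); lower is better.

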