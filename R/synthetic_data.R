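#' Simulation settings for synthetic genotypes and phenotypes
#'
#' Defaults emulate a multi-environment elite-wheat trial: ~500 lines scored
#' on biallelic markers with minor allele frequency above 0.05 and a
#' substantial missing-call rate, four managed environments with distinct
#' mean yields (ton/ha), an additive (optionally partly epistatic) genomic
#' main effect shared across environments, an independent G-by-E deviation
#' per environment, and residual noise sized so per-environment narrow-sense
#' heritabilities land around 0.5-0.7.
#'
#' @param n_lines Number of lines (default 500).
#' @param n_markers Number of markers (default 2000).
#' @param maf_range Allele-frequency range markers are drawn from
#'   (default `c(0.05, 0.5)`).
#' @param missing_rate Fraction of calls masked as missing (default 0.1).
#' @param n_envs Number of environments (default 4).
#' @param env_means Per-environment intercepts in trait units; default
#'   `c(6, 5.5, 3.5, 4)` ton/ha (two irrigated, two drought-stressed levels).
#' @param var_additive Variance of the genomic main effect u1 (default 1).
#' @param var_epistatic Fraction of `var_additive` carried by pairwise
#'   marker-product (epistatic) effects rather than additive effects
#'   (default 0).
#' @param var_gxe Variance of the per-environment G-by-E deviation
#'   (default 0.3).
#' @param var_error Residual variance (default 0.4). With the defaults
#'   `h2 = 1 / (1 + 0.3 + 0.4) = 0.59`.
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lines = 500L, n_markers = 2000L,
                       maf_range = c(0.05, 0.5), missing_rate = 0.1,
                       n_envs = 4L, env_means = NULL,
                       var_additive = 1, var_epistatic = 0, var_gxe = 0.3,
                       var_error = 0.4, seed = 1L) {
  if (is.null(env_means))
    env_means <- rep_len(c(6, 5.5, 3.5, 4), n_envs)
  stopifnot(n_lines >= 2L, n_markers >= 1L, n_envs >= 1L,
            length(env_means) == n_envs,
            maf_range[1L] > 0, maf_range[2L] <= 0.5,
            maf_range[1L] <= maf_range[2L],
            missing_rate >= 0, missing_rate < 1,
            var_additive >= 0, var_epistatic >= 0, var_epistatic <= 1,
            var_gxe >= 0, var_error >= 0)
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers),
                 maf_range = maf_range, missing_rate = missing_rate,
                 n_envs = as.integer(n_envs), env_means = env_means,
                 var_additive = var_additive, var_epistatic = var_epistatic,
                 var_gxe = var_gxe, var_error = var_error,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate biallelic genotype calls
#'
#' Per marker, an allele frequency is drawn uniformly from `maf_range`;
#' dosages are then Binomial(2, freq) independently per line, and calls are
#' masked as missing uniformly at random at `missing_rate`.
#'
#' @param cfg A `sim_config`.
#' @return A `raw_genotypes` object.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_lines; p <- cfg$n_markers
  freq <- stats::runif(p, cfg$maf_range[1L], cfg$maf_range[2L])
  calls <- matrix(stats::rbinom(n * p, 2L, rep(freq, each = n)), n, p)
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(n * p) < cfg$missing_rate
    calls[mask] <- NA_integer_
  }
  new_raw_genotypes(calls,
                    line_ids = sprintf("L%04d", seq_len(n)),
                    marker_ids = sprintf("M%05d", seq_len(p)))
}

#' Simulate multi-environment phenotypes with G-by-E structure
#'
#' Builds, per line, a genomic main effect `u1` (additive marker effects plus
#' an optional epistatic component from products of randomly paired markers;
#' the realized variance of `u1` is rescaled to exactly `var_additive`),
#' draws a per-environment G-by-E deviation `u2 ~ N(0, var_gxe * G)`
#' (independent across environments, `G` the additive relationship matrix),
#' and sets `y(line, env) = env_mean + u1 + u2 + e` with
#' `e ~ N(0, var_error)` record by record.
#'
#' @param g A `raw_genotypes` object (missing calls are mean-imputed).
#' @param cfg The `sim_config` used (its phenotype draws use `seed + 1`).
#' @return List with `pheno` (a complete `phenotype_table`) and `truth`
#'   (per-line `u1`, per-cell `u2` and noise, realized variance components and
#'   per-environment heritabilities).
#' @export
simulate_phenotypes <- function(g, cfg) {
  stopifnot(inherits(g, "raw_genotypes"), inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  X <- impute_and_scale(g, "standardized")
  n <- nrow(X$X); p <- X$p
  m <- cfg$n_envs
  env_labels <- paste0("ENV", seq_len(m))

  f_epi <- cfg$var_epistatic
  u_add <- drop(X$X %*% stats::rnorm(p))
  u_add <- scale_to_var(u_add, cfg$var_additive * (1 - f_epi))
  if (f_epi > 0) {
    pairs <- cbind(sample.int(p, p, replace = TRUE),
                   sample.int(p, p, replace = TRUE))
    same <- pairs[, 1L] == pairs[, 2L]
    pairs[same, 2L] <- (pairs[same, 2L] %% p) + 1L
    E <- X$X[, pairs[, 1L], drop = FALSE] * X$X[, pairs[, 2L], drop = FALSE]
    u_epi <- scale_to_var(drop(E %*% stats::rnorm(ncol(E))),
                          cfg$var_additive * f_epi)
  } else u_epi <- numeric(n)
  u1 <- u_add + u_epi

  u2 <- matrix(0, n, m)
  if (cfg$var_gxe > 0) {
    G <- tcrossprod(X$X) / p
    R <- chol(G + diag(1e-8, n))
    for (e in seq_len(m))
      u2[, e] <- sqrt(cfg$var_gxe) * drop(crossprod(R, stats::rnorm(n)))
  }
  noise <- matrix(stats::rnorm(n * m, sd = sqrt(cfg$var_error)), n, m)

  Y <- outer(rep(1, n), cfg$env_means) + u1 + u2 + noise
  pheno <- phenotype_table(rep(X$line_ids, times = m),
                           rep(env_labels, each = n),
                           as.vector(Y), envs = env_labels)

  var_u2 <- apply(u2, 2L, stats::var)
  var_eps <- apply(noise, 2L, stats::var)
  h2 <- stats::var(u1) / (stats::var(u1) + var_u2 + var_eps)
  truth <- list(u1 = stats::setNames(u1, X$line_ids),
                u2 = u2, noise = noise,
                genetic_values = u1 + u2,
                env_means = stats::setNames(cfg$env_means, env_labels),
                realized = list(var_u1 = stats::var(u1), var_u2 = var_u2,
                                var_error = var_eps),
                h2 = stats::setNames(h2, env_labels),
                config = cfg)
  list(pheno = pheno, truth = truth)
}

# Rescale a vector to an exact sample variance (zero target -> zero vector).
scale_to_var <- function(v, target) {
  if (target <= 0) return(v * 0)
  s <- stats::var(v)
  if (s < 1e-300) stop("cannot rescale a constant vector to positive variance")
  v * sqrt(target / s)
}

#' Write a simulated data set to plain-text files
#'
#' Emits the genotype CSV (lines x markers with NA for missing), the
#' phenotype CSV (line, env, value) and a JSON truth file with the realized
#' variance components and heritabilities.
#'
#' @param g A `raw_genotypes`.
#' @param sim Output of [simulate_phenotypes()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the three paths written, invisibly.
#' @export
write_simulation <- function(g, sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  geno_path <- file.path(dir, "genotypes.csv")
  tab <- data.frame(line = g$line_ids, g$calls, check.names = FALSE)
  colnames(tab) <- c("line", g$marker_ids)
  utils::write.csv(tab, geno_path, row.names = FALSE, quote = FALSE, na = "NA")
  pheno_path <- file.path(dir, "phenotypes.csv")
  write_phenotypes(sim$pheno, pheno_path)
  truth_path <- file.path(dir, "truth.yaml")
  yaml::write_yaml(list(h2 = as.list(sim$truth$h2),
                        var_u1 = sim$truth$realized$var_u1,
                        var_u2 = as.list(sim$truth$realized$var_u2),
                        var_error = as.list(sim$truth$realized$var_error)),
                   truth_path)
  invisible(c(geno_path, pheno_path, truth_path))
}
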