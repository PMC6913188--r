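# Shared fixture builders: everything is generated in code at test time.

# Write a genotype CSV and return its path.
write_geno_csv <- function(cells, line_ids = NULL, marker_ids = NULL,
                           path = tempfile(fileext = ".csv")) {
  cells <- as.matrix(cells)
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(cells)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(cells)))
  tab <- cbind(line = line_ids, as.data.frame(cells))
  colnames(tab) <- c("line", marker_ids)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "NA")
  path
}

# Small standardized marker matrix from binomial dosages.
random_marker_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  freq <- runif(p, 0.1, 0.5)
  calls <- matrix(rbinom(n * p, 2, rep(freq, each = n)), n, p)
  # guard against constant columns in tiny fixtures
  for (j in which(apply(calls, 2, function(v) length(unique(v))) == 1))
    calls[1 + (j %% n), j] <- (calls[1, j] + 1) %% 3
  g <- new_raw_genotypes(calls, paste0("L", seq_len(n)), paste0("M", seq_len(p)))
  impute_and_scale(g, "standardized")
}

# Dense multivariate-normal log density: the likelihood oracle.
dense_mvn_logpdf <- function(y, mean, Sigma) {
  n <- length(y)
  r <- y - mean
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(Sigma)$modulus) +
            drop(crossprod(r, solve(Sigma, r))))
}

# Simulated multi-environment data set at test scale.
quick_sim <- function(n_lines = 60, n_markers = 200, n_envs = 3,
                      var_gxe = 0.3, var_error = 0.4, var_epistatic = 0,
                      missing_rate = 0, seed = 1) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers,
                    missing_rate = missing_rate, n_envs = n_envs,
                    env_means = seq(6, 4, length.out = n_envs),
                    var_gxe = var_gxe, var_error = var_error,
                    var_epistatic = var_epistatic, seed = seed)
  g <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(g, cfg)
  list(cfg = cfg, g = g, pheno = sim$pheno, truth = sim$truth,
       X = impute_and_scale(g, "standardized"))
}
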