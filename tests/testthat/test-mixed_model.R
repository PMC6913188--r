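test_that("incidence matrices put exactly one 1 per row in the right column", {
  pt <- phenotype_table(line = c("A", "B", "A", "B"),
                        env = c("E1", "E1", "E2", "E2"),
                        value = 1:4)
  inc <- build_incidence(pt, line_order = c("A", "B"))
  expect_equal(unname(colSums(inc$Zg)), c(2, 2))
  expect_true(all(rowSums(inc$Zg) == 1))
  expect_true(all(rowSums(inc$ZE) == 1))
  expect_equal(unname(inc$Zg[1, "A"]), 1)
  expect_equal(unname(inc$ZE[3, "E2"]), 1)

  single <- phenotype_table(c("A", "B"), c("E1", "E1"), c(1, 2))
  inc1 <- build_incidence(single, c("A", "B"))
  expect_equal(unname(inc1$ZE), matrix(1, 2, 1))

  expect_error(build_incidence(pt, line_order = "A"), "unknown line")
  expect_error(build_incidence(pt, c("A", "B"), env_order = "E1"),
               "unknown environment")
})

test_that("expand_main_kernel is the index-lookup expansion Zg G Zg'", {
  Xm <- random_marker_matrix(4, 10, seed = 21)
  G <- linear_kernel(Xm)
  pt <- phenotype_table(line = c("L1", "L2", "L3", "L4", "L2", "L2"),
                        env = c(rep("E1", 4), "E2", "E3"),
                        value = rnorm(6))
  inc <- build_incidence(pt, Xm$line_ids)
  K1 <- expand_main_kernel(G, inc)
  # brute-force index lookup oracle
  for (a in 1:6) for (b in 1:6)
    expect_equal(K1[a, b], G$K[pt$line[a], pt$line[b]])
  # repeated observations of one line form a constant block
  expect_equal(K1[5, 6], G$K["L2", "L2"])
  # one observation per line in kernel order reproduces G
  ident <- phenotype_table(Xm$line_ids, rep("E1", 4), rnorm(4))
  expect_equal(unname(expand_main_kernel(G, build_incidence(ident, Xm$line_ids))),
               unname(G$K))
  expect_error(expand_main_kernel(G, build_incidence(pt, c(Xm$line_ids, "L9"))),
               "does not match")
})

test_that("the G-by-E kernel zeroes cross-environment pairs and stays PSD", {
  Xm <- random_marker_matrix(5, 12, seed = 22)
  G <- linear_kernel(Xm)
  pt <- phenotype_table(rep(Xm$line_ids, 2), rep(c("E1", "E2"), each = 5),
                        rnorm(10))
  inc <- build_incidence(pt, Xm$line_ids)
  K1 <- expand_main_kernel(G, inc)
  K2 <- gxe_kernel(K1, inc)
  expect_equal(K2[1:5, 1:5], K1[1:5, 1:5])
  expect_true(all(K2[1:5, 6:10] == 0))
  ev <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(1, max(ev)))

  one_env <- phenotype_table(Xm$line_ids, rep("E1", 5), rnorm(5))
  inc1 <- build_incidence(one_env, Xm$line_ids)
  K1s <- expand_main_kernel(G, inc1)
  expect_equal(gxe_kernel(K1s, inc1), K1s)
})

test_that("single-kernel ML fit matches the dense multivariate-normal oracle", {
  Xm <- random_marker_matrix(8, 30, seed = 23)
  G <- linear_kernel(Xm)
  set.seed(23)
  y <- 5 + drop(chol(G$K + diag(1e-6, 8)) %*% rnorm(8)) + rnorm(8, sd = 0.5)
  fit <- fit_single_kernel(y, G)
  vc <- fit$var_components
  Sigma <- vc[["u"]] * G$K + diag(vc[["residual"]], 8)
  expect_equal(fit$logML, dense_mvn_logpdf(y, fit$mu, Sigma), tolerance = 1e-6)
  expect_true(all(vc >= 0))
})

test_that("single-kernel fit handles degenerate and invalid inputs", {
  Xm <- random_marker_matrix(6, 10, seed = 24)
  G <- linear_kernel(Xm)
  fit <- fit_single_kernel(rep(3.2, 6), G)
  expect_equal(fit$mu, 3.2)
  expect_lte(fit$var_components[["u"]], 1e-9)
  expect_lte(fit$var_components[["residual"]], 1e-9)
  expect_error(fit_single_kernel(c(1, NA, 3, 4, 5, 6), G), "non-finite")
  expect_error(fit_single_kernel(1:3, G), "length")
})

test_that("single-kernel fit recovers simulated variance components", {
  Xm <- random_marker_matrix(300, 400, seed = 25)
  G <- linear_kernel(Xm)
  R <- chol(G$K + diag(1e-8, 300))
  set.seed(25)
  y <- 10 + sqrt(2) * drop(crossprod(R, rnorm(300))) + rnorm(300, sd = 1)
  fit <- fit_single_kernel(y, G)
  expect_gt(fit$var_components[["u"]], 1)
  expect_lt(fit$var_components[["u"]], 3.5)
  expect_gt(fit$var_components[["residual"]], 0.6)
  expect_lt(fit$var_components[["residual"]], 1.6)
  expect_equal(fit$mu, 10, tolerance = 0.5)
})

test_that("multi-kernel ML fit matches the dense oracle and nests the single fit", {
  sim <- quick_sim(n_lines = 6, n_markers = 20, n_envs = 2, seed = 26)
  G <- linear_kernel(sim$X)
  inc <- build_incidence(sim$pheno, sim$X$line_ids)
  K1 <- expand_main_kernel(G, inc)
  K2 <- gxe_kernel(K1, inc)
  y <- sim$pheno$value
  fit <- fit_multi_kernel(y, list(u1 = K1, u2 = K2), ZE = inc$ZE)
  vc <- fit$var_components
  Sigma <- vc[["u1"]] * K1 + vc[["u2"]] * K2 + diag(vc[["residual"]], 12)
  mean_vec <- drop(inc$ZE %*% fit$beta_E)
  expect_equal(fit$logML, dense_mvn_logpdf(y, mean_vec, Sigma),
               tolerance = 1e-6)

  # single-environment nesting: one kernel, intercept only (fewer markers
  # than lines makes the kernel rank-deficient, keeping the optimum interior)
  simn <- quick_sim(n_lines = 40, n_markers = 20, n_envs = 2, seed = 126)
  e1 <- simn$pheno$env == "ENV1"
  y1 <- simn$pheno$value[e1]
  Kobs <- linear_kernel(simn$X)$K[match(simn$pheno$line[e1], simn$X$line_ids),
                                  match(simn$pheno$line[e1], simn$X$line_ids)]
  f_single <- fit_single_kernel(y1, Kobs)
  f_multi <- fit_multi_kernel(y1, list(u = Kobs), ZE = NULL)
  expect_equal(f_multi$logML, f_single$logML, tolerance = 1e-6)

  expect_error(fit_multi_kernel(y, list(K1), ZE = cbind(inc$ZE, inc$ZE[, 1])),
               "singular")
})

test_that("adding a variance component never lowers the maximized likelihood", {
  sim <- quick_sim(n_lines = 25, n_markers = 60, n_envs = 2, var_gxe = 0.5,
                   seed = 27)
  G <- linear_kernel(sim$X)
  inc <- build_incidence(sim$pheno, sim$X$line_ids)
  K1 <- expand_main_kernel(G, inc)
  K2 <- gxe_kernel(K1, inc)
  f1 <- fit_multi_kernel(sim$pheno$value, list(u1 = K1), ZE = inc$ZE)
  f2 <- fit_multi_kernel(sim$pheno$value, list(u1 = K1, u2 = K2), ZE = inc$ZE)
  expect_gte(f2$logML, f1$logML - 1e-6)
})

test_that("fits are invariant to observation reordering", {
  sim <- quick_sim(n_lines = 15, n_markers = 40, n_envs = 2, seed = 28)
  G <- linear_kernel(sim$X)
  inc <- build_incidence(sim$pheno, sim$X$line_ids)
  K1 <- expand_main_kernel(G, inc)
  K2 <- gxe_kernel(K1, inc)
  y <- sim$pheno$value
  fit <- fit_multi_kernel(y, list(u1 = K1, u2 = K2), ZE = inc$ZE)
  set.seed(28); perm <- sample(length(y))
  fitp <- fit_multi_kernel(y[perm],
                           list(u1 = K1[perm, perm], u2 = K2[perm, perm]),
                           ZE = inc$ZE[perm, , drop = FALSE])
  expect_equal(fitp$logML, fit$logML, tolerance = 1e-6)
  expect_equal(fitp$blups$u1, fit$blups$u1[perm], tolerance = 1e-4)
})

test_that("predict_cells interpolates training cells as residual variance vanishes", {
  Xm <- random_marker_matrix(30, 60, seed = 29)
  G <- linear_kernel(Xm)
  R <- chol(G$K + diag(1e-8, 30))
  set.seed(29)
  y <- 4 + drop(crossprod(R, rnorm(30)))       # pure genetic signal, no noise
  fit <- fit_single_kernel(y, G)
  expect_lt(fit$var_components[["residual"]], 1e-4)
  train <- phenotype_table(Xm$line_ids, rep("E1", 30), y)
  pred <- predict_cells(fit, G, train, data.frame(line = Xm$line_ids[1:5],
                                                  env = "E1"))
  expect_equal(pred$y_hat, unname(y[1:5]), tolerance = 1e-3)
})

test_that("predict_cells matches the conditional-Gaussian block formula", {
  sim <- quick_sim(n_lines = 4, n_markers = 15, n_envs = 2, seed = 30)
  G <- linear_kernel(sim$X)
  pheno <- sim$pheno                          # 8 observations
  train <- pheno[-c(3, 8), , drop = FALSE]
  attr(train, "envs") <- pheno_envs(pheno); class(train) <- class(pheno)
  targets <- pheno[c(3, 8), c("line", "env")]
  inc <- build_incidence(train, sim$X$line_ids)
  K1 <- expand_main_kernel(G, inc)
  K2 <- gxe_kernel(K1, inc)
  fit <- fit_multi_kernel(train$value, list(u1 = K1, u2 = K2), ZE = inc$ZE)
  pred <- predict_cells(fit, G, train, targets)

  # dense oracle over the union, built from incidence matrices
  all_pt <- phenotype_table(c(train$line, targets$line),
                            c(train$env, targets$env),
                            c(train$value, 0, 0))
  inc_all <- build_incidence(all_pt, sim$X$line_ids,
                             env_order = pheno_envs(pheno))
  vc <- fit$var_components
  Zg <- inc_all$Zg; ZE <- inc_all$ZE
  C <- vc[["u1"]] * Zg %*% G$K %*% t(Zg) +
    vc[["u2"]] * ((Zg %*% G$K %*% t(Zg)) * tcrossprod(ZE))
  fx <- drop(ZE %*% fit$beta_E)
  iT <- 1:6; iU <- 7:8
  oracle <- fx[iU] + C[iU, iT] %*%
    solve(C[iT, iT] + diag(vc[["residual"]], 6), train$value - fx[iT])
  expect_equal(pred$y_hat, drop(oracle), tolerance = 1e-8)
  expect_equal(nrow(pred), 2L)

  expect_error(predict_cells(fit, G, train,
                             data.frame(line = "L9999", env = "ENV1")),
               "absent from kernel")
})

test_that("predictions correlate with true genetic values on simulated data", {
  hits <- 0L
  for (s in 1:10) {
    sim <- quick_sim(n_lines = 50, n_markers = 150, n_envs = 2,
                     var_gxe = 0.2, var_error = 0.6, seed = 100 + s)
    G <- linear_kernel(sim$X)
    e1 <- sim$pheno$env == "ENV1"
    y1 <- sim$pheno$value[e1]
    idx <- match(sim$pheno$line[e1], sim$X$line_ids)
    tr <- 1:40; te <- 41:50
    fit <- fit_single_kernel(y1[tr], G$K[idx[tr], idx[tr]])
    train <- phenotype_table(sim$pheno$line[e1][tr], rep("ENV1", 40), y1[tr])
    pred <- predict_cells(fit, G, train,
                          data.frame(line = sim$pheno$line[e1][te], env = "ENV1"))
    truth <- sim$truth$u1[sim$pheno$line[e1][te]] + sim$truth$u2[idx[te], 1]
    if (cor(pred$y_hat, truth) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("heritability follows the variance-ratio conventions and is monotone in noise", {
  sim <- quick_sim(n_lines = 30, n_markers = 80, n_envs = 2, seed = 31)
  G <- linear_kernel(sim$X)
  inc <- build_incidence(sim$pheno, sim$X$line_ids)
  K1 <- expand_main_kernel(G, inc)
  K2 <- gxe_kernel(K1, inc)
  fit <- fit_multi_kernel(sim$pheno$value, list(u1 = K1, u2 = K2), ZE = inc$ZE)
  vc <- fit$var_components
  expect_equal(heritability(fit),
               vc[["u1"]] / (vc[["u1"]] + vc[["u2"]] + vc[["residual"]]))

  # arithmetic check via a hand-built single fit: su2 = se2 -> h2 = 0.5
  fake <- fit
  fake$var_components <- c(u1 = 1, u2 = 0, residual = 1)
  expect_equal(heritability(fake), 0.5)
  # strictly decreasing in residual variance at fixed genetic variances
  noisier <- fake
  noisier$var_components <- c(u1 = 1, u2 = 0, residual = 2)
  expect_lt(heritability(noisier), heritability(fake))

  bad <- fit; bad$converged <- FALSE
  expect_error(heritability(bad), "converge")
})
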