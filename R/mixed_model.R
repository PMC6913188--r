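#' Incidence matrices linking observations to lines and environments
#'
#' @param pheno A `phenotype_table`.
#' @param line_order Ordered line identifiers (columns of `Zg`).
#' @param env_order Ordered environment labels (columns of `ZE`).
#' @return List with 0/1 matrices `Zg` (n_obs x n_lines) and `ZE`
#'   (n_obs x n_envs); every row of each has exactly one 1.
#' @export
build_incidence <- function(pheno, line_order, env_order = pheno_envs(pheno)) {
  stopifnot(inherits(pheno, "phenotype_table"))
  li <- match(pheno$line, line_order)
  ei <- match(pheno$env, env_order)
  if (anyNA(li))
    stop("unknown line id: ", pheno$line[which(is.na(li))[1L]])
  if (anyNA(ei))
    stop("unknown environment: ", pheno$env[which(is.na(ei))[1L]])
  n <- nrow(pheno)
  Zg <- matrix(0, n, length(line_order), dimnames = list(NULL, line_order))
  Zg[cbind(seq_len(n), li)] <- 1
  ZE <- matrix(0, n, length(env_order), dimnames = list(NULL, env_order))
  ZE[cbind(seq_len(n), ei)] <- 1
  list(Zg = Zg, ZE = ZE, line_index = li, env_index = ei)
}

#' Expand a line-level kernel to observation level
#'
#' `K1 = Zg G Zg'`: the genomic main-effect covariance among observations,
#' computed by index lookup (`K1[a,b] = G[line(a), line(b)]`).
#'
#' @param G A `kernel_matrix` over lines.
#' @param inc Output of [build_incidence()].
#' @return Dense n_obs x n_obs matrix.
#' @export
expand_main_kernel <- function(G, inc) {
  stopifnot(inherits(G, "kernel_matrix"))
  if (ncol(inc$Zg) != nrow(G$K))
    stop("kernel dimension (", nrow(G$K), ") does not match number of lines (",
         ncol(inc$Zg), ")")
  idx <- inc$line_index
  G$K[idx, idx, drop = FALSE]
}

#' Genotype-by-environment interaction kernel
#'
#' `K2 = (Zg G Zg') o (ZE ZE')` (Hadamard product): the main-effect covariance
#' masked to pairs of observations sharing an environment. PSD by the Schur
#' product theorem.
#'
#' @param K1 Observation-level main-effect covariance from
#'   [expand_main_kernel()].
#' @param inc Output of [build_incidence()].
#' @return Dense n_obs x n_obs matrix.
#' @export
gxe_kernel <- function(K1, inc) {
  if (nrow(K1) != nrow(inc$ZE))
    stop("K1 dimension does not match number of observations")
  same_env <- outer(inc$env_index, inc$env_index, "==")
  K1 * same_env
}

variance_floor <- 1e-10

new_kernel_fit <- function(mu, beta_E, var_components, blups, logML,
                           converged, n_iter, model, env_order = NULL,
                           kernel_kind = NULL) {
  structure(list(mu = mu, beta_E = beta_E, var_components = var_components,
                 blups = blups, logML = logML, converged = converged,
                 n_iter = n_iter, model = model, env_order = env_order,
                 kernel_kind = kernel_kind),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("kernel_fit (%s model): logML = %.4f, converged = %s\n",
              x$model, x$logML, x$converged))
  cat("variance components:\n")
  print(round(x$var_components, 6))
  invisible(x)
}

#' Fit the single-kernel Gaussian-process model
#'
#' Maximum-likelihood fit of `y = mu 1 + u + e` with `u ~ N(0, su2 K)` and
#' `e ~ N(0, se2 I)`. The kernel is eigendecomposed once and the likelihood
#' profiled over the variance ratio `lambda = su2 / se2`, so the optimization
#' is a one-dimensional search; `mu` and the residual variance have closed
#' forms at each `lambda`. Variances are floored at 1e-10.
#'
#' @param y Numeric observation vector (one per row/column of `K`).
#' @param K A `kernel_matrix` or plain symmetric PSD matrix.
#' @param lambda_bounds Search interval for `log(lambda)`.
#' @return A `kernel_fit` with fields `mu`, `var_components` (named `u`,
#'   `residual`), `blups$u`, `logML`, `converged`, `n_iter`.
#' @export
fit_single_kernel <- function(y, K, lambda_bounds = c(-25, 25)) {
  Kmat <- if (inherits(K, "kernel_matrix")) K$K else as.matrix(K)
  kind <- if (inherits(K, "kernel_matrix")) K$kind else NULL
  n <- length(y)
  if (!all(is.finite(y))) stop("y contains non-finite values")
  if (n != nrow(Kmat)) stop("length(y) must equal dim(K)")
  if (n < 2L) stop("need at least two observations")

  vy <- stats::var(y)
  if (vy < 1e-12) {
    # degenerate: no variation to partition
    vc <- c(u = variance_floor, residual = variance_floor)
    return(new_kernel_fit(mu = mean(y), beta_E = NULL, var_components = vc,
                          blups = list(u = rep(0, n)),
                          logML = single_kernel_logml(y, Kmat, vc["u"], vc["residual"]),
                          converged = TRUE, n_iter = 0L, model = "single",
                          kernel_kind = kind))
  }

  ed <- eigen((Kmat + t(Kmat)) / 2, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  yt <- drop(crossprod(U, y))
  ot <- drop(crossprod(U, rep(1, n)))

  n_eval <- 0L
  prof <- function(loglam) {
    n_eval <<- n_eval + 1L
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    mu <- sum(w * ot * yt) / sum(w * ot^2)
    rss <- sum(w * (yt - mu * ot)^2)
    se2 <- rss / n
    -0.5 * (n * log(2 * pi) + n * log(se2) + sum(log(lam * d + 1)) + n)
  }
  # the profile can be multimodal (an interior mode plus a boundary tail),
  # so scan a coarse grid first, then refine locally around the best bracket
  grid <- seq(lambda_bounds[1L], lambda_bounds[2L], length.out = 61L)
  vals <- vapply(grid, prof, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(prof, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-10)
  lam <- exp(opt$maximum)
  w <- 1 / (lam * d + 1)
  mu <- sum(w * ot * yt) / sum(w * ot^2)
  se2_raw <- sum(w * (yt - mu * ot)^2) / n
  su2 <- max(lam * se2_raw, variance_floor)
  se2 <- max(se2_raw, variance_floor)
  # BLUP u = su2 K Sigma^-1 (y - mu 1) via the eigenbasis
  rt <- yt - mu * ot
  shrink <- su2 * d / (su2 * d + se2)
  u_hat <- drop(U %*% (shrink * rt))

  vc <- c(u = su2, residual = se2)
  new_kernel_fit(mu = mu, beta_E = NULL, var_components = vc,
                 blups = list(u = u_hat),
                 logML = single_kernel_logml(y, Kmat, su2, se2),
                 converged = TRUE, n_iter = n_eval, model = "single",
                 kernel_kind = kind)
}

# Exact marginal log-likelihood of y ~ N(mu 1, su2 K + se2 I), dense form.
single_kernel_logml <- function(y, Kmat, su2, se2, mu = NULL) {
  n <- length(y)
  Sigma <- su2 * Kmat + diag(se2, n)
  L <- chol(Sigma)
  if (is.null(mu)) {
    si1 <- backsolve(L, backsolve(L, rep(1, n), transpose = TRUE))
    mu <- sum(si1 * y) / sum(si1)
  }
  r <- y - mu
  z <- backsolve(L, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

#' Fit the multi-kernel G-by-E mixed model
#'
#' Maximum-likelihood fit of `y = ZE beta_E + sum_r u_r + e` with
#' `u_r ~ N(0, s_r^2 K_r)` and `e ~ N(0, se2 I)`. Fixed effects (one intercept
#' per environment; a single grand intercept when `ZE = NULL`) are profiled by
#' generalized least squares inside each likelihood evaluation. The variance
#' components are optimized on the log scale by L-BFGS-B with the analytic
#' gradient of the profiled likelihood; `n_starts` starting points guard
#' against local optima and the best final likelihood is kept.
#'
#' @param y Numeric observation vector.
#' @param kernels Named list of observation-level covariance matrices (e.g.
#'   `list(u1 = K1, u2 = K2)`); names default to `u1`, `u2`, ...
#' @param ZE Observation-by-environment 0/1 incidence matrix, or `NULL` for an
#'   intercept-only fixed part.
#' @param n_starts Number of optimizer starts (default 3).
#' @param reltol Convergence tolerance passed to the optimizer (`factr` scale).
#' @return A `kernel_fit` with per-environment intercepts in `beta_E`
#'   (`mu` is their mean), one variance per kernel plus `residual` in
#'   `var_components`, per-kernel observation-level BLUPs, and the exact
#'   `logML` at the optimum.
#' @export
fit_multi_kernel <- function(y, kernels, ZE = NULL, n_starts = 3,
                             reltol = 1e-10) {
  n <- length(y)
  if (!all(is.finite(y))) stop("y contains non-finite values")
  if (!is.list(kernels) || length(kernels) < 1L) stop("kernels must be a non-empty list")
  Ks <- lapply(kernels, function(k) {
    m <- if (inherits(k, "kernel_matrix")) k$K else as.matrix(k)
    if (nrow(m) != n) stop("kernel dimension does not match length(y)")
    (m + t(m)) / 2
  })
  if (is.null(names(Ks)) || any(names(Ks) == ""))
    names(Ks) <- paste0("u", seq_along(Ks))
  X <- if (is.null(ZE)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
       else as.matrix(ZE)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")

  nk <- length(Ks)
  vy <- max(stats::var(y), 1e-8)
  lb <- log(variance_floor)
  ub <- log(vy * 1e6)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    v <- exp(theta)
    Sigma <- diag(v[nk + 1L], n)
    for (r in seq_len(nk)) Sigma <- Sigma + v[r] * Ks[[r]]
    L <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(L)) {
      val <- list(nll = 1e10, grad = rep(0, nk + 1L))
      cache$key <- key; cache$val <- val
      return(val)
    }
    SiX <- backsolve(L, backsolve(L, X, transpose = TRUE))
    XtSiX <- crossprod(X, SiX)
    beta <- solve(XtSiX, crossprod(SiX, y))
    r <- y - drop(X %*% beta)
    a <- backsolve(L, backsolve(L, r, transpose = TRUE))   # Sigma^-1 r
    logdet <- 2 * sum(log(diag(L)))
    nll <- 0.5 * (n * log(2 * pi) + logdet + sum(r * a))
    Si <- chol2inv(L)
    grad <- numeric(nk + 1L)
    for (k in seq_len(nk))
      grad[k] <- 0.5 * v[k] * (sum(Si * Ks[[k]]) - drop(crossprod(a, Ks[[k]] %*% a)))
    grad[nk + 1L] <- 0.5 * v[nk + 1L] * (sum(diag(Si)) - sum(a^2))
    val <- list(nll = nll, grad = grad, beta = beta, a = a)
    cache$key <- key; cache$val <- val
    val
  }

  starts <- list(log(rep(vy / (nk + 1L), nk + 1L)),
                 log(c(rep(vy * 0.05 / nk, nk), vy * 0.95)),
                 log(c(rep(vy * 0.45 / nk * 2, nk), vy * 0.1)))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  if (n_starts > length(starts))
    starts <- c(starts, replicate(n_starts - length(starts),
                                  log(vy * stats::runif(nk + 1L, 0.05, 1)),
                                  simplify = FALSE))

  best <- NULL
  total_iter <- 0L
  any_conv <- FALSE
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(pmin(pmax(s, lb), ub),
                   fn = function(th) evaluate(th)$nll,
                   gr = function(th) evaluate(th)$grad,
                   method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 200L, factr = reltol / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(opt)) next
    total_iter <- total_iter + opt$counts[[1L]]
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("multi-kernel optimization failed from every start")
  theta <- best$par
  fin <- evaluate(theta)
  v <- pmax(exp(theta), variance_floor)
  names(v) <- c(names(Ks), "residual")
  beta <- drop(fin$beta)
  names(beta) <- colnames(X)
  a <- fin$a
  blups <- lapply(seq_len(nk), function(k) drop(v[k] * Ks[[k]] %*% a))
  names(blups) <- names(Ks)

  env_order <- if (!is.null(ZE)) colnames(X) else NULL
  new_kernel_fit(mu = mean(beta),
                 beta_E = if (!is.null(ZE)) beta else NULL,
                 var_components = v, blups = blups, logML = -fin$nll,
                 converged = any_conv, n_iter = total_iter, model = "multi",
                 env_order = env_order)
}

#' Predict unobserved line-by-environment cells
#'
#' Conditional-Gaussian (BLUP) prediction under a fitted model: with
#' `C = sum_r s_r^2 K_r` extended over the union of training observations (T)
#' and target cells (U),
#' `y_hat = fixed_U + C_UT (C_TT + se2 I)^-1 (y_T - fixed_T)`.
#' Covariances are rebuilt from the line-level kernel `G`, so a target line
#' must be genotyped but need not be phenotyped in the target environment.
#'
#' @param fit A `kernel_fit` from [fit_single_kernel()] or
#'   [fit_multi_kernel()].
#' @param G The line-level `kernel_matrix` the fit used.
#' @param train `phenotype_table` of the training observations, in the order
#'   the model was fitted.
#' @param targets Data frame with columns `line` and `env` naming the cells to
#'   predict.
#' @return A `prediction_set` data frame with columns `line`, `env`, `y_hat`.
#' @export
predict_cells <- function(fit, G, train, targets) {
  stopifnot(inherits(fit, "kernel_fit"), inherits(G, "kernel_matrix"))
  targets <- as.data.frame(targets)
  if (!all(c("line", "env") %in% colnames(targets)))
    stop("targets must have columns line, env")
  all_line <- c(train$line, as.character(targets$line))
  all_env <- c(train$env, as.character(targets$env))
  li <- match(all_line, G$line_ids)
  if (anyNA(li))
    stop("target line absent from kernel: ", all_line[which(is.na(li))[1L]])
  nT <- nrow(train)
  nU <- nrow(targets)
  idxT <- seq_len(nT)
  idxU <- nT + seq_len(nU)

  vc <- fit$var_components
  Gfull <- G$K[li, li, drop = FALSE]
  if (fit$model == "single") {
    C <- vc[["u"]] * Gfull
    fixed <- rep(fit$mu, nT + nU)
  } else {
    C <- vc[[1L]] * Gfull
    if (length(vc) > 2L) {          # G-by-E component present
      same_env <- outer(all_env, all_env, "==")
      C <- C + vc[[2L]] * (Gfull * same_env)
    }
    if (!is.null(fit$beta_E)) {
      be <- fit$beta_E[match(all_env, fit$env_order)]
      if (anyNA(be))
        stop("unknown environment in targets: ",
             all_env[which(is.na(be))[1L]])
      fixed <- unname(be)
    } else fixed <- rep(fit$mu, nT + nU)
  }
  se2 <- vc[["residual"]]
  CTT <- C[idxT, idxT, drop = FALSE] + diag(se2, nT)
  CUT <- C[idxU, idxT, drop = FALSE]
  rT <- train$value - fixed[idxT]
  y_hat <- fixed[idxU] + drop(CUT %*% solve(CTT, rT))

  out <- data.frame(line = as.character(targets$line),
                    env = as.character(targets$env),
                    y_hat = y_hat, stringsAsFactors = FALSE)
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Genomic (narrow-sense) heritability from a fitted model
#'
#' For the multi-kernel G-by-E model the convention used here is
#' `h2 = s_u1^2 / (s_u1^2 + s_u2^2 + se2)`; for the single-kernel model
#' `h2 = s_u^2 / (s_u^2 + se2)`.
#'
#' @param fit A converged `kernel_fit`.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "kernel_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  vc <- fit$var_components
  total <- sum(vc)
  if (total <= 2 * variance_floor * length(vc))
    stop("zero total variance; heritability undefined")
  unname(vc[[1L]] / total)
}
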