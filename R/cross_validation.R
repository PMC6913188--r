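#' Sparse-testing (CV2) cross-validation plan
#'
#' For each replicate and each environment independently, lines are randomly
#' partitioned into `k` folds. A line held out in environment j in fold f is
#' therefore typically observed in the other environments — the sparse-testing
#' prediction problem. Fully reproducible from `seed`.
#'
#' @param lines Character vector of line identifiers.
#' @param envs Character vector of environment labels.
#' @param k Number of folds (default 5, i.e. 20% of lines tested per
#'   environment).
#' @param replicates Number of independent replicate partitions (default 10).
#' @param seed Integer RNG seed.
#' @return A `cv_plan` data frame with columns `replicate`, `env`, `line`,
#'   `fold` and attributes `k`, `replicates`, `seed`.
#' @export
make_cv2_plan <- function(lines, envs, k = 5L, replicates = 10L, seed = 1L) {
  lines <- as.character(lines); envs <- as.character(envs)
  n <- length(lines)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of lines (", n, ")")
  if (replicates < 1L) stop("replicates must be >= 1")
  set.seed(seed)
  out <- vector("list", replicates * length(envs))
  i <- 0L
  for (r in seq_len(replicates)) {
    for (e in envs) {
      i <- i + 1L
      fold <- sample(rep_len(seq_len(k), n))
      out[[i]] <- data.frame(replicate = r, env = e, line = lines,
                             fold = fold, stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, out)
  rownames(plan) <- NULL
  attr(plan, "k") <- as.integer(k)
  attr(plan, "replicates") <- as.integer(replicates)
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("cv_plan", "data.frame")
  plan
}

#' Mean squared error of prediction
#'
#' @param y_obs,y_pred Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
msep <- function(y_obs, y_pred) {
  if (length(y_obs) == 0L) stop("msep of empty input")
  if (length(y_obs) != length(y_pred)) stop("length mismatch")
  mean((y_obs - y_pred)^2)
}

#' Benchmark settings
#'
#' @param ak_l_max Deepest arc-cosine layer evaluated during selection.
#' @param gk_grid Bandwidth grid for Gaussian-kernel selection.
#' @param dl_grid Hyperparameter grid for the neural-network baseline
#'   (rows of [dl_default_grid()] or a restricted frame).
#' @param dl_epochs Training epochs for the baseline.
#' @param dl_inner_folds Inner CV folds for baseline tuning.
#' @param seed Seed for the baseline's stochastic training.
#' @return List of settings for [run_benchmark()].
#' @export
benchmark_control <- function(ak_l_max = 8L,
                              gk_grid = c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2.5, 5),
                              dl_grid = NULL, dl_epochs = 1000L,
                              dl_inner_folds = 5L, seed = 1L) {
  list(ak_l_max = as.integer(ak_l_max), gk_grid = gk_grid,
       dl_grid = dl_grid, dl_epochs = as.integer(dl_epochs),
       dl_inner_folds = as.integer(dl_inner_folds), seed = as.integer(seed))
}

# Fit one single-kernel model per candidate line-level kernel; keep the
# marginal-likelihood argmax (ties toward the simpler candidate).
select_fit_single <- function(y, line_index, kernel_list, values) {
  fits <- lapply(kernel_list, function(K) {
    tryCatch(fit_single_kernel(y, K$K[line_index, line_index, drop = FALSE]),
             error = function(e) NULL)
  })
  logml <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$logML,
                  numeric(1))
  chosen <- choose_candidate(values, logml)
  j <- which(values == chosen)[1L]
  list(fit = fits[[j]], kernel = kernel_list[[j]], value = chosen)
}

select_fit_multi <- function(y, inc, kernel_list, values) {
  fits <- lapply(kernel_list, function(G) {
    tryCatch({
      K1 <- expand_main_kernel(G, inc)
      K2 <- gxe_kernel(K1, inc)
      fit_multi_kernel(y, list(u1 = K1, u2 = K2), ZE = inc$ZE)
    }, error = function(e) NULL)
  })
  logml <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$logML,
                  numeric(1))
  chosen <- choose_candidate(values, logml)
  j <- which(values == chosen)[1L]
  list(fit = fits[[j]], kernel = kernel_list[[j]], value = chosen)
}

#' Run the CV2 prediction benchmark
#'
#' For every partition of `plan`, the test cells are masked; the
#' single-environment model (`"G"`) is fitted per environment on that
#' environment's training lines only, while the multi-environment model
#' (`"E+G+GE"`) is fitted jointly on all training cells. Per method the tuning
#' parameter (arc-cosine layers, Gaussian bandwidth) is selected by marginal
#' likelihood on the training portion of each partition; the neural-network
#' baseline tunes its grid by inner cross-validation on the same training
#' portion. All methods see identical masks; masked phenotypes never enter any
#' training step. Genomic kernels are built once from all genotyped lines
#' (marker data are never masked).
#'
#' @param pheno A `phenotype_table`.
#' @param X A standardized `marker_matrix` covering all phenotyped lines.
#' @param plan A `cv_plan` from [make_cv2_plan()].
#' @param methods Subset of `c("GB", "GK", "AK", "DL")`.
#' @param models Subset of `c("G", "E+G+GE")`.
#' @param control Settings from [benchmark_control()].
#' @return A `cv_result`: `records` (method, model, environment, replicate,
#'   fold, msep, n_test, param) and `summary` (mean and SD of MSEP across
#'   partitions).
#' @export
run_benchmark <- function(pheno, X, plan, methods = c("GB", "GK", "AK"),
                          models = c("G", "E+G+GE"),
                          control = benchmark_control()) {
  stopifnot(inherits(pheno, "phenotype_table"), inherits(X, "marker_matrix"),
            inherits(plan, "cv_plan"))
  methods <- match.arg(methods, c("GB", "GK", "AK", "DL"), several.ok = TRUE)
  models <- match.arg(models, c("G", "E+G+GE"), several.ok = TRUE)
  validate_pheno_lines(pheno, X)
  if (!all(unique(pheno$line) %in% unique(plan$line)) ||
      !all(unique(pheno$env) %in% unique(plan$env)))
    stop("plan does not cover all phenotyped lines/environments")

  envs <- pheno_envs(pheno)
  k <- attr(plan, "k"); reps <- attr(plan, "replicates")
  fold_of <- stats::setNames(plan$fold,
                             paste(plan$replicate, plan$env, plan$line, sep = "\r"))

  # Line-level similarity structures, built once from all genotyped lines.
  gb <- if (any(c("GB") %in% methods)) linear_kernel(X) else NULL
  d2 <- if ("GK" %in% methods) squared_distances(X) else NULL
  gk_list <- if ("GK" %in% methods)
    lapply(sort(control$gk_grid), function(h) gaussian_kernel(d2, h)) else NULL
  gk_grid <- sort(control$gk_grid)
  ak_list <- if ("AK" %in% methods) ak_series(X, control$ak_l_max) else NULL

  pheno_line_index <- match(pheno$line, X$line_ids)
  dl_grid <- if (is.null(control$dl_grid)) dl_default_grid() else control$dl_grid

  records <- list()
  push <- function(method, model, env, r, f, value, n_test, param) {
    records[[length(records) + 1L]] <<- data.frame(
      method = method, model = model, environment = env, replicate = r,
      fold = f, msep = value, n_test = n_test, param = param,
      stringsAsFactors = FALSE)
  }

  for (r in seq_len(reps)) {
    for (f in seq_len(k)) {
      key <- paste(r, pheno$env, pheno$line, sep = "\r")
      is_test <- fold_of[key] == f
      if (!any(is_test) || all(is_test)) next
      train <- pheno[!is_test, , drop = FALSE]
      test <- pheno[is_test, , drop = FALSE]
      attr(train, "envs") <- envs; class(train) <- class(pheno)

      for (method in setdiff(methods, "DL")) {
        kernel_list <- switch(method, GB = list(gb), GK = gk_list, AK = ak_list)
        values <- switch(method, GB = 1, GK = gk_grid,
                         AK = seq_len(control$ak_l_max))

        if ("G" %in% models) {
          for (e in envs) {
            tr <- train[train$env == e, , drop = FALSE]
            te <- test[test$env == e, , drop = FALSE]
            if (nrow(te) == 0L || nrow(tr) < 2L) next
            res <- tryCatch({
              sel <- select_fit_single(tr$value,
                                       match(tr$line, X$line_ids),
                                       kernel_list, values)
              attr(tr, "envs") <- envs; class(tr) <- class(pheno)
              pred <- predict_cells(sel$fit, sel$kernel, tr,
                                    te[, c("line", "env")])
              list(ms = msep(te$value, pred$y_hat), param = sel$value)
            }, error = function(err) {
              warning(sprintf("%s/G failed for env %s (rep %d fold %d): %s",
                              method, e, r, f, conditionMessage(err)))
              NULL
            })
            if (!is.null(res)) push(method, "G", e, r, f, res$ms, nrow(te), res$param)
          }
        }

        if ("E+G+GE" %in% models) {
          res <- tryCatch({
            inc <- build_incidence(train, line_order = X$line_ids,
                                   env_order = envs)
            sel <- select_fit_multi(train$value, inc, kernel_list, values)
            pred <- predict_cells(sel$fit, sel$kernel, train,
                                  test[, c("line", "env")])
            list(pred = pred, param = sel$value)
          }, error = function(err) {
            warning(sprintf("%s/E+G+GE failed (rep %d fold %d): %s",
                            method, r, f, conditionMessage(err)))
            NULL
          })
          if (!is.null(res)) {
            for (e in envs) {
              sel_e <- test$env == e
              if (!any(sel_e)) next
              push(method, "E+G+GE", e, r, f,
                   msep(test$value[sel_e], res$pred$y_hat[sel_e]),
                   sum(sel_e), res$param)
            }
          }
        }
      }

      if ("DL" %in% methods) {
        dl_seed <- control$seed + 1009L * r + f
        if ("G" %in% models) {
          feats <- build_feature_matrix(X, model = "g")
          for (e in envs) {
            tr <- train[train$env == e, , drop = FALSE]
            te <- test[test$env == e, , drop = FALSE]
            if (nrow(te) == 0L || nrow(tr) < 2L) next
            res <- tryCatch({
              ftr <- feats[match(tr$line, X$line_ids), , drop = FALSE]
              fte <- feats[match(te$line, X$line_ids), , drop = FALSE]
              tune <- tune_grid(ftr, tr$value, grid = dl_grid,
                                inner_folds = control$dl_inner_folds,
                                seed = dl_seed, epochs = control$dl_epochs)
              pr <- fit_predict(ftr, tr$value, fte, tune$best, seed = dl_seed)
              msep(te$value, pr)
            }, error = function(err) {
              warning(sprintf("DL/G failed for env %s (rep %d fold %d): %s",
                              e, r, f, conditionMessage(err)))
              NULL
            })
            if (!is.null(res)) push("DL", "G", e, r, f, res, nrow(te), NA)
          }
        }
        if ("E+G+GE" %in% models) {
          res <- tryCatch({
            ftr <- build_feature_matrix(X, pheno = train, model = "e-g-ge",
                                        envs = envs)
            fte <- build_feature_matrix(X, pheno = test, model = "e-g-ge",
                                        envs = envs)
            tune <- tune_grid(ftr, train$value, grid = dl_grid,
                              inner_folds = control$dl_inner_folds,
                              seed = dl_seed, epochs = control$dl_epochs)
            fit_predict(ftr, train$value, fte, tune$best, seed = dl_seed)
          }, error = function(err) {
            warning(sprintf("DL/E+G+GE failed (rep %d fold %d): %s",
                            r, f, conditionMessage(err)))
            NULL
          })
          if (!is.null(res)) {
            for (e in envs) {
              sel_e <- test$env == e
              if (!any(sel_e)) next
              push("DL", "E+G+GE", e, r, f,
                   msep(test$value[sel_e], res[sel_e]), sum(sel_e), NA)
            }
          }
        }
      }
    }
  }

  records <- do.call(rbind, records)
  structure(list(records = records, summary = summarize_cv(records),
                 k = k, replicates = reps, seed = attr(plan, "seed")),
            class = "cv_result")
}

#' Aggregate per-partition MSEP records
#'
#' @param records Data frame with columns `method`, `model`, `environment`,
#'   `msep` (e.g. `cv_result$records`).
#' @return Data frame with mean MSEP, SD across partitions and partition count
#'   per (method, model, environment).
#' @export
summarize_cv <- function(records) {
  agg <- stats::aggregate(msep ~ method + model + environment, data = records,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- cbind(agg[, c("method", "model", "environment")],
               as.data.frame(agg$msep))
  names(out) <- c("method", "model", "environment", "msep_mean", "msep_sd",
                  "n_partitions")
  out[order(out$model, out$method, out$environment), , drop = FALSE]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds x %d replicates\n", x$k, x$replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
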