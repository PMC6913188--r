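#' Neural-network baseline configuration
#'
#' Hyperparameters of the feed-forward (multilayer perceptron) baseline:
#' ReLU hidden layers with dropout, a linear output unit, mean-squared-error
#' loss and RMSprop updates with fixed batch size and epoch count. The
#' canonical tuning grid ([dl_default_grid()]) uses 1-4 hidden layers,
#' 80-400 units and dropout 0-0.35 at batch size 56 and 1000 epochs; any
#' positive values are accepted here so the grid can be shrunk for quick runs.
#'
#' @param n_hidden_layers Number of hidden layers (`>= 1`).
#' @param units Units per hidden layer.
#' @param dropout Fraction of hidden units dropped per training step, in
#'   `[0, 1)`.
#' @param batch_size Samples per gradient step (default 56).
#' @param epochs Full passes over the training data (default 1000).
#' @param learning_rate RMSprop step size (default 0.001).
#' @return A `dl_config` list.
#' @export
dl_config <- function(n_hidden_layers = 1L, units = 80L, dropout = 0,
                      batch_size = 56L, epochs = 1000L,
                      learning_rate = 0.001) {
  stopifnot(n_hidden_layers >= 1L, units >= 1L,
            dropout >= 0, dropout < 1, batch_size >= 1L, epochs >= 0L,
            learning_rate > 0)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 units = as.integer(units), dropout = dropout,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 activation = "relu", optimizer = "rmsprop",
                 learning_rate = learning_rate),
            class = "dl_config")
}

#' Canonical hyperparameter grid for the baseline
#'
#' The Cartesian product of 1-4 hidden layers, \{80, 160, 240, 320, 400\}
#' units and dropout \{0, 0.05, 0.10, 0.20, 0.25, 0.35\}: 120 configurations,
#' ordered by layers, then units, then dropout (the tie-breaking order used by
#' [tune_grid()]).
#'
#' @return Data frame with columns `n_hidden_layers`, `units`, `dropout`.
#' @export
dl_default_grid <- function() {
  g <- expand.grid(dropout = c(0, 0.05, 0.10, 0.20, 0.25, 0.35),
                   units = c(80L, 160L, 240L, 320L, 400L),
                   n_hidden_layers = 1:4)
  g <- g[, c("n_hidden_layers", "units", "dropout")]
  g[order(g$n_hidden_layers, g$units, g$dropout), , drop = FALSE]
}

#' Build the baseline's feature matrix
#'
#' For the single-environment model the features are the marker matrix rows
#' (one per line). For the multi-environment model each phenotype record gets
#' its line's markers concatenated with a one-hot environment indicator.
#'
#' @param X A `marker_matrix`.
#' @param pheno A `phenotype_table` (required for `model = "e-g-ge"`); feature
#'   rows align with its records.
#' @param model `"g"` or `"e-g-ge"`.
#' @param envs Ordered environment labels (defaults to those of `pheno`).
#' @return Numeric feature matrix.
#' @export
build_feature_matrix <- function(X, pheno = NULL, model = c("g", "e-g-ge"),
                                 envs = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(X, "marker_matrix"))
  if (model == "g") return(X$X)
  if (is.null(pheno)) stop("model 'e-g-ge' requires a phenotype table")
  if (is.null(envs)) envs <- pheno_envs(pheno)
  li <- match(pheno$line, X$line_ids)
  if (anyNA(li)) stop("phenotyped line absent from marker data")
  ei <- match(pheno$env, envs)
  if (anyNA(ei)) stop("environment label not in 'envs'")
  onehot <- matrix(0, nrow(pheno), length(envs),
                   dimnames = list(NULL, paste0("env_", envs)))
  onehot[cbind(seq_len(nrow(pheno)), ei)] <- 1
  cbind(X$X[li, , drop = FALSE], onehot)
}

# ---- minimal MLP engine (ReLU, dropout, RMSprop, MSE loss) ----

mlp_init <- function(n_in, cfg) {
  sizes <- c(n_in, rep(cfg$units, cfg$n_hidden_layers), 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    # He-normal initialization, suited to ReLU units
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, Xb, dropout = 0, training = FALSE) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  masks <- vector("list", L)
  acts[[1L]] <- Xb
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    if (l < L) {
      a <- pmax(z, 0)
      if (training && dropout > 0) {
        keep <- matrix(stats::rbinom(length(a), 1L, 1 - dropout) / (1 - dropout),
                       nrow(a), ncol(a))
        a <- a * keep
        masks[[l]] <- keep
      }
      acts[[l + 1L]] <- a
    } else acts[[l + 1L]] <- z      # linear output
  }
  list(acts = acts, masks = masks)
}

mlp_train <- function(Xtr, ytr, cfg) {
  n <- nrow(Xtr)
  net <- mlp_init(ncol(Xtr), cfg)
  if (cfg$epochs == 0L) return(net)
  L <- length(net$W)
  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(x) x * 0)
  rho <- 0.9; eps <- 1e-7; lr <- cfg$learning_rate
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- Xtr[idx, , drop = FALSE]
      yb <- ytr[idx]
      fw <- mlp_forward(net, Xb, cfg$dropout, training = TRUE)
      m <- length(idx)
      delta <- 2 * (fw$acts[[L + 1L]] - yb) / m   # d(MSE)/d(output)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$acts[[l]], delta)
        gb <- colSums(delta)
        if (!all(is.finite(gW)))
          stop("non-finite loss gradient (layers=", cfg$n_hidden_layers,
               ", units=", cfg$units, ", dropout=", cfg$dropout, ")")
        vW[[l]] <- rho * vW[[l]] + (1 - rho) * gW^2
        vb[[l]] <- rho * vb[[l]] + (1 - rho) * gb^2
        if (l > 1L) {
          delta <- (delta %*% t(net$W[[l]])) * (fw$acts[[l]] > 0)
          if (cfg$dropout > 0 && !is.null(fw$masks[[l - 1L]]))
            delta <- delta * fw$masks[[l - 1L]]
        }
        net$W[[l]] <- net$W[[l]] - lr * gW / (sqrt(vW[[l]]) + eps)
        net$b[[l]] <- net$b[[l]] - lr * gb / (sqrt(vb[[l]]) + eps)
      }
    }
  }
  net
}

mlp_predict <- function(net, Xnew) {
  fw <- mlp_forward(net, Xnew, dropout = 0, training = FALSE)
  drop(fw$acts[[length(fw$acts)]])
}

#' Tune the baseline's hyperparameters by inner cross-validation
#'
#' Scores every grid row by inner `inner_folds`-fold cross-validated MSEP on
#' the supplied training data; a configuration whose training diverges
#' (non-finite loss) is scored `Inf` and reported. Ties are broken toward
#' fewer layers, then fewer units, then lower dropout.
#'
#' @param train_features,train_y Training features and responses.
#' @param grid Data frame with columns `n_hidden_layers`, `units`, `dropout`
#'   (default [dl_default_grid()]).
#' @param inner_folds Inner CV folds (default 5).
#' @param seed Seed for fold assignment and weight initialization.
#' @param epochs,batch_size Training-schedule overrides applied to every
#'   configuration (`NULL` keeps the [dl_config()] defaults).
#' @return List with `best` (a `dl_config`) and `grid_scores` (the grid with
#'   an `msep` column).
#' @export
tune_grid <- function(train_features, train_y, grid = dl_default_grid(),
                      inner_folds = 5L, seed = 1L, epochs = NULL,
                      batch_size = NULL) {
  grid <- as.data.frame(grid)
  stopifnot(all(c("n_hidden_layers", "units", "dropout") %in% colnames(grid)),
            nrow(grid) >= 1L)
  grid <- grid[order(grid$n_hidden_layers, grid$units, grid$dropout), ,
               drop = FALSE]
  n <- nrow(train_features)
  if (inner_folds > n) stop("inner_folds exceeds the number of samples")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(inner_folds), n))
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- dl_config(grid$n_hidden_layers[i], grid$units[i], grid$dropout[i],
                     batch_size = if (is.null(batch_size)) 56L else batch_size,
                     epochs = if (is.null(epochs)) 1000L else epochs)
    errs <- numeric(inner_folds)
    ok <- TRUE
    for (f in seq_len(inner_folds)) {
      te <- fold == f
      pr <- tryCatch({
        set.seed(seed + 131L * i + f)
        ybar <- mean(train_y[!te])   # train on centered response
        net <- mlp_train(train_features[!te, , drop = FALSE],
                         train_y[!te] - ybar, cfg)
        mlp_predict(net, train_features[te, , drop = FALSE]) + ybar
      }, error = function(e) NULL)
      if (is.null(pr) || !all(is.finite(pr))) { ok <- FALSE; break }
      errs[f] <- msep(train_y[te], pr)
    }
    scores[i] <- if (ok) mean(errs) else Inf
    if (!ok)
      warning(sprintf("config (layers=%d, units=%d, dropout=%.2f) diverged; scored Inf",
                      grid$n_hidden_layers[i], grid$units[i], grid$dropout[i]))
  }
  grid$msep <- scores
  best_i <- which.min(scores)    # grid pre-sorted: first minimum is simplest
  best <- dl_config(grid$n_hidden_layers[best_i], grid$units[best_i],
                    grid$dropout[best_i],
                    batch_size = if (is.null(batch_size)) 56L else batch_size,
                    epochs = if (is.null(epochs)) 1000L else epochs)
  list(best = best, grid_scores = grid)
}

#' Train the baseline on the full training data and predict
#'
#' Trains the network defined by `cfg` on all supplied training samples (the
#' refit after tuning) and returns predictions for `test_features`.
#' The response is centered on its training mean during optimization and the
#' mean is added back to the predictions, so the adaptive-gradient steps work
#' on deviations rather than the raw trait scale. Reproducible for a given
#' `seed`.
#'
#' @param train_features,train_y Training data.
#' @param test_features Feature rows to predict.
#' @param cfg A `dl_config`.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return Numeric vector of predictions.
#' @export
fit_predict <- function(train_features, train_y, test_features, cfg,
                        seed = 1L) {
  stopifnot(inherits(cfg, "dl_config"))
  if (!all(is.finite(train_features)) || !all(is.finite(train_y)))
    stop("non-finite training data")
  set.seed(seed)
  ybar <- mean(train_y)              # train on centered response
  net <- mlp_train(as.matrix(train_features), as.numeric(train_y) - ybar, cfg)
  pr <- mlp_predict(net, as.matrix(test_features)) + ybar
  if (!all(is.finite(pr)))
    stop("non-finite predictions (layers=", cfg$n_hidden_layers,
         ", units=", cfg$units, ", dropout=", cfg$dropout, ")")
  pr
}
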