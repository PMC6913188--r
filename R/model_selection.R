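#' Pick the candidate with maximal marginal likelihood
#'
#' Exact ties are broken toward the simpler (smaller) candidate; `NA` entries
#' (failed fits) are skipped.
#'
#' @param candidates Numeric candidate values (layer counts or bandwidths),
#'   assumed ordered from simplest to most complex.
#' @param logML Log marginal likelihood per candidate (`NA` = failed fit).
#' @return The chosen candidate value.
#' @export
choose_candidate <- function(candidates, logML) {
  stopifnot(length(candidates) == length(logML))
  ok <- which(is.finite(logML))
  if (!length(ok)) stop("no converged candidate to select from")
  best <- max(logML[ok])
  hit <- ok[logML[ok] >= best]
  candidates[min(hit)]
}

new_selection_trace <- function(candidate, logML, converged, chosen, what) {
  out <- data.frame(candidate = candidate, logML = logML,
                    converged = converged,
                    chosen = candidate == chosen, stringsAsFactors = FALSE)
  attr(out, "chosen") <- chosen
  attr(out, "what") <- what
  class(out) <- c("selection_trace", "data.frame")
  out
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace (%s): chosen = %s\n", attr(x, "what"),
              format(attr(x, "chosen"))))
  print(as.data.frame(x))
  invisible(x)
}

# Fit one model variant and return its logML (NA on failure).
fit_candidate_logml <- function(y, K_line, model, inc, line_index) {
  tryCatch({
    if (model == "g") {
      Kobs <- K_line$K[line_index, line_index, drop = FALSE]
      fit_single_kernel(y, Kobs)$logML
    } else {
      K1 <- expand_main_kernel(K_line, inc)
      K2 <- gxe_kernel(K1, inc)
      fit_multi_kernel(y, list(u1 = K1, u2 = K2), ZE = inc$ZE)$logML
    }
  }, error = function(e) NA_real_)
}

prep_selection_inputs <- function(y, line_ids, model, env, lines) {
  n <- length(y)
  if (is.null(lines)) {
    if (n != length(line_ids))
      stop("supply 'lines' when observations are not one-per-line in X order")
    lines <- line_ids
  }
  line_index <- match(as.character(lines), line_ids)
  if (anyNA(line_index)) stop("observation line not found in marker data")
  inc <- NULL
  if (model == "e-g-ge") {
    if (is.null(env)) stop("model 'e-g-ge' requires an 'env' vector")
    env <- as.character(env)
    pt <- phenotype_table(as.character(lines), env, y)
    inc <- build_incidence(pt, line_order = line_ids)
  }
  list(line_index = line_index, inc = inc)
}

#' Select the arc-cosine layer count by marginal likelihood
#'
#' Builds the arc-cosine kernel series up to `l_max`, fits the requested model
#' with each layer's kernel, and returns the per-layer log marginal
#' likelihoods with the argmax (ties toward fewer layers). Failed fits are
#' recorded and skipped.
#'
#' @param y Observation vector.
#' @param X A `marker_matrix` over the genotyped lines.
#' @param model `"g"` (single-kernel) or `"e-g-ge"` (environment + genomic +
#'   G-by-E).
#' @param env Environment label per observation (required for `"e-g-ge"`).
#' @param lines Line id per observation; defaults to one observation per line
#'   in the order of `X`.
#' @param l_max Deepest layer evaluated (default 8).
#' @return A `selection_trace` data frame (`candidate`, `logML`, `converged`,
#'   `chosen`) with the chosen layer in `attr(, "chosen")`.
#' @export
select_ak_layers <- function(y, X, model = c("g", "e-g-ge"), env = NULL,
                             lines = NULL, l_max = 8L) {
  model <- match.arg(model)
  stopifnot(inherits(X, "marker_matrix"), l_max >= 1L)
  prep <- prep_selection_inputs(y, X$line_ids, model, env, lines)
  series <- ak_series(X, l_max)
  logml <- vapply(series, fit_candidate_logml, numeric(1), y = y,
                  model = model, inc = prep$inc, line_index = prep$line_index)
  chosen <- choose_candidate(seq_len(l_max), logml)
  new_selection_trace(seq_len(l_max), logml, is.finite(logml), chosen,
                      what = "AK layers")
}

#' Select the Gaussian-kernel bandwidth by marginal likelihood
#'
#' Fits the requested model at every bandwidth in `grid` (on the
#' `q`-standardized distance scale) and returns the trace with the argmax
#' (ties toward the smaller bandwidth). The chosen value is invariant to the
#' order of the grid.
#'
#' @param y Observation vector.
#' @param D2 A `distance_matrix` from [squared_distances()].
#' @param model `"g"` or `"e-g-ge"`.
#' @param env,lines See [select_ak_layers()].
#' @param grid Candidate bandwidths, all `> 0`
#'   (default `c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2.5, 5)`).
#' @return A `selection_trace` data frame.
#' @export
select_gk_bandwidth <- function(y, D2, model = c("g", "e-g-ge"), env = NULL,
                                lines = NULL,
                                grid = c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2.5, 5)) {
  model <- match.arg(model)
  stopifnot(inherits(D2, "distance_matrix"))
  if (!length(grid) || any(grid <= 0)) stop("grid must be non-empty with h > 0")
  grid <- sort(unique(grid))
  prep <- prep_selection_inputs(y, D2$line_ids, model, env, lines)
  logml <- vapply(grid, function(h) {
    fit_candidate_logml(y, gaussian_kernel(D2, h), model = model,
                        inc = prep$inc, line_index = prep$line_index)
  }, numeric(1))
  chosen <- choose_candidate(grid, logml)
  new_selection_trace(grid, logml, is.finite(logml), chosen,
                      what = "GK bandwidth")
}

#' Write a selection trace to CSV
#' @param trace A `selection_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
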