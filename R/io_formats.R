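#' Read a genotype matrix from CSV/TSV
#'
#' Reads a lines-by-markers genotype table coded 0/1/2 (minor-allele dosage)
#' with an arbitrary set of missing-value tokens. The first column holds line
#' identifiers and the header row holds marker identifiers. Tab separation is
#' auto-detected from a `.tsv` extension; pass `sep` to override.
#'
#' @param path Path to the genotype file.
#' @param missing_tokens Character vector of tokens mapped to missing calls.
#' @param sep Field separator; `NULL` (default) auto-detects from the extension.
#' @return A `raw_genotypes` object: integer call matrix (`NA` = missing) with
#'   `line_ids` rows and `marker_ids` columns.
#' @export
read_genotypes <- function(path, missing_tokens = c("NA", "", "-9"), sep = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      na.strings = character(0)),
    error = function(e) stop("parse error reading '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("parse error: '", path, "' has no genotype calls", call. = FALSE)
  line_ids <- as.character(tab[[1L]])
  marker_ids <- colnames(tab)[-1L]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  cells[cells %in% missing_tokens] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("parse error: non-numeric call '%s' at line '%s', marker '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]], line_ids[bad[1L, 1L]],
                 marker_ids[bad[1L, 2L]]), call. = FALSE)
  new_raw_genotypes(num, line_ids, marker_ids)
}

#' Construct a raw genotype object
#'
#' @param calls Numeric matrix of dosages in \{0, 1, 2\}; `NA` marks missing.
#' @param line_ids,marker_ids Unique row/column identifiers.
#' @return A validated `raw_genotypes` object.
#' @export
new_raw_genotypes <- function(calls, line_ids, marker_ids) {
  calls <- as.matrix(calls)
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(line_ids)) {
    dup <- line_ids[duplicated(line_ids)][1L]
    stop("validation error: duplicate line id '", dup, "'", call. = FALSE)
  }
  if (anyDuplicated(marker_ids))
    stop("validation error: duplicate marker id '",
         marker_ids[duplicated(marker_ids)][1L], "'", call. = FALSE)
  if (nrow(calls) != length(line_ids) || ncol(calls) != length(marker_ids))
    stop("calls dimensions do not match identifier lengths", call. = FALSE)
  ok <- is.na(calls) | calls %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("validation error: call value %s at line '%s', marker '%s' not in {0,1,2}",
                 format(calls[bad[1L], bad[2L]]), line_ids[bad[1L]],
                 marker_ids[bad[2L]]), call. = FALSE)
  }
  dimnames(calls) <- list(line_ids, marker_ids)
  structure(list(calls = calls, line_ids = line_ids, marker_ids = marker_ids),
            class = "raw_genotypes")
}

#' @export
print.raw_genotypes <- function(x, ...) {
  cat(sprintf("raw_genotypes: %d lines x %d markers (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Quality-control filter for genotype calls
#'
#' Removes markers with minor allele frequency strictly below `maf_min` or a
#' missing-call fraction strictly above `max_missing_marker`, then removes
#' lines that do not have strictly more than `min_called_per_line` called
#' markers among the survivors. Row and column order of survivors is
#' preserved; removal counts are attached as the `"qc_log"` attribute and
#' reported via [message()].
#'
#' @param g A `raw_genotypes` object.
#' @param maf_min Minimum minor allele frequency retained (default 0.05).
#' @param max_missing_marker Maximum tolerated missing fraction per marker
#'   (default 0.60; a marker at exactly the threshold is retained).
#' @param min_called_per_line Lines must have more than this many called
#'   markers (default 2000).
#' @return A filtered `raw_genotypes` object.
#' @export
qc_filter <- function(g, maf_min = 0.05, max_missing_marker = 0.60,
                      min_called_per_line = 2000) {
  stopifnot(inherits(g, "raw_genotypes"))
  if (maf_min < 0 || maf_min > 1 || max_missing_marker < 0 || max_missing_marker > 1)
    stop("maf_min and max_missing_marker must lie in [0, 1]")
  if (min_called_per_line < 0) stop("min_called_per_line must be >= 0")

  calls <- g$calls
  p_hat <- colMeans(calls, na.rm = TRUE) / 2       # allele frequency of the counted allele
  maf <- pmin(p_hat, 1 - p_hat)
  maf[is.nan(maf)] <- 0                            # all-missing column: drop as monomorphic
  miss_frac <- colMeans(is.na(calls))
  keep_marker <- maf >= maf_min & miss_frac <= max_missing_marker
  n_maf <- sum(maf < maf_min)
  n_miss <- sum(miss_frac > max_missing_marker & maf >= maf_min)
  if (!any(keep_marker))
    stop("empty after QC: all markers removed", call. = FALSE)

  calls <- calls[, keep_marker, drop = FALSE]
  n_called <- rowSums(!is.na(calls))
  keep_line <- n_called > min_called_per_line
  if (!any(keep_line))
    stop("empty after QC: all lines removed", call. = FALSE)
  n_lines_dropped <- sum(!keep_line)
  calls <- calls[keep_line, , drop = FALSE]

  out <- new_raw_genotypes(calls, g$line_ids[keep_line], g$marker_ids[keep_marker])
  attr(out, "qc_log") <- list(markers_dropped_maf = n_maf,
                              markers_dropped_missing = n_miss,
                              lines_dropped = n_lines_dropped,
                              markers_kept = ncol(calls),
                              lines_kept = nrow(calls))
  message(sprintf("QC: dropped %d markers (MAF < %s), %d markers (missing > %s), %d lines (<= %s called); kept %d lines x %d markers",
                  n_maf, format(maf_min), n_miss, format(max_missing_marker),
                  n_lines_dropped, format(min_called_per_line),
                  nrow(calls), ncol(calls)))
  out
}

#' Impute missing calls and scale the marker matrix
#'
#' Missing calls are replaced by the column mean of non-missing calls, then
#' columns are centered and (optionally) divided by their standard deviation.
#' Constant columns are centered to zero and left unscaled.
#'
#' @param g A `raw_genotypes` object (typically the output of [qc_filter()]).
#' @param scaling One of `"standardized"` (default), `"centered"`, `"raw"`.
#' @return A `marker_matrix` object with fields `X` (n x p, no missing
#'   entries), `p`, `line_ids`, `marker_ids`, `scaling`.
#' @export
impute_and_scale <- function(g, scaling = c("standardized", "centered", "raw")) {
  stopifnot(inherits(g, "raw_genotypes"))
  scaling <- match.arg(scaling)
  X <- g$calls
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing))
    stop("marker '", g$marker_ids[which(all_missing)[1L]],
         "' is entirely missing; run qc_filter first", call. = FALSE)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  if (scaling != "raw") {
    ctr <- colMeans(X)
    X <- sweep(X, 2L, ctr, "-")
    if (scaling == "standardized") {
      s <- apply(X, 2L, stats::sd)
      s[s < 1e-12] <- 1               # constant columns stay at zero
      X <- sweep(X, 2L, s, "/")
    }
  }
  new_marker_matrix(X, g$line_ids, g$marker_ids, scaling)
}

#' Construct a marker matrix object
#'
#' @param X Numeric n x p matrix without missing values.
#' @param line_ids,marker_ids Row/column identifiers.
#' @param scaling One of `"raw"`, `"centered"`, `"standardized"`.
#' @return A `marker_matrix` object.
#' @export
new_marker_matrix <- function(X, line_ids, marker_ids = NULL,
                              scaling = "standardized") {
  X <- as.matrix(X)
  if (anyNA(X)) stop("marker_matrix must not contain missing values")
  line_ids <- as.character(line_ids)
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(line_ids), ncol(X) == length(marker_ids),
            scaling %in% c("raw", "centered", "standardized"))
  if (scaling == "standardized") {
    cm <- colMeans(X)
    if (max(abs(cm)) >= 1e-8)
      stop("standardized marker_matrix has non-zero column means")
  }
  dimnames(X) <- list(line_ids, as.character(marker_ids))
  structure(list(X = X, p = ncol(X), line_ids = line_ids,
                 marker_ids = as.character(marker_ids), scaling = scaling),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers (%s)\n",
              nrow(x$X), x$p, x$scaling))
  invisible(x)
}

#' Construct a long-format phenotype table
#'
#' One row per observed (line, environment) cell; values are per-environment
#' adjusted line means (e.g. BLUEs of grain yield in ton/ha).
#'
#' @param line,env,value Equal-length vectors of line ids, environment labels
#'   and trait values.
#' @param envs Optional ordered environment labels; defaults to order of first
#'   appearance.
#' @return A `phenotype_table` (a `data.frame` with columns `line`, `env`,
#'   `value` and an `envs` attribute).
#' @export
phenotype_table <- function(line, env, value, envs = NULL) {
  line <- as.character(line); env <- as.character(env)
  value <- as.numeric(value)
  stopifnot(length(line) == length(env), length(env) == length(value))
  if (is.null(envs)) envs <- unique(env)
  if (!all(env %in% envs)) stop("environment label not in 'envs'")
  key <- paste(line, env, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, env) pair: ", sub("\r", " / ", key[duplicated(key)][1L]))
  out <- data.frame(line = line, env = env, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "envs") <- as.character(envs)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read a phenotype CSV (columns line, env, value)
#'
#' @param path CSV path with a header containing columns `line`, `env`, `value`.
#' @return A `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "env", "value")
  if (!all(need %in% colnames(tab)))
    stop("phenotype file must have columns line, env, value")
  phenotype_table(tab$line, tab$env, tab$value)
}

#' Write a phenotype table to CSV
#'
#' @param pheno A `phenotype_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno)[, c("line", "env", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Environment labels of a phenotype table
#' @param pheno A `phenotype_table`.
#' @return Character vector of ordered environment labels.
#' @export
pheno_envs <- function(pheno) attr(pheno, "envs")

#' Check that every phenotyped line is genotyped
#'
#' @param pheno A `phenotype_table`.
#' @param X A `marker_matrix` (or anything with `line_ids`).
#' @return `TRUE` invisibly; errors naming the first unmatched line otherwise.
#' @export
validate_pheno_lines <- function(pheno, X) {
  missing <- setdiff(unique(pheno$line), X$line_ids)
  if (length(missing))
    stop("phenotyped line(s) absent from marker data: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Read a YAML run configuration
#'
#' Convenience reader for analysis settings (QC thresholds, kernel settings,
#' cross-validation folds/replicates, seeds). Returns the parsed list as-is;
#' individual functions validate the values they consume.
#'
#' @param path Path to a YAML file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
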