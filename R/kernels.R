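#' Construct a kernel matrix object
#'
#' Symmetrizes, validates and (optionally) PSD-checks a genomic similarity
#' matrix. Eigenvalues are required to satisfy
#' `lambda_min >= -1e-8 * max(1, lambda_max)`; violations within that tolerance
#' are repaired by adding `(|lambda_min| + 1e-10) * I` (reported via
#' [message()]), larger violations are an error.
#'
#' @param K Square numeric matrix.
#' @param kind One of `"GB"`, `"GK"`, `"AK"`.
#' @param line_ids Optional line identifiers (defaults to rownames or L1..Ln).
#' @param layer Layer index `l >= 1` (AK only).
#' @param bandwidth Bandwidth `h > 0` (GK only).
#' @param check_psd Run the eigenvalue check (skip for cheap subsetting of an
#'   already-validated kernel).
#' @return A `kernel_matrix` object with fields `K`, `kind`, `layer`,
#'   `bandwidth`, `line_ids`.
#' @export
new_kernel_matrix <- function(K, kind = c("GB", "GK", "AK"), line_ids = NULL,
                              layer = NULL, bandwidth = NULL, check_psd = TRUE) {
  kind <- match.arg(kind)
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel must be square")
  asym <- max(abs(K - t(K)))
  if (asym >= 1e-10)
    stop("kernel is not symmetric (max |K - t(K)| = ", format(asym), ")")
  K <- (K + t(K)) / 2
  if (is.null(line_ids)) {
    line_ids <- rownames(K)
    if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(K)))
  }
  stopifnot(length(line_ids) == nrow(K))
  if (kind == "AK") {
    if (is.null(layer)) layer <- 1L
    stopifnot(layer >= 1L)
  }
  if (kind == "GK") {
    if (is.null(bandwidth)) stop("GK kernel requires a bandwidth")
    stopifnot(bandwidth > 0)
  }
  if (check_psd) K <- ensure_psd(K)
  dimnames(K) <- list(line_ids, line_ids)
  structure(list(K = K, kind = kind, layer = if (kind == "AK") as.integer(layer) else NULL,
                 bandwidth = if (kind == "GK") bandwidth else NULL,
                 line_ids = as.character(line_ids)),
            class = "kernel_matrix")
}

# PSD guard: small negative eigenvalues (floating-point) are lifted by a
# diagonal shift; violations beyond tolerance indicate a broken kernel.
ensure_psd <- function(K, tol_factor = 1e-8) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev); lmax <- max(ev)
  tol <- tol_factor * max(1, lmax)
  if (lmin < -tol)
    stop("kernel is not positive semidefinite (lambda_min = ", format(lmin), ")")
  if (lmin < 0) {
    eps <- abs(lmin) + 1e-10
    message("kernel repaired: added ", format(eps), " to the diagonal")
    K <- K + diag(eps, nrow(K))
  }
  K
}

#' @export
print.kernel_matrix <- function(x, ...) {
  extra <- if (x$kind == "AK") sprintf(" (layer %d)", x$layer)
           else if (x$kind == "GK") sprintf(" (h = %g)", x$bandwidth) else ""
  cat(sprintf("kernel_matrix %s%s: %d x %d\n", x$kind, extra,
              nrow(x$K), ncol(x$K)))
  invisible(x)
}

# Restrict a kernel to a subset of lines (PSD is preserved; no re-check).
subset_kernel <- function(k, idx) {
  new_kernel_matrix(k$K[idx, idx, drop = FALSE], kind = k$kind,
                    line_ids = k$line_ids[idx], layer = k$layer,
                    bandwidth = k$bandwidth, check_psd = FALSE)
}

#' Linear GBLUP genomic relationship matrix
#'
#' The additive genomic relationship matrix `G = X X' / p` from a scaled
#' marker matrix `X` with `p` markers. With standardized markers the
#' diagonal averages 1 as in the VanRaden parameterization.
#'
#' @param X A `marker_matrix` (standardized scaling expected).
#' @return A `kernel_matrix` of kind `"GB"`.
#' @export
linear_kernel <- function(X) {
  stopifnot(inherits(X, "marker_matrix"))
  if (nrow(X$X) < 2L) stop("need at least two lines")
  if (X$p < 1L) stop("need at least one marker")
  if (X$scaling != "standardized")
    warning("linear kernel expects a standardized marker matrix")
  K <- tcrossprod(X$X) / X$p
  new_kernel_matrix(K, kind = "GB", line_ids = X$line_ids, check_psd = FALSE)
}

#' Pairwise squared Euclidean marker distances
#'
#' Computes `d2[i,j] = sum_k (x_ik - x_jk)^2`, the genetic distance underlying
#' the Gaussian kernel, together with the normalizer `q`, the median of the
#' off-diagonal squared distances (diagonal zeros excluded; an even count is
#' resolved by the midpoint).
#'
#' @param X A `marker_matrix`.
#' @return A `distance_matrix` object with fields `D2`, `q`, `line_ids`.
#' @export
squared_distances <- function(X) {
  stopifnot(inherits(X, "marker_matrix"))
  M <- X$X
  sq <- rowSums(M^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(M)
  D2[D2 < 0] <- 0                      # floating-point underflow
  diag(D2) <- 0
  D2 <- (D2 + t(D2)) / 2
  off <- D2[upper.tri(D2)]
  q <- if (length(off)) stats::median(off) else 0
  structure(list(D2 = D2, q = q, line_ids = X$line_ids),
            class = "distance_matrix")
}

#' Gaussian kernel
#'
#' `K[i,j] = exp(-h * d2[i,j] / q)` where `h` is the bandwidth and `q` the
#' median squared distance from [squared_distances()]. Standardizing by `q`
#' puts the useful bandwidth range on a common scale across data sets.
#'
#' @param d A `distance_matrix`.
#' @param h Bandwidth, `> 0`.
#' @return A `kernel_matrix` of kind `"GK"` with unit diagonal.
#' @export
gaussian_kernel <- function(d, h) {
  stopifnot(inherits(d, "distance_matrix"))
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("bandwidth h must be > 0")
  if (d$q <= 0) stop("q must be > 0 (all lines identical?)")
  K <- exp(-h * d$D2 / d$q)
  diag(K) <- 1
  new_kernel_matrix(K, kind = "GK", line_ids = d$line_ids,
                    bandwidth = h, check_psd = FALSE)
}

# Angular ramp function J(theta) = sin(theta) + (pi - theta) * cos(theta),
# the order-1 arc-cosine angular kernel.
j_ramp <- function(theta) sin(theta) + (pi - theta) * cos(theta)

# Clip a cosine-argument matrix to [-1, 1]; overshoot beyond tol is an error.
clip_cosine <- function(C, tol = 1e-12) {
  over <- max(abs(C)) - 1
  if (over > tol)
    stop("cosine argument exceeds [-1, 1] by ", format(over),
         "; inputs are inconsistent")
  pmin(pmax(C, -1), 1)
}

#' First-layer arc-cosine kernel
#'
#' The arc-cosine kernel of a single hidden layer of ramp (ReLU) units:
#' with `theta = acos(x_i . x_j / (||x_i|| ||x_j||))`,
#' `AK1(x_i, x_j) = (1/pi) ||x_i|| ||x_j|| (sin(theta) + (pi - theta) cos(theta))`.
#' It equals `2 E[max(0, w.x_i) max(0, w.x_j)]` over standard normal weights
#' `w`, i.e. the covariance of an infinitely wide ramp network, and preserves
#' norms: `AK1(x, x) = ||x||^2`, `AK1(x, -x) = 0`. Unlike the Gaussian kernel
#' its diagonal is heterogeneous.
#'
#' @param X A `marker_matrix`; rows with zero norm are rejected.
#' @return List with components `kernel` (a `kernel_matrix`, kind `"AK"`,
#'   layer 1) and `angles` (an `angle_matrix` of pairwise angles in radians).
#' @export
ak_layer1 <- function(X) {
  stopifnot(inherits(X, "marker_matrix"))
  M <- X$X
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm < 1e-12))
    stop("zero-norm line(s): ",
         paste(utils::head(X$line_ids[nrm < 1e-12], 5L), collapse = ", "))
  C <- tcrossprod(M) / outer(nrm, nrm)
  C <- clip_cosine((C + t(C)) / 2)
  diag(C) <- 1
  Theta <- acos(C)
  K <- outer(nrm, nrm) * j_ramp(Theta) / pi
  kernel <- new_kernel_matrix(K, kind = "AK", line_ids = X$line_ids,
                              layer = 1L, check_psd = FALSE)
  angles <- structure(list(Theta = Theta, line_ids = X$line_ids),
                      class = "angle_matrix")
  list(kernel = kernel, angles = angles)
}

#' One step of the arc-cosine layer recursion
#'
#' Deepens an arc-cosine kernel by one emulated hidden layer:
#' `theta_l[i,j] = acos( K_l[i,j] / sqrt(K_l[i,i] K_l[j,j]) )` and
#' `K_{l+1}[i,j] = (1/pi) sqrt(K_l[i,i] K_l[j,j]) * J(theta_l[i,j])` with
#' `J(theta) = sin(theta) + (pi - theta) cos(theta)`. The diagonal is
#' invariant under the recursion (`theta = 0`, `J(0) = pi`).
#'
#' @param K_l A `kernel_matrix` of kind `"AK"` with strictly positive diagonal.
#' @return A `kernel_matrix` of kind `"AK"` at layer `l + 1`.
#' @export
ak_recurse <- function(K_l) {
  if (!inherits(K_l, "kernel_matrix") || K_l$kind != "AK")
    stop("ak_recurse requires an AK kernel_matrix")
  d <- diag(K_l$K)
  if (any(d <= 0))
    stop("AK diagonal must be strictly positive (line '",
         K_l$line_ids[which(d <= 0)[1L]], "')")
  s <- sqrt(d)
  C <- K_l$K / outer(s, s)
  C <- clip_cosine(C)
  diag(C) <- 1
  Theta <- acos(C)
  K_next <- outer(s, s) * j_ramp(Theta) / pi
  new_kernel_matrix(K_next, kind = "AK", line_ids = K_l$line_ids,
                    layer = K_l$layer + 1L, check_psd = FALSE)
}

#' Arc-cosine kernel series over layers 1..l_max
#'
#' @param X A `marker_matrix`.
#' @param l_max Deepest layer to compute (`>= 1`).
#' @return List of `kernel_matrix` objects, element `l` being the layer-`l`
#'   arc-cosine kernel.
#' @export
ak_series <- function(X, l_max) {
  stopifnot(l_max >= 1L)
  out <- vector("list", l_max)
  out[[1L]] <- ak_layer1(X)$kernel
  if (l_max > 1L)
    for (l in seq_len(l_max - 1L)) out[[l + 1L]] <- ak_recurse(out[[l]])
  out
}

#' Write a kernel matrix to CSV (line ids as header row and first column)
#'
#' @param k A `kernel_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(k, path) {
  stopifnot(inherits(k, "kernel_matrix"))
  tab <- data.frame(line = k$line_ids, k$K, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("line", k$line_ids)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kernel matrix from CSV written by [write_kernel()]
#'
#' @param path CSV path.
#' @param kind Kernel kind label to attach (`"GB"`, `"GK"`, `"AK"`).
#' @param layer,bandwidth Metadata to attach (see [new_kernel_matrix()]).
#' @return A `kernel_matrix`.
#' @export
read_kernel <- function(path, kind = "GB", layer = NULL, bandwidth = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  K <- as.matrix(tab[, -1L, drop = FALSE])
  # tolerate round-tripped asymmetry at print precision
  K <- (K + t(K)) / 2
  new_kernel_matrix(K, kind = kind, line_ids = ids, layer = layer,
                    bandwidth = bandwidth)
}
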