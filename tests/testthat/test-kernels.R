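test_that("linear kernel equals XX'/p and has unit average diagonal for standardized markers", {
  X <- new_marker_matrix(diag(2), c("a", "b"), scaling = "raw")
  expect_warning(K <- linear_kernel(X), "standardized")
  expect_equal(unname(K$K), matrix(c(0.5, 0, 0, 0.5), 2))

  # brute-force double-loop oracle on a 5 x 8 fixture
  Xm <- random_marker_matrix(5, 8, seed = 3)
  K2 <- linear_kernel(Xm)
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    oracle[i, j] <- sum(Xm$X[i, ] * Xm$X[j, ]) / Xm$p
  expect_equal(unname(K2$K), oracle, tolerance = 1e-12)

  # law of large numbers: with many standardized markers diag(G) averages 1
  Xl <- random_marker_matrix(40, 5000, seed = 4)
  expect_equal(mean(diag(linear_kernel(Xl)$K)), 1, tolerance = 0.05)
})

test_that("squared distances match the brute-force loop and q the off-diagonal median", {
  X <- new_marker_matrix(rbind(c(0, 0), c(3, 4)), c("a", "b"), scaling = "raw")
  d <- squared_distances(X)
  expect_equal(unname(d$D2), matrix(c(0, 25, 25, 0), 2))

  Xi <- new_marker_matrix(rbind(c(1, 2), c(1, 2)), c("a", "b"), scaling = "raw")
  expect_equal(max(squared_distances(Xi)$D2), 0)

  Xm <- random_marker_matrix(6, 10, seed = 5)
  d2 <- squared_distances(Xm)
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    oracle[i, j] <- sum((Xm$X[i, ] - Xm$X[j, ])^2)
  expect_equal(unname(d2$D2), oracle, tolerance = 1e-10)
  off <- sort(oracle[upper.tri(oracle)])
  expect_equal(d2$q, off[8])                  # 15 off-diagonals: median is the 8th
  # even count resolved by the midpoint
  X4 <- new_marker_matrix(Xm$X[1:4, ], Xm$line_ids[1:4], Xm$marker_ids,
                          scaling = "raw")
  off4 <- sort(squared_distances(X4)$D2[upper.tri(diag(4))])
  expect_equal(squared_distances(X4)$q, (off4[3] + off4[4]) / 2)
})

test_that("Gaussian kernel follows exp(-h d2 / q) with the expected limits and monotonicity", {
  Xm <- random_marker_matrix(8, 15, seed = 6)
  d <- squared_distances(Xm)
  gk <- gaussian_kernel(d, 1)
  expect_equal(unname(diag(gk$K)), rep(1, 8))
  expect_true(all(gk$K > 0 & gk$K <= 1))
  # entry at d2 = q equals exp(-1) by construction
  expect_equal(exp(-1 * d$q / d$q), exp(-1))
  i <- which(abs(d$D2 - d$q) == min(abs(d$D2 - d$q)), arr.ind = TRUE)[1, ]
  expect_equal(gk$K[i[1], i[2]], exp(-d$D2[i[1], i[2]] / d$q), tolerance = 1e-12)
  # h -> 0 limit: all entries -> 1
  expect_equal(max(abs(gaussian_kernel(d, 1e-10)$K - 1)), 0, tolerance = 1e-8)
  # monotone decreasing in h at fixed d2 > 0
  g1 <- gaussian_kernel(d, 0.5)$K; g2 <- gaussian_kernel(d, 2)$K
  offd <- upper.tri(g1)
  expect_true(all(g2[offd] < g1[offd]))
  expect_error(gaussian_kernel(d, 0), "h must be > 0")
  expect_error(gaussian_kernel(d, -1), "h must be > 0")
})

test_that("first-layer arc-cosine kernel preserves norms and kills antipodes", {
  X <- new_marker_matrix(rbind(c(1, 2, 2), c(-1, -2, -2), c(1, 0, 0),
                               c(0, 1, 0)),
                         c("x", "negx", "e1", "e2"), scaling = "raw")
  ak <- ak_layer1(X)
  K <- ak$kernel$K
  expect_equal(K["x", "x"], 9)                 # ||x||^2
  expect_equal(K["x", "negx"], 0, tolerance = 1e-12)
  expect_equal(K["e1", "e2"], 1 / pi, tolerance = 1e-12)   # orthogonal unit pair
  expect_equal(ak$angles$Theta["x", "negx"], pi)
  expect_equal(ak$angles$Theta["e1", "e2"], pi / 2)
  expect_equal(unname(diag(ak$angles$Theta)), rep(0, 4))

  Xz <- new_marker_matrix(rbind(c(0, 0), c(1, 1)), c("zero", "ok"),
                          scaling = "raw")
  expect_error(ak_layer1(Xz), "zero-norm line.*zero")
})

test_that("arc-cosine recursion matches a scalar-loop oracle and leaves the diagonal invariant", {
  Xm <- random_marker_matrix(6, 12, seed = 8)
  ak1 <- ak_layer1(Xm)$kernel
  ak2 <- ak_recurse(ak1)
  expect_equal(ak2$layer, 2L)
  expect_equal(diag(ak2$K), diag(ak1$K), tolerance = 1e-12)

  # independent element-wise implementation of the recursion
  oracle <- matrix(0, 6, 6)
  K <- ak1$K
  for (i in 1:6) for (j in 1:6) {
    cth <- K[i, j] / sqrt(K[i, i] * K[j, j])
    cth <- max(-1, min(1, cth))
    th <- acos(cth)
    oracle[i, j] <- sqrt(K[i, i] * K[j, j]) *
      (sin(th) + (pi - th) * cos(th)) / pi
  }
  expect_equal(unname(ak2$K), oracle, tolerance = 1e-10)

  # zero off-diagonal with unit diagonal maps to 1/pi
  K0 <- new_kernel_matrix(diag(2), kind = "AK", layer = 1L)
  expect_equal(unname(ak_recurse(K0)$K[1, 2]), 1 / pi, tolerance = 1e-12)

  expect_error(ak_recurse(linear_kernel(Xm)), "requires an AK")
})

test_that("ak_series stacks recursions, stays PSD, and keeps its diagonal across layers", {
  Xm <- random_marker_matrix(20, 40, seed = 9)
  series <- ak_series(Xm, 4)
  expect_length(series, 4)
  expect_equal(series[[1]]$K, ak_layer1(Xm)$kernel$K)
  for (l in 1:4) {
    ev <- eigen(series[[l]]$K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(1, max(ev)))
    expect_equal(diag(series[[l]]$K), diag(series[[1]]$K), tolerance = 1e-10)
  }
  expect_length(ak_series(Xm, 1), 1)
})

test_that("AK diagonal is heterogeneous while GK diagonal is homogeneous", {
  Xm <- random_marker_matrix(15, 30, seed = 10)
  ak <- ak_layer1(Xm)$kernel
  gk <- gaussian_kernel(squared_distances(Xm), 1)
  expect_gt(stats::sd(diag(ak$K)), 1e-4)
  expect_equal(unname(diag(gk$K)), rep(1, 15))
})

test_that("kernel constructors commute with line reordering", {
  Xm <- random_marker_matrix(10, 20, seed = 12)
  perm <- c(3, 1, 7, 2, 10, 5, 4, 9, 6, 8)
  Xp <- new_marker_matrix(Xm$X[perm, ], Xm$line_ids[perm], Xm$marker_ids,
                          scaling = "standardized")
  expect_equal(unname(linear_kernel(Xp)$K),
               unname(linear_kernel(Xm)$K[perm, perm]), tolerance = 1e-12)
  expect_equal(unname(gaussian_kernel(squared_distances(Xp), 1)$K),
               unname(gaussian_kernel(squared_distances(Xm), 1)$K[perm, perm]),
               tolerance = 1e-12)
  expect_equal(unname(ak_series(Xp, 2)[[2]]$K),
               unname(ak_series(Xm, 2)[[2]]$K[perm, perm]), tolerance = 1e-10)
})

test_that("Hadamard products of PSD kernels stay PSD (Schur closure)", {
  Xm <- random_marker_matrix(12, 25, seed = 13)
  A <- linear_kernel(Xm)$K
  B <- gaussian_kernel(squared_distances(Xm), 0.8)$K
  ev <- eigen(A * B, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(1, max(ev)))
})

test_that("kernel CSV round-trip preserves entries and line ids", {
  Xm <- random_marker_matrix(6, 10, seed = 14)
  K <- linear_kernel(Xm)
  path <- tempfile(fileext = ".csv")
  write_kernel(K, path)
  back <- read_kernel(path, kind = "GB")
  expect_equal(back$line_ids, K$line_ids)
  expect_equal(unname(back$K), unname(K$K), tolerance = 1e-6)
})

test_that("kernel validation rejects asymmetry and gross indefiniteness", {
  M <- matrix(c(1, 0.5, 0.2, 1), 2)
  expect_error(new_kernel_matrix(M, "GB"), "not symmetric")
  bad <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3 and -1
  expect_error(new_kernel_matrix(bad, "GB"), "not positive semidefinite")
  # a tiny negative eigenvalue is repaired with a logged diagonal shift
  nearly <- matrix(1, 2, 2) - diag(1e-12, 2)   # eigenvalues ~2 and -1e-12
  expect_message(fixed <- new_kernel_matrix(nearly, "GB"), "repaired")
  ev <- eigen(fixed$K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})
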