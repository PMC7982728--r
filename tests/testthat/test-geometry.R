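test_that("sample covariance matches the definition and its symmetries", {
  # 2x2 identity data with 2 samples: P = X X^T / 1 = I
  expect_equal(estimate_scm(diag(2)), diag(2))
  # quadratic scaling in the data
  set.seed(11)
  X <- matrix(rnorm(3 * 200), 3)
  expect_equal(estimate_scm(3.7 * X), 3.7^2 * estimate_scm(X))
  # element-by-element double-loop oracle
  P <- estimate_scm(X)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    oracle[i, j] <- sum(X[i, ] * X[j, ]) / (ncol(X) - 1)
  expect_equal(P, oracle, tolerance = 1e-12)
  # shrinkage blends toward the scaled identity
  Ps <- estimate_scm(X, shrinkage = 0.3)
  expect_equal(Ps, 0.7 * P + 0.3 * (sum(diag(P)) / 3) * diag(3))
})

test_that("covariance estimation rejects degenerate input", {
  expect_error(estimate_scm(matrix(1, 3, 1)), "at least 2 samples")
  # rank-deficient data at zero shrinkage names the eigenvalue problem
  X <- matrix(rnorm(10), 1, 10)
  X3 <- rbind(X, X, X)
  expect_error(estimate_scm(X3), "rank deficient|eigenvalue")
  expect_silent(estimate_scm(X3, shrinkage = 1e-3))
  expect_error(estimate_scm(matrix(rnorm(20), 2), shrinkage = 1), "shrinkage")
})

test_that("geodesic distance matches eigenvalue formula and whitened-log oracle", {
  expect_equal(riemannian_distance(diag(2), diag(2)), 0)
  expect_equal(riemannian_distance(diag(2), exp(2) * diag(2)), 2 * sqrt(2))
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    P1 <- rspd(n); P2 <- rspd(n)
    # oracle: Frobenius norm of logm(P1^{-1/2} P2 P1^{-1/2})
    E <- eigen(P1, symmetric = TRUE)
    W <- E$vectors %*% diag(1 / sqrt(E$values), n) %*% t(E$vectors)
    A <- W %*% P2 %*% W
    EV <- eigen((A + t(A)) / 2, symmetric = TRUE)
    L <- EV$vectors %*% diag(log(EV$values), n) %*% t(EV$vectors)
    expect_equal(riemannian_distance(P1, P2), norm(L, "F"), tolerance = 1e-10)
  }
})

test_that("geodesic distance satisfies the metric axioms and affine invariance", {
  set.seed(22)
  for (rep in 1:15) {
    n <- sample(2:5, 1)
    P1 <- rspd(n); P2 <- rspd(n); P3 <- rspd(n)
    d12 <- riemannian_distance(P1, P2)
    # symmetry, identity, triangle inequality
    expect_equal(d12, riemannian_distance(P2, P1), tolerance = 1e-8)
    expect_gt(d12, 0)
    expect_lte(d12, riemannian_distance(P1, P3) + riemannian_distance(P3, P2) + 1e-8)
    # invariance under congruence by any invertible W
    W <- matrix(rnorm(n * n), n) + diag(n)
    expect_equal(riemannian_distance(t(W) %*% P1 %*% W, t(W) %*% P2 %*% W),
                 d12, tolerance = 1e-8)
  }
})

test_that("euclidean distance is the Frobenius norm of the difference", {
  expect_equal(euclidean_distance(diag(2), diag(2)), 0)
  expect_equal(euclidean_distance(diag(2), 3 * diag(2)), 2 * sqrt(2))
  set.seed(23)
  P1 <- rspd(4); P2 <- rspd(4)
  expect_equal(euclidean_distance(P1, P2), sqrt(sum((P1 - P2)^2)))
  expect_error(euclidean_distance(diag(2), diag(3)), "mismatch")
})

test_that("exp and log maps are mutual inverses at any base point", {
  set.seed(24)
  P <- rspd(4)
  expect_equal(exp_map(P, matrix(0, 4, 4)), P, tolerance = 1e-10)
  expect_equal(log_map(P, P), matrix(0, 4, 4), tolerance = 1e-10)
  # at the identity the maps reduce to plain matrix exp/log
  S <- rsym(3)
  E <- eigen(S, symmetric = TRUE)
  expm_S <- E$vectors %*% diag(exp(E$values)) %*% t(E$vectors)
  expect_equal(exp_map(diag(3), S), expm_S, tolerance = 1e-10)
  Q <- rspd(3)
  EQ <- eigen(Q, symmetric = TRUE)
  logm_Q <- EQ$vectors %*% diag(log(EQ$values)) %*% t(EQ$vectors)
  expect_equal(log_map(diag(3), Q), logm_Q, tolerance = 1e-10)
  # round trips on random pairs
  for (rep in 1:10) {
    P <- rspd(4); Q <- rspd(4)
    expect_equal(exp_map(P, log_map(P, Q)), Q, tolerance = 1e-8)
    S <- rsym(4) / 2
    expect_equal(log_map(P, exp_map(P, S)), S, tolerance = 1e-8)
  }
  # whitened log-map norm reproduces the geodesic distance
  set.seed(25)
  P <- rspd(5); Q <- rspd(5)
  E <- eigen(P, symmetric = TRUE)
  W <- E$vectors %*% diag(1 / sqrt(E$values)) %*% t(E$vectors)
  expect_equal(norm(W %*% log_map(P, Q) %*% W, "F"),
               riemannian_distance(P, Q), tolerance = 1e-10)
  expect_error(exp_map(P, matrix(rnorm(25), 5)), "symmetric")
})

test_that("euclidean mean averages elementwise", {
  expect_equal(euclidean_mean(list(diag(2))), diag(2))
  expect_equal(euclidean_mean(list(diag(2), 3 * diag(2))), 2 * diag(2))
  set.seed(26)
  covs <- replicate(5, rspd(3), simplify = FALSE)
  expect_equal(euclidean_mean(covs), Reduce(`+`, covs) / 5)
  expect_error(euclidean_mean(list()), "non-empty")
})

test_that("Riemannian mean solves the Frechet problem", {
  set.seed(27)
  P <- rspd(3)
  expect_equal(unclass(riemannian_mean(list(P))), P,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unclass(riemannian_mean(list(P, P))), P,
               tolerance = 1e-8, ignore_attr = TRUE)
  # two-point closed form: geodesic midpoint; commuting case = geometric mean
  M <- riemannian_mean(list(diag(2), diag(c(4, 4))))
  expect_equal(unclass(M), diag(c(2, 2)), tolerance = 1e-8, ignore_attr = TRUE)
  # gradient condition sum Log_M(P_i) ~ 0 on random sets
  covs <- replicate(6, rspd(4), simplify = FALSE)
  M <- riemannian_mean(covs)
  G <- Reduce(`+`, lapply(covs, function(Pi) log_map(M, Pi))) / 6
  expect_lt(norm(G, "F"), 1e-6)
  expect_lte(attr(M, "grad_norm"), 1e-8)
})

test_that("Riemannian mean respects commuting and congruence structure", {
  set.seed(28)
  # commuting family: geometric mean of eigenvalues in the shared eigenbasis
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  d <- replicate(5, exp(rnorm(4)), simplify = FALSE)
  covs <- lapply(d, function(di) Q %*% diag(di) %*% t(Q))
  M <- riemannian_mean(covs)
  gm <- exp(Reduce(`+`, lapply(d, log)) / 5)
  expect_equal(unclass(M), Q %*% diag(gm) %*% t(Q),
               tolerance = 1e-7, ignore_attr = TRUE)
  # congruence equivariance
  covs <- replicate(5, rspd(3), simplify = FALSE)
  W <- matrix(rnorm(9), 3) + diag(3)
  M1 <- riemannian_mean(lapply(covs, function(P) t(W) %*% P %*% W))
  M2 <- t(W) %*% riemannian_mean(covs) %*% W
  expect_equal(unclass(M1), unclass(M2), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tangent space mapping vectorizes the whitened log with norm preservation", {
  # reference point itself maps to zero
  set.seed(29)
  P <- rspd(4)
  expect_equal(as.numeric(tangent_space_map(list(P), P)), rep(0, 10),
               tolerance = 1e-10)
  # diagonal example under row-major upper ordering
  expect_equal(as.numeric(tangent_space_map(list(diag(c(exp(2), 1))), diag(2))),
               c(2, 0, 0))
  # vector norm equals geodesic distance to the reference
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    R <- rspd(n); Pi <- rspd(n)
    s <- tangent_space_map(list(Pi), R)
    expect_length(as.numeric(s), n * (n + 1) / 2)
    expect_equal(sqrt(sum(s^2)), riemannian_distance(R, Pi), tolerance = 1e-10)
  }
})

test_that("tangent vectors at the Riemannian mean average to (near) zero", {
  set.seed(30)
  covs <- replicate(8, rspd(4), simplify = FALSE)
  M <- riemannian_mean(covs, tol = 1e-8)
  S <- tangent_space_map(covs, M)
  expect_lt(sqrt(sum(colMeans(S)^2)), 2e-8)
})

test_that("geometry functions validate their inputs", {
  expect_error(riemannian_distance(diag(2), diag(3)), "mismatch")
  notspd <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  expect_error(riemannian_distance(notspd, diag(2)), "positive definite")
  expect_error(log_map(diag(2), notspd), "positive definite")
  asym <- matrix(c(1, 0.5, 0, 1), 2)
  expect_error(riemannian_distance(asym, diag(2)), "symmetric")
})
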