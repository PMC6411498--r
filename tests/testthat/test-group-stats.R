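# Mahalanobis statistic against scalar oracles, the two-level permutation
# scheme against exhaustive enumeration, ratio maps, CDF curves, and the
# volume permutation test.

test_that("mahalanobis_stat: zero for identical means, label symmetry", {
  set.seed(2)
  A <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  B <- A + 0  # identical group values -> identical means
  M <- mahalanobis_stat(A, B)
  expect_equal(M, rep(0, 5), tolerance = 1e-12)
  C <- array(rnorm(5 * 4 * 5), c(5, 4, 5))
  expect_equal(mahalanobis_stat(A, C), mahalanobis_stat(C, A),
               tolerance = 1e-10)
  expect_error(mahalanobis_stat(A[1:1, , , drop = FALSE], C), "2 subjects")
})

test_that("mahalanobis_stat matches the scalar 1-D oracle", {
  # 1-D reduction: pad three constant columns (shrunk covariance keeps the
  # informative coordinate dominant)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  Xa <- array(0, c(3, 1, 1)); Xa[, 1, 1] <- a
  Xb <- array(0, c(3, 1, 1)); Xb[, 1, 1] <- b
  M <- mahalanobis_stat(Xa, Xb)
  nA <- 3; nB <- 3
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (nA + nB - 2)
  oracle <- nA * nB / (nA + nB) * (mean(a) - mean(b))^2 / s2
  expect_equal(M, oracle, tolerance = 1e-12)
})

test_that("pooled-covariance M agrees with a plain-R matrix oracle", {
  set.seed(5)
  N <- 12; W <- 30
  X <- array(rnorm(N * 4 * W), c(N, 4, W))
  M <- mahalanobis_stat(X[1:6, , ], X[7:12, , ])
  oracle <- vapply(seq_len(W), function(w) {
    a <- X[1:6, , w]; b <- X[7:12, , w]
    S <- (crossprod(scale(a, scale = FALSE)) +
          crossprod(scale(b, scale = FALSE))) / (N - 2)
    d <- colMeans(a) - colMeans(b)
    (6 * 6 / 12) * drop(t(d) %*% solve(S) %*% d)
  }, 1)
  expect_equal(M, oracle, tolerance = 1e-10)
})

test_that("permutation p-values track exhaustive enumeration for 3 vs 3", {
  set.seed(9)
  W <- 5
  X <- array(rnorm(6 * 2 * W), c(6, 2, W))
  X[4:6, 1, ] <- X[4:6, 1, ] + 1.5
  # exhaustive oracle over all 20 label splits
  splits <- combn(6, 3)
  Mex <- matrix(0, ncol(splits), W)
  for (s in seq_len(ncol(splits))) {
    ia <- splits[, s]
    Mex[s, ] <- mahalanobis_stat(X[ia, , , drop = FALSE],
                                 X[-ia, , , drop = FALSE])
  }
  obs <- Mex[1, ]  # identity split is column 1 of combn
  p_ex <- colMeans(sweep(Mex, 2, obs, ">=") )
  ct <- permutation_pmap(X[1:3, , ], X[4:6, , ], n_perm = 2000, seed = 4)
  # sampled p within 3 Monte-Carlo SEs of the exhaustive p at every vertex
  se <- sqrt(p_ex * (1 - p_ex) / 2000) + 1e-3
  expect_true(all(abs(ct$p_uncorrected - p_ex) <= 3 * se + 1 / 2001))
})

test_that("permutation_pmap defaults, bounds, and reproducibility", {
  d <- hm_defaults()
  expect_identical(d$n_perm, 10000L)
  expect_identical(d$alpha, 0.05)
  expect_identical(formals(permutation_pmap)$n_perm, 10000L)
  expect_identical(formals(permutation_pmap)$alpha, 0.05)
  set.seed(1)
  X <- array(rnorm(10 * 4 * 8), c(10, 4, 8))
  ct1 <- permutation_pmap(X[1:5, , ], X[6:10, , ], n_perm = 300, seed = 7)
  ct2 <- permutation_pmap(X[1:5, , ], X[6:10, , ], n_perm = 300, seed = 7)
  expect_identical(ct1$p_uncorrected, ct2$p_uncorrected)
  expect_identical(ct1$corrected_p, ct2$corrected_p)
  expect_true(all(ct1$p_uncorrected >= 1 / 301))
  expect_true(all(ct1$p_uncorrected <= 1))
  expect_gt(ct1$corrected_p, 0)
  expect_error(permutation_pmap(X[1:5, , ], X[6:10, , ], n_perm = 50), "100")
  expect_error(permutation_pmap(X[1:5, , ], X[6:10, , ], n_perm = 300,
                                alpha = 1.2), "alpha")
})

test_that("ratio_map closed forms, inversion, and empty masks", {
  D1 <- matrix(1, 5, 10)
  D2 <- matrix(0.81, 6, 10)
  mask <- rep(c(TRUE, FALSE), 5)
  rm_ <- ratio_map(D1, D2, mask)
  expect_equal(rm_$R[mask], rep(1 / 0.81, 5), tolerance = 1e-12)
  expect_true(all(rm_$classification[mask] == "atrophy"))
  expect_true(all(is.na(rm_$R[!mask])))
  # identical groups: R = 1
  rm0 <- ratio_map(D1, matrix(1, 4, 10), mask)
  expect_equal(rm0$R[mask], rep(1, 5))
  # reversing group order inverts R
  rmi <- ratio_map(D2, D1, mask)
  expect_equal(rmi$R[mask], 1 / rm_$R[mask], tolerance = 1e-12)
  expect_warning(r0 <- ratio_map(D1, D2, rep(FALSE, 10)), "empty")
  expect_true(all(is.na(r0$R)))
  expect_error(ratio_map(D1 - 2, D2, mask), "positive")
})

test_that("pvalue_cdf diagonal, degenerate, and deviation cases", {
  fake <- function(p) structure(list(p_uncorrected = p), class = "hm_contrast")
  n <- 200
  unif <- fake((1:n) / n)
  out <- pvalue_cdf(unif)[[1]]
  expect_equal(out$deviation, 0, tolerance = 1e-12)
  tiny <- fake(rep(1 / 1001, n))
  out2 <- pvalue_cdf(tiny)[[1]]
  expect_gt(out2$deviation, 0.99)
  # stronger signal gives larger deviation
  strong <- fake(pmin((1:n) / n, 0.2)^2)
  expect_gt(pvalue_cdf(strong)[[1]]$deviation, out$deviation)
})

test_that("compare_volumes: identical, exhaustive oracle, null calibration", {
  expect_warning(p1 <- compare_volumes(c(5, 5, 5), c(5, 5, 5)), "degenerate")
  expect_equal(p1, 1)
  # strongly separated samples reach the smallest attainable p
  p <- compare_volumes(c(1, 2, 3), c(101, 102, 103), n_perm = 5000, seed = 2)
  # exhaustive: 2 of the 20 splits attain |diff| >= observed (the split and
  # its mirror), so p is near 0.1
  expect_lt(abs(p - 0.1), 0.02)
  # null rejection rate near 5% over replicates
  set.seed(31)
  rej <- mean(replicate(400, {
    compare_volumes(rnorm(8), rnorm(8), n_perm = 200, seed = sample.int(1e6, 1)) < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
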