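# Face Jacobians, TBM/mTBM closed forms, Log-Euclidean invariances, medial
# core and radial distances, and the registered-subject MMS assembly.

test_that("face_jacobian maps source edges to target edges exactly", {
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(face_jacobian(src, src), diag(2))
  # axis stretch: hand evaluation of the closed form
  expect_equal(face_jacobian(src, rbind(c(0, 0), c(2, 0), c(0, 1))),
               diag(c(2, 1)))
  # pure rotation: J orthogonal with unit determinant
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  tgt <- t(R %*% t(src))
  J <- face_jacobian(src, tgt)
  expect_equal(J, R, tolerance = 1e-12)
  expect_equal(det(J), 1, tolerance = 1e-12)
  # random affine maps are recovered exactly
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(4), 2)
    if (abs(det(A)) < 0.1) next
    src2 <- matrix(rnorm(6), 3)
    tgt2 <- t(A %*% t(src2)) + rnorm(2)[col(src2[, 1:2])]
    expect_equal(face_jacobian(src2, t(A %*% t(src2))), A, tolerance = 1e-9)
  }
  expect_error(face_jacobian(rbind(c(0, 0), c(1, 1), c(2, 2)), src),
               "degenerate")
})

test_that("tbm is sqrt(det J) with the determinant attached", {
  expect_equal(as.numeric(tbm(diag(2))), 1)
  expect_equal(as.numeric(tbm(diag(c(2, 1)))), sqrt(2))
  expect_equal(as.numeric(tbm(diag(c(0.25, 1)))), 0.5)
  expect_equal(attr(tbm(diag(c(0.25, 1))), "detJ"), 0.25)
  expect_error(tbm(diag(c(-1, 1))), "flip")
  # tbm(J)^2 recovers det J over random positive-determinant matrices
  set.seed(1)
  for (i in 1:50) {
    J <- matrix(rnorm(4), 2)
    if (det(J) <= 0) J <- J[2:1, ]
    expect_equal(as.numeric(tbm(J))^2, det(J), tolerance = 1e-12)
  }
})

test_that("mtbm closed forms: identity, diagonal, rotation", {
  expect_equal(mtbm(diag(2)), c(0, 0, 0))
  expect_equal(mtbm(diag(c(2, 1))), c(log(2), 0, 0))
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(mtbm(R), c(0, 0, 0), tolerance = 1e-12)
  expect_error(mtbm(matrix(c(1, 0, 0, -1), 2)), "flip")
})

test_that("mtbm equals half the log of the deformation tensor (oracle)", {
  set.seed(11)
  for (i in 1:40) {
    J <- matrix(rnorm(4), 2)
    if (det(J) <= 0) J <- J[2:1, ]
    m <- mtbm(J)
    # independent oracle: eigendecomposition of JJ^T, then 1/2 log
    e <- eigen(J %*% t(J), symmetric = TRUE)
    L <- e$vectors %*% diag(0.5 * log(e$values)) %*% t(e$vectors)
    expect_equal(m, c(L[1, 1], L[1, 2], L[2, 2]), tolerance = 1e-10)
    # invariance to right-multiplication by a rotation
    th <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    expect_equal(mtbm(J %*% R), m, tolerance = 1e-10)
    # axis transposition swaps the diagonal components
    P <- rbind(c(0, 1), c(1, 0))
    mt <- mtbm(P %*% J %*% P)
    expect_equal(mt[c(3, 2, 1)], m, tolerance = 1e-10)
  }
})

make_grid_cylinder <- function(n_u = 12, n_v = 36, radius = 5, height = 30) {
  uu <- seq(0, height, length.out = n_u)
  vv <- 2 * pi * (seq_len(n_v) - 1) / n_v
  pos <- array(0, c(n_u, n_v, 3))
  pos[, , 1] <- matrix(uu, n_u, n_v)
  pos[, , 2] <- matrix(radius * cos(vv), n_u, n_v, byrow = TRUE)
  pos[, , 3] <- matrix(radius * sin(vv), n_u, n_v, byrow = TRUE)
  structure(list(pos = pos, log_lambda = matrix(0, n_u, n_v),
                 mean_curv = matrix(1 / radius, n_u, n_v),
                 n_u = n_u, n_v = n_v, n_fallback = 0L),
            class = "hm_grid_surface")
}

test_that("medial core and radial distances on cylinders", {
  g <- make_grid_cylinder()
  core <- medial_core(g)
  expect_identical(dim(core), c(12L, 3L))
  expect_equal(max(abs(core[, 2:3])), 0, tolerance = 1e-6 * 5)
  expect_equal(as.vector(radial_distances(g)), rep(5, 12 * 36),
               tolerance = 1e-6)
  gs <- g; gs$pos <- g$pos * 0.8
  expect_equal(as.vector(radial_distances(gs)), rep(4, 12 * 36),
               tolerance = 1e-6)
  # elliptic cylinder: distances bounded by the semi-axes
  ge <- g
  ge$pos[, , 2] <- g$pos[, , 2] * (7 / 5)
  ge$pos[, , 3] <- g$pos[, , 3] * (3 / 5)
  rd <- radial_distances(ge)
  expect_true(all(rd >= 3 - 1e-9 & rd <= 7 + 1e-9))
  expect_equal(range(rd), c(3, 7), tolerance = 1e-9)
})

test_that("medial core of a bent tube stays inside the surface", {
  tube <- make_template_tube(30, 20, length = 40, radius_profile = 5,
                             bend = 0.8)
  g <- resample_to_grid(conformal_parameterize(compute_cuts(tube)), 15, 40)
  core <- medial_core(g)
  expect_identical(nrow(core), 15L)
  vol <- rasterize_mesh(tube, voxel_size = 0.5)
  # voxel membership of each core point
  idx <- round(t(solve(vol$affine) %*% t(cbind(core, 1)))[, 1:3]) + 1L
  inside <- vapply(seq_len(nrow(idx)), function(i)
    vol$data[idx[i, 1], idx[i, 2], idx[i, 3]], logical(1))
  expect_true(all(inside))
})

test_that("compute_mms: identity registration gives zero mTBM and unit det J", {
  tube <- make_template_tube(30, 20)
  g <- resample_to_grid(conformal_parameterize(compute_cuts(tube)), 15, 40)
  f <- fluid_register(g, g)
  m <- compute_mms(g, g, f)
  expect_lt(max(abs(m$features[, 1:3])), 1e-6)
  expect_equal(m$detj, rep(1, 600), tolerance = 1e-6)
  expect_equal(m$features[, 4], as.vector(radial_distances(g)),
               tolerance = 1e-9)
})

test_that("compute_mms: uniform 0.9 surface scaling gives the closed form", {
  tube <- make_template_tube(30, 20)
  g <- resample_to_grid(conformal_parameterize(compute_cuts(tube)), 15, 40)
  gs <- g
  gs$pos <- g$pos * 0.9
  f <- fluid_register(gs, g)
  m <- compute_mms(gs, g, f)
  expect_equal(mean(m$detj), 0.81, tolerance = 1e-3)
  expect_equal(mean(m$features[, 1]), log(0.9), tolerance = 1e-3)
  expect_equal(mean(m$features[, 3]), log(0.9), tolerance = 1e-3)
  expect_lt(max(abs(m$features[, 2])), 1e-3)
})

test_that("seeded atrophy lowers in-patch area measures relative to outside", {
  spec <- small_cohort_spec(seed = 21)
  feats <- cohort_features(spec, 15, 40)
  hm <- feats$mms[feats$labels == "HM"]
  inside <- vapply(hm, function(m) mean(m$features[, 1] + m$features[, 3],
                                        na.rm = TRUE), 1)
  m_in <- vapply(hm, function(m) mean((m$features[, 1] + m$features[, 3])[feats$truth]), 1)
  m_out <- vapply(hm, function(m) mean((m$features[, 1] + m$features[, 3])[!feats$truth]), 1)
  expect_lt(mean(m_in), mean(m_out))
})

test_that("MMS round-trips through the flat binary + JSON serialization", {
  spec <- small_cohort_spec(seed = 8)
  feats <- cohort_features(spec, 10, 30)
  m <- feats$mms[[1]]
  path <- file.path(tempdir(), "mms_test.bin")
  write_mms(m, path)
  m2 <- read_mms(path)
  expect_equal(m2$features, m$features)
  expect_equal(m2$detj, m$detj)
  unlink(c(path, sub("\\.bin$", ".json", path)))
})
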