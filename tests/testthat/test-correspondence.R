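# Two-cut topology, conformal tube parameterization (closed-form cylinder
# checks, area accounting, dilatation), grid resampling, and the
# inverse-consistent fluid registration.

test_that("compute_cuts opens a capped tube into an annulus", {
  tube <- make_template_tube(30, 20, length = 40, radius_profile = 5,
                             bend = 0, cross_aspect = 1)
  om <- compute_cuts(tube, cap_fraction = 0.02)
  top <- check_topology(om)
  expect_identical(top$euler, 0L)
  expect_identical(top$n_boundary_loops, 2L)
  # anterior loop sits at the positive end of the principal axis
  t_ant <- mean(om$vertices[om$loop_anterior, 1])
  t_post <- mean(om$vertices[om$loop_posterior, 1])
  expect_gt(abs(t_ant - t_post), 30)
})

test_that("compute_cuts rejects near-isotropic shapes and accepts manual axes", {
  sph <- icosphere_mesh(1, 3)
  expect_error(compute_cuts(sph), "ambiguous")
  om <- compute_cuts(sph, axis = c(0, 0, 1))
  expect_identical(check_topology(om)$euler, 0L)
})

test_that("cuts on a bent tube fall near the ends of the known centerline", {
  tube <- make_template_tube(40, 24, length = 40, bend = 0.8)
  cl <- attr(tube, "centerline")
  om <- compute_cuts(tube, cap_fraction = 0.02)
  # arclength position of each boundary loop, via nearest centerline point
  arc <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  loop_arc <- function(loop) {
    P <- om$vertices[loop, , drop = FALSE]
    mean(vapply(seq_len(nrow(P)), function(i) {
      d2 <- rowSums(sweep(cl, 2, P[i, ])^2)
      arc[which.min(d2)]
    }, 1))
  }
  total <- max(arc)
  expect_lt(loop_arc(om$loop_posterior), 0.1 * total)
  expect_gt(loop_arc(om$loop_anterior), 0.9 * total)
})

test_that("conformal parameterization of a circular cylinder is the closed form", {
  cyl <- make_template_tube(40, 36, length = 30, radius_profile = 4,
                            bend = 0, cross_aspect = 1)
  om <- compute_cuts(cyl, cap_fraction = 0.03)
  ps <- conformal_parameterize(om)
  # u equals the normalized axial coordinate
  x <- ps$vertices[, 1]
  u_true <- (x - min(x)) / (max(x) - min(x))
  expect_lt(max(abs(ps$u - u_true)), 1e-6)
  # boundary values are exact
  expect_identical(min(ps$u), 0)
  expect_identical(max(ps$u), 1)
  # v equals the normalized angle up to gauge rotation and orientation
  ang <- (atan2(ps$vertices[, 3], ps$vertices[, 2]) / (2 * pi)) %% 1
  err <- vapply(c(1, -1), function(s) {
    d <- ((s * ps$v - ang) %% 1)
    offs <- atan2(mean(sin(2 * pi * d)), mean(cos(2 * pi * d))) / (2 * pi)
    max(abs(((d - offs + 0.5) %% 1) - 0.5))
  }, 1)
  expect_lt(min(err), 1e-3)
})

test_that("parameter domain closes exactly and stays flip-free", {
  tube <- make_template_tube(30, 20)
  ps <- conformal_parameterize(compute_cuts(tube))
  F_ <- ps$faces
  pa <- 0.5 * ((ps$u[F_[, 2]] - ps$u[F_[, 1]]) * (ps$v[F_[, 3]] - ps$v[F_[, 1]]) -
               (ps$u[F_[, 3]] - ps$u[F_[, 1]]) * (ps$v[F_[, 2]] - ps$v[F_[, 1]]))
  expect_identical(ps$n_flips, 0L)
  expect_true(all(pa > 0))
  expect_equal(sum(pa), 1, tolerance = 1e-6)
})

test_that("tube template parameterization is near-conformal", {
  tube <- make_template_tube(50, 30)
  ps <- conformal_parameterize(compute_cuts(tube))
  dil <- qc_dilatation(ps)
  expect_lt(quantile(dil, 0.95), 1.5)
})

test_that("resample_to_grid honors shape, bounding box, and surface fidelity", {
  cyl <- make_template_tube(40, 36, length = 30, radius_profile = 4,
                            bend = 0, cross_aspect = 1)
  ps <- conformal_parameterize(compute_cuts(cyl, cap_fraction = 0.03))
  g <- resample_to_grid(ps, 10, 40)
  expect_identical(dim(g$pos), c(10L, 40L, 3L))
  # cylinder nodes lie on the true cylinder radius
  r <- sqrt(g$pos[, , 2]^2 + g$pos[, , 3]^2)
  expect_lt(max(abs(r - 4)), 4e-3 * 4)
  # tiny grid stays within the surface bounding box
  g2 <- resample_to_grid(ps, 2, 4)
  expect_identical(dim(g2$pos), c(2L, 4L, 3L))
  bb <- apply(ps$vertices, 2, range)
  P <- matrix(g2$pos, ncol = 3)
  expect_true(all(t(P) >= bb[1, ] - 1e-9 & t(P) <= bb[2, ] + 1e-9))
  # default shape gives the full analysis vertex count
  d <- hm_defaults()
  expect_identical(d$grid_nu * d$grid_nv, 15000L)
})

test_that("fluid registration: identity, periodic shift recovery, inverse consistency", {
  tube <- make_template_tube(50, 30)
  g <- resample_to_grid(conformal_parameterize(compute_cuts(tube)), 20, 75)
  f0 <- fluid_register(g, g)
  expect_lt(max(abs(c(f0$pullback$du, f0$pullback$dv))), 1e-8)

  roll <- function(m, k) m[, ((seq_len(ncol(m)) - 1 - k) %% ncol(m)) + 1]
  g2 <- g
  g2$log_lambda <- roll(g$log_lambda, 3)
  g2$mean_curv <- roll(g$mean_curv, 3)
  g2$pos <- array(c(roll(g$pos[, , 1], 3), roll(g$pos[, , 2], 3),
                    roll(g$pos[, , 3], 3)), dim(g$pos))
  f <- fluid_register(g2, g)
  expect_lt(abs(median(f$pullback$dv) - 3), 0.5)
  expect_lt(f$ic_deviation, f$params$ic_tol)
  # mismatch decreases monotonically across accepted outer iterations
  expect_true(all(diff(f$trace) <= 1e-12))
  expect_true(all(f$node_detj > 0))
})

test_that("registration of distinct subjects composes to identity within tolerance", {
  spec <- small_cohort_spec(seed = 3)
  co <- make_cohort(spec)
  g1 <- resample_to_grid(conformal_parameterize(compute_cuts(co$meshes[[1]])), 20, 75)
  g2 <- resample_to_grid(conformal_parameterize(compute_cuts(co$meshes[[5]])), 20, 75)
  f <- fluid_register(g1, g2)
  comp <- hippomorph:::compose_fields(f$pullback, f$forward)
  dev <- quantile(sqrt(comp$du^2 + comp$dv^2), 0.95)
  expect_lt(dev, f$params$ic_tol)
})

test_that("gauge alignment pins the elliptic major axis and is idempotent", {
  tube <- make_template_tube(30, 20)
  g <- resample_to_grid(conformal_parameterize(compute_cuts(tube)), 20, 75)
  ga <- align_grid_gauge(g)
  # after alignment, a second pass finds (almost) no offset
  gb <- align_grid_gauge(ga)
  expect_lt(abs(attr(gb, "gauge_offset")), 0.2)
  # the major axis now sits at column 1 on middle rows
  i <- 10
  X <- matrix(ga$pos[i, , ], 75, 3)
  Xc <- sweep(X, 2, colMeans(X))
  d2 <- rowSums(Xc^2)
  jmax <- which.max(d2)
  dj <- min(abs(jmax - 1), 75 - abs(jmax - 1))
  # the farthest node lies at either end of the major axis (v = 0 or 0.5)
  expect_lte(min(dj, abs(dj - 37.5)), 2.5)
})
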