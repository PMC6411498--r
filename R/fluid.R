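# Inverse-consistent fluid surface registration on the parameter grid.
# Demons-style compositive updates with Gaussian velocity smoothing (the
# standard fluid approximation), periodic in the angular direction v and with
# zero normal displacement at the tube ends (u = 0, 1).  Forward and backward
# problems are solved jointly and symmetrized by averaging each field with
# the inverse of the other.

# separable Gaussian smoothing: reflected in u (rows), periodic in v (cols)
gauss_kernel_mat <- function(n, sigma, periodic) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    idx <- seq_len(n) + d
    if (periodic) {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      idx <- pmin(pmax(idx, 1L), n)  # replicate edge
    }
    K[cbind(seq_len(n), idx)] <- K[cbind(seq_len(n), idx)] + k[d + r + 1L]
  }
  K
}

smooth_field <- function(M, Ku, Kv) Ku %*% M %*% t(Kv)

# bilinear sampling of a grid image at (row, col) positions; rows clamped to
# [1, n_u], columns periodic with period n_v
sample_bilinear <- function(img, ru, cv) {
  n_u <- nrow(img); n_v <- ncol(img)
  dm <- dim(ru)
  ru <- pmin(pmax(as.vector(ru), 1), n_u)
  cv <- as.vector(cv)
  r0 <- pmin(floor(ru), n_u - 1)
  fu <- ru - r0
  c0 <- floor(cv)
  fv <- cv - c0
  wrap <- function(ci) ((as.integer(ci) - 1L) %% n_v) + 1L
  i00 <- cbind(r0, wrap(c0)); i10 <- cbind(r0 + 1, wrap(c0))
  i01 <- cbind(r0, wrap(c0 + 1)); i11 <- cbind(r0 + 1, wrap(c0 + 1))
  out <- (1 - fu) * (1 - fv) * img[i00] + fu * (1 - fv) * img[i10] +
    (1 - fu) * fv * img[i01] + fu * fv * img[i11]
  if (!is.null(dm)) dim(out) <- dm
  out
}

# central-difference gradients; periodic in v, one-sided at u borders
grid_gradient <- function(img) {
  n_u <- nrow(img); n_v <- ncol(img)
  gu <- img
  gu[2:(n_u - 1), ] <- (img[3:n_u, ] - img[1:(n_u - 2), ]) / 2
  gu[1, ] <- img[2, ] - img[1, ]
  gu[n_u, ] <- img[n_u, ] - img[n_u - 1, ]
  gv <- (img[, c(2:n_v, 1)] - img[, c(n_v, 1:(n_v - 1))]) / 2
  list(u = gu, v = gv)
}

zscore <- function(m) (m - mean(m)) / max(sd(as.vector(m)), 1e-12)

# z-scored feature channels, optionally pre-smoothed on the grid (suppresses
# vertex-noise-driven curvature speckle before matching)
feature_stack <- function(grid, feature_sigma = 0) {
  feats <- list(grid$log_lambda, grid$mean_curv)
  if (feature_sigma > 0) {
    Ku <- gauss_kernel_mat(nrow(feats[[1]]), feature_sigma, periodic = FALSE)
    Kv <- gauss_kernel_mat(ncol(feats[[1]]), feature_sigma, periodic = TRUE)
    feats <- lapply(feats, function(m) as.matrix(smooth_field(m, Ku, Kv)))
  }
  lapply(feats, zscore)
}

field_ssd <- function(fixed_feats, moving_feats, disp) {
  n_u <- nrow(disp$du)
  ru <- matrix(seq_len(n_u), n_u, ncol(disp$du)) + disp$du
  cv <- matrix(seq_len(ncol(disp$du)), n_u, ncol(disp$du), byrow = TRUE) + disp$dv
  s <- 0
  for (c_ in seq_along(fixed_feats)) {
    w <- sample_bilinear(moving_feats[[c_]], ru, cv)
    s <- s + mean((fixed_feats[[c_]] - w)^2)
  }
  s
}

# best global circular shift (in columns) of the moving features onto the
# fixed features; returns the signed shift in cells
best_rotation <- function(fixed_feats, moving_feats) {
  n_v <- ncol(fixed_feats[[1]])
  ssd <- vapply(seq_len(n_v) - 1L, function(k) {
    idx <- ((seq_len(n_v) - 1L + k) %% n_v) + 1L
    s <- 0
    for (c_ in seq_along(fixed_feats))
      s <- s + mean((moving_feats[[c_]][, idx] - fixed_feats[[c_]])^2)
    s
  }, numeric(1))
  k <- which.min(ssd) - 1L
  if (k > n_v / 2) k <- k - n_v
  k
}

demons_direction <- function(fixed_feats, moving_feats, params) {
  n_u <- nrow(fixed_feats[[1]]); n_v <- ncol(fixed_feats[[1]])
  Ku <- gauss_kernel_mat(n_u, params$sigma, periodic = FALSE)
  Kv <- gauss_kernel_mat(n_v, params$sigma, periodic = TRUE)
  if (params$disp_sigma > 0) {
    Kud <- gauss_kernel_mat(n_u, params$disp_sigma, periodic = FALSE)
    Kvd <- gauss_kernel_mat(n_v, params$disp_sigma, periodic = TRUE)
  }
  init <- if (is.null(params$init_dv)) 0 else params$init_dv
  du <- matrix(0, n_u, n_v); dv <- matrix(init, n_u, n_v)
  R0 <- matrix(seq_len(n_u), n_u, n_v)
  C0 <- matrix(seq_len(n_v), n_u, n_v, byrow = TRUE)
  grads <- lapply(fixed_feats, grid_gradient)
  trace <- numeric(0)
  step <- params$step
  ssd <- field_ssd(fixed_feats, moving_feats, list(du = du, dv = dv))
  trace <- ssd
  n_regrid <- 0L
  for (it in seq_len(params$max_iter)) {
    vu <- matrix(0, n_u, n_v); vv <- matrix(0, n_u, n_v)
    denom <- matrix(params$kappa^2, n_u, n_v)
    num_u <- matrix(0, n_u, n_v); num_v <- matrix(0, n_u, n_v)
    for (c_ in seq_along(fixed_feats)) {
      w <- sample_bilinear(moving_feats[[c_]], R0 + du, C0 + dv)
      r <- w - fixed_feats[[c_]]
      g <- grads[[c_]]
      num_u <- num_u - r * g$u
      num_v <- num_v - r * g$v
      denom <- denom + g$u^2 + g$v^2 + r^2
    }
    vu <- num_u / denom
    vv <- num_v / denom
    vu <- as.matrix(smooth_field(vu, Ku, Kv)) * step
    vv <- as.matrix(smooth_field(vv, Ku, Kv)) * step
    # cap the incremental displacement so each composed increment stays
    # diffeomorphic (regridding)
    mag <- sqrt(vu^2 + vv^2)
    mx <- max(mag)
    if (mx > params$max_step) {
      sc <- params$max_step / mx
      vu <- vu * sc; vv <- vv * sc
      n_regrid <- n_regrid + 1L
    }
    vu[1, ] <- 0; vu[n_u, ] <- 0  # zero normal displacement at tube ends
    # compositive update: phi <- phi o (id + v)
    du_new <- vu + sample_bilinear(du, R0 + vu, C0 + vv)
    dv_new <- vv + sample_bilinear(dv, R0 + vu, C0 + vv)
    if (params$disp_sigma > 0) {  # diffusion regularization of the total field
      du_new <- as.matrix(smooth_field(du_new, Kud, Kvd))
      dv_new <- as.matrix(smooth_field(dv_new, Kud, Kvd))
      du_new[1, ] <- 0; du_new[n_u, ] <- 0
    }
    ssd_new <- field_ssd(fixed_feats, moving_feats,
                         list(du = du_new, dv = dv_new))
    if (ssd_new <= ssd) {
      du <- du_new; dv <- dv_new
      improve <- ssd - ssd_new
      ssd <- ssd_new
      trace <- c(trace, ssd)
      step <- min(step * 1.05, params$step)
      if (improve < params$tol * (ssd + 1e-12)) break
    } else {
      step <- step / 2
      if (step < 1e-4) break
    }
  }
  list(du = du, dv = dv, trace = trace, n_regrid = n_regrid)
}

# fixed-point inverse of a displacement field (grid-cell units)
invert_field <- function(disp, iters = 10L) {
  n_u <- nrow(disp$du); n_v <- ncol(disp$du)
  R0 <- matrix(seq_len(n_u), n_u, n_v)
  C0 <- matrix(seq_len(n_v), n_u, n_v, byrow = TRUE)
  iu <- -disp$du; iv <- -disp$dv
  for (k in seq_len(iters)) {
    iu <- -sample_bilinear(disp$du, R0 + iu, C0 + iv)
    iv <- -sample_bilinear(disp$dv, R0 + iu, C0 + iv)
  }
  list(du = iu, dv = iv)
}

compose_fields <- function(a, b) {
  # (a then b): x -> x + a(x) + b(x + a(x))
  n_u <- nrow(a$du); n_v <- ncol(a$du)
  R0 <- matrix(seq_len(n_u), n_u, n_v)
  C0 <- matrix(seq_len(n_v), n_u, n_v, byrow = TRUE)
  list(du = a$du + sample_bilinear(b$du, R0 + a$du, C0 + a$dv),
       dv = a$dv + sample_bilinear(b$dv, R0 + a$du, C0 + a$dv))
}

field_jacobians <- function(disp) {
  # Jacobian determinant of (id + disp) per node, central differences
  gu_u <- grid_gradient(disp$du)
  gv_v <- grid_gradient(disp$dv)
  (1 + gu_u$u) * (1 + gv_v$v) - gu_u$v * gv_v$u
}

#' Inverse-consistent fluid registration of two grid surfaces
#'
#' Matches the 2-channel feature image (z-scored log conformal factor and
#' mean curvature) of `source` to `target` with demons-style compositive
#' updates under Gaussian velocity smoothing, periodic in v and with zero
#' normal displacement at u ends. The forward (target frame -> source
#' coordinates) and backward problems are solved jointly and symmetrized by
#' averaging with the partner inverse until composition deviates from the
#' identity by less than `ic_tol` (95th percentile, grid cells).
#'
#' @param source,target `hm_grid_surface` objects of identical shape.
#' @param params list: `sigma` (smoothing, cells), `max_iter`, `step`,
#'   `max_step` (regridding cap, cells), `kappa` (demons stabilizer),
#'   `tol` (relative SSD improvement), `ic_tol` (cells), `n_sym`
#'   (symmetrization sweeps).
#' @return An `hm_deformation`: `pullback` (displacement on target nodes
#'   into source coordinates; `du`, `dv` in grid cells), `forward`
#'   (source-frame counterpart), `trace`, inverse-consistency deviation, and
#'   node Jacobian determinants of the pullback map.
#' @export
fluid_register <- function(source, target, params = list()) {
  stopifnot(inherits(source, "hm_grid_surface"),
            inherits(target, "hm_grid_surface"),
            source$n_u == target$n_u, source$n_v == target$n_v)
  p <- utils::modifyList(list(sigma = 3, max_iter = 80, step = 0.8,
                              max_step = 0.4, kappa = 0.5, tol = 1e-7,
                              ic_tol = 0.1, n_sym = 6, feature_sigma = 1.5,
                              disp_sigma = 3), params)
  sf <- feature_stack(source, p$feature_sigma)
  tf <- feature_stack(target, p$feature_sigma)
  # global rotational initialization: the angular gauge can differ between
  # subjects by more than the demons capture range
  k <- best_rotation(tf, sf)
  fwd <- demons_direction(fixed_feats = tf, moving_feats = sf,
                          utils::modifyList(p, list(init_dv = k)))
  bwd <- demons_direction(fixed_feats = sf, moving_feats = tf,
                          utils::modifyList(p, list(init_dv = -k)))
  a <- list(du = fwd$du, dv = fwd$dv)
  b <- list(du = bwd$du, dv = bwd$dv)
  ic_dev <- Inf
  for (s in seq_len(p$n_sym)) {
    ib <- invert_field(b)
    ia <- invert_field(a)
    a <- list(du = 0.5 * (a$du + ib$du), dv = 0.5 * (a$dv + ib$dv))
    b <- list(du = 0.5 * (b$du + ia$du), dv = 0.5 * (b$dv + ia$dv))
    comp <- compose_fields(a, b)
    ic_dev <- as.numeric(quantile(sqrt(comp$du^2 + comp$dv^2), 0.95))
    if (ic_dev < p$ic_tol) break
  }
  a$du[1, ] <- 0; a$du[source$n_u, ] <- 0
  detj <- field_jacobians(a)
  if (any(detj <= 0))
    stop("diffeomorphism violated: ", sum(detj <= 0),
         " non-positive node Jacobians in the final field", call. = FALSE)
  structure(list(pullback = a, forward = b,
                 trace = fwd$trace, trace_backward = bwd$trace,
                 ic_deviation = ic_dev, node_detj = detj,
                 n_regrid = fwd$n_regrid + bwd$n_regrid,
                 params = p, n_u = source$n_u, n_v = source$n_v),
            class = "hm_deformation")
}

#' @export
print.hm_deformation <- function(x, ...) {
  cat(sprintf(
    "<hm_deformation> %d x %d grid, %d iterations, ic deviation %.4f cells\n",
    x$n_u, x$n_v, length(x$trace), x$ic_deviation))
  invisible(x)
}
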