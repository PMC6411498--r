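# Common rectangular analysis grid over the tube parameter domain:
# n_u rows span u in [0,1] (cut to cut), n_v columns span the periodic
# angular coordinate v in [0,1).

#' Resample a parameterized surface to a rectangular grid
#'
#' Grid nodes (u_i, v_j), u_i equally spaced on \[0,1\], v_j on \[0,1),
#' are located in the parameter triangulation (with periodic wrap copies in
#' v) and position, conformal factor and mean curvature are interpolated
#' barycentrically. Nodes falling in numeric gaps are filled by
#' nearest-triangle projection and counted; more than `max_fallback_fraction`
#' such nodes raises a quality error.
#'
#' @param ps an `hm_param_surface`.
#' @param n_u grid rows (default 100).
#' @param n_v grid columns (default 150; 100 x 150 = 15,000 analysis
#'   vertices).
#' @param max_fallback_fraction tolerated fraction of gap-filled nodes.
#' @return An `hm_grid_surface` with `pos` (n_u x n_v x 3), `log_lambda`,
#'   `mean_curv` (n_u x n_v), and bookkeeping fields.
#' @export
resample_to_grid <- function(ps, n_u = 100L, n_v = 150L,
                             max_fallback_fraction = 0.01) {
  stopifnot(n_u >= 2L, n_v >= 2L)
  F_ <- ps$faces
  tri <- cbind(ps$u[F_[, 1]], ps$v[F_[, 1]],
               ps$u[F_[, 2]], ps$v[F_[, 2]],
               ps$u[F_[, 3]], ps$v[F_[, 3]])
  # periodic wrap copies in v (the cut path can wander, so two copies each
  # way are needed to guarantee coverage of the unit band)
  shift <- function(s) { t2 <- tri; t2[, c(2, 4, 6)] <- t2[, c(2, 4, 6)] + s; t2 }
  tri_all <- rbind(tri, shift(1), shift(-1), shift(2), shift(-2))
  face_of <- rep(seq_len(nrow(F_)), 5L)
  uu <- seq(0, 1, length.out = n_u)
  vv <- (seq_len(n_v) - 1L) / n_v
  P <- cbind(rep(uu, times = n_v), rep(vv, each = n_u))
  loc <- cpp_locate_points2d(tri_all, P, 1e-7)
  fidx <- loc$face
  fallback <- is.na(fidx)
  fidx[fallback] <- loc$fallback_face[fallback]
  if (anyNA(fidx)) stop("grid nodes could not be located", call. = FALSE)
  n_fallback <- sum(fallback)
  if (n_fallback > max_fallback_fraction * nrow(P))
    stop("grid resampling quality: ", n_fallback,
         " nodes outside the parameter triangulation", call. = FALSE)
  f0 <- face_of[fidx]
  b <- loc$bary
  interp <- function(x) {
    b[, 1] * x[F_[f0, 1]] + b[, 2] * x[F_[f0, 2]] + b[, 3] * x[F_[f0, 3]]
  }
  pos <- array(0, c(n_u, n_v, 3))
  for (d in 1:3) pos[, , d] <- matrix(interp(ps$vertices[, d]), n_u, n_v)
  structure(list(pos = pos,
                 log_lambda = matrix(interp(ps$log_lambda), n_u, n_v),
                 mean_curv = matrix(interp(ps$mean_curv), n_u, n_v),
                 n_u = n_u, n_v = n_v, n_fallback = n_fallback,
                 id = ps$id, side = ps$side),
            class = "hm_grid_surface")
}

#' @export
print.hm_grid_surface <- function(x, ...) {
  cat(sprintf("<hm_grid_surface> %d x %d nodes (%d gap-filled)\n",
              x$n_u, x$n_v, x$n_fallback))
  invisible(x)
}

grid_points <- function(grid) {
  matrix(grid$pos, ncol = 3)
}

#' Align the angular gauge of a grid surface to its cross-section moments
#'
#' Estimates, per ring, the in-plane major axis of the node spread and the
#' sub-cell angular position where it occurs; the circular mean over the
#' middle rows gives a rotation offset, and all node data are resampled so
#' the major axis (on the bend-plane side selected by the centerline
#' sagitta) sits at v = 0. This pins the rotational gauge to a global
#' geometric moment, independent of surface features or localized
#' deformations. Near-circular cross-sections (moment ratio < `min_ratio`)
#' are returned unchanged.
#'
#' @param grid an `hm_grid_surface`.
#' @param min_ratio minimal in-plane eigenvalue ratio for a defined axis.
#' @param per_row also correct twist: each ring is aligned to its own axis
#'   position, smoothed along u (rings without a defined axis inherit the
#'   global offset).
#' @param twist_sigma Gaussian smoothing (rows) of the per-ring offsets.
#' @return The re-gauged `hm_grid_surface` with attribute `gauge_offset`
#'   (cells; the circular-mean offset that was removed).
#' @export
align_grid_gauge <- function(grid, min_ratio = 1.05, per_row = TRUE,
                             twist_sigma = 2) {
  n_u <- grid$n_u; n_v <- grid$n_v
  core <- medial_core(grid)
  # bend-plane side: offset of the mid-core from the end-to-end chord
  chord <- core[n_u, ] - core[1, ]
  chord <- chord / sqrt(sum(chord^2))
  midoff <- core[round(n_u / 2), ] - core[1, ]
  perp <- midoff - sum(midoff * chord) * chord
  if (sqrt(sum(perp^2)) < 1e-8) perp <- c(0, 0, 1)  # straight tube fallback
  ang <- rep(NA_real_, n_u)
  for (i in seq_len(n_u)) {
    X <- matrix(grid$pos[i, , ], n_v, 3)
    Xc <- sweep(X, 2, colMeans(X))
    ev <- eigen(crossprod(Xc) / n_v, symmetric = TRUE)
    if (ev$values[1] < min_ratio * ev$values[2]) next
    d <- ev$vectors[, 1]
    if (sum(d * perp) < 0) d <- -d
    val <- Xc %*% d
    j <- which.max(val)
    jm <- (j - 2) %% n_v + 1; jp <- j %% n_v + 1
    den <- val[jm] - 2 * val[j] + val[jp]
    delta <- if (abs(den) > 1e-12) 0.5 * (val[jm] - val[jp]) / den else 0
    delta <- max(min(delta, 0.5), -0.5)
    ang[i] <- 2 * pi * (j - 1 + delta) / n_v
  }
  ok <- !is.na(ang)
  if (sum(ok) < 2L) {
    attr(grid, "gauge_offset") <- 0
    return(grid)
  }
  off_global <- atan2(mean(sin(ang[ok])), mean(cos(ang[ok])))
  if (per_row) {
    # unwrap per-row angles about the global offset, fill gaps, smooth
    rel <- ang - off_global
    rel <- atan2(sin(rel), cos(rel))
    rel[!ok] <- 0
    if (twist_sigma > 0) {
      r <- max(1L, ceiling(3 * twist_sigma))
      k <- exp(-(seq(-r, r))^2 / (2 * twist_sigma^2))
      idx <- function(i, d) pmin(pmax(i + d, 1L), n_u)
      sm <- numeric(n_u)
      wt <- numeric(n_u)
      for (d_ in seq(-r, r)) {
        sm <- sm + k[d_ + r + 1] * rel[idx(seq_len(n_u), d_)]
        wt <- wt + k[d_ + r + 1]
      }
      rel <- sm / wt
    }
    off_rows <- (off_global + rel) / (2 * pi) * n_v
  } else {
    off_rows <- rep(off_global / (2 * pi) * n_v, n_u)
  }
  out <- grid
  roll_row <- function(vec, off) {
    src <- (seq_len(n_v) - 1 + off) %% n_v
    j0 <- floor(src); fj <- src - j0
    jA <- as.integer(j0) %% n_v + 1L
    jB <- (as.integer(j0) + 1L) %% n_v + 1L
    vec[jA] * (1 - fj) + vec[jB] * fj
  }
  for (i in seq_len(n_u)) {
    for (d_ in 1:3) out$pos[i, , d_] <- roll_row(grid$pos[i, , d_], off_rows[i])
    out$log_lambda[i, ] <- roll_row(grid$log_lambda[i, ], off_rows[i])
    out$mean_curv[i, ] <- roll_row(grid$mean_curv[i, ], off_rows[i])
  }
  attr(out, "gauge_offset") <- off_global / (2 * pi) * n_v
  attr(out, "gauge_twist") <- off_rows
  out
}

#' Medial core (centerline) of a grid surface
#'
#' Core point i is the arithmetic centroid of ring i's nodes.
#'
#' @param grid an `hm_grid_surface`.
#' @return n_u x 3 matrix of core points.
#' @export
medial_core <- function(grid) {
  t(apply(grid$pos, 1, colMeans))
}

#' Radial distances from grid nodes to their ring's core point
#'
#' @param grid an `hm_grid_surface`.
#' @param core optional precomputed [medial_core()].
#' @return n_u x n_v matrix of distances (mm).
#' @export
radial_distances <- function(grid, core = medial_core(grid)) {
  d2 <- matrix(0, grid$n_u, grid$n_v)
  for (d in 1:3) d2 <- d2 + (grid$pos[, , d] - core[, d])^2
  sqrt(d2)
}

#' Serialize a grid surface as VTK structured grid plus JSON sidecar
#'
#' @param grid an `hm_grid_surface`.
#' @param path output `.vtk` path; the sidecar is written next to it.
#' @param point_data optional named list of n_u x n_v matrices.
#' @return `path`, invisibly.
#' @export
write_grid_vtk <- function(grid, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- grid$n_u * grid$n_v
  writeLines(c("# vtk DataFile Version 3.0", "hippomorph grid surface",
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", grid$n_u, grid$n_v),
               sprintf("POINTS %d double", n)), con)
  P <- grid_points(grid)
  writeLines(apply(P, 1, paste, collapse = " "), con)
  pd <- c(list(log_lambda = grid$log_lambda, mean_curv = grid$mean_curv),
          point_data)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(pd)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(as.vector(pd[[nm]]), digits = 10), con)
  }
  sidecar <- sub("\\.vtk$", ".json", path)
  jsonlite::write_json(list(n_u = grid$n_u, n_v = grid$n_v,
                            n_fallback = grid$n_fallback,
                            id = grid$id, side = grid$side),
                       sidecar, auto_unbox = TRUE, null = "null")
  invisible(path)
}
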