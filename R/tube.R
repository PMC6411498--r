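#' Closed tube template mesh
#'
#' Builds an elongated, optionally bent tube (rings of vertices along a
#' planar-arc centerline, capped with triangle fans) as a stand-in for a
#' tube-like subcortical surface. The mesh is closed, genus zero, and
#' consistently outward-oriented; the generation parameterization
#' (`u` = ring fraction along the centerline, `v` = angular fraction) is
#' stored for seeding localized effects.
#'
#' @param n_rings number of cross-sectional rings (>= 4).
#' @param n_around vertices per ring (>= 4).
#' @param length centerline length (mm).
#' @param radius_profile constant radius (mm) or function of u in \[0,1\];
#'   the effective radius (cross-section area = pi r^2 regardless of
#'   aspect).
#' @param bend total turning angle of the planar-arc centerline (radians);
#'   0 gives a straight tube.
#' @param cross_aspect major/minor axis ratio of the elliptic cross-section
#'   (area-preserving; 1 gives a circle). The major axis lies in the bend
#'   plane, which anchors the angular gauge of downstream
#'   parameterizations.
#' @param jitter_sd optional isotropic vertex jitter (mm).
#' @param seed RNG seed (only used when `jitter_sd > 0`).
#' @return A closed [hm_mesh()] with attributes `uv` (N x 2 generation
#'   parameters; cap centres get v = NA), `centerline` (n_rings x 3) and
#'   `ring_index`.
#' @export
#' @examples
#' tube <- make_template_tube(20, 12, length = 40, radius_profile = 5)
#' check_topology(tube)$euler  # 2
make_template_tube <- function(n_rings = 50L, n_around = 30L, length = 40,
                               radius_profile = 5, bend = 0.6,
                               cross_aspect = 1.5, jitter_sd = 0, seed = 1L) {
  if (n_rings < 4L || n_around < 4L)
    stop("n_rings and n_around must be >= 4", call. = FALSE)
  if (length <= 0) stop("length must be positive", call. = FALSE)
  rfun <- if (is.function(radius_profile)) radius_profile
          else function(u) rep(radius_profile, length(u))
  u <- seq(0, 1, length.out = n_rings)
  r <- rfun(u)
  if (any(r <= 0)) stop("radii must be positive", call. = FALSE)

  # planar-arc centerline in the xz plane; bend = total turning angle
  if (abs(bend) < 1e-12) {
    C <- cbind(u * length, 0, 0)
    Tg <- matrix(rep(c(1, 0, 0), each = n_rings), ncol = 3)
    Nv <- matrix(rep(c(0, 0, 1), each = n_rings), ncol = 3)
  } else {
    R <- length / bend
    th <- u * bend
    C <- cbind(R * sin(th), 0, R * (1 - cos(th)))
    Tg <- cbind(cos(th), 0, sin(th))
    Nv <- cbind(-sin(th), 0, cos(th))
  }
  B <- cbind(0, 1, 0)

  if (cross_aspect < 1) stop("cross_aspect must be >= 1", call. = FALSE)
  amaj <- sqrt(cross_aspect); bmin <- 1 / sqrt(cross_aspect)
  phi <- 2 * pi * (seq_len(n_around) - 1L) / n_around
  V <- matrix(0, n_rings * n_around + 2L, 3)
  uv <- matrix(NA_real_, nrow(V), 2)
  ring <- integer(nrow(V))
  for (i in seq_len(n_rings)) {
    idx <- (i - 1L) * n_around + seq_len(n_around)
    V[idx, ] <- matrix(C[i, ], n_around, 3, byrow = TRUE) +
      r[i] * (amaj * cos(phi) %o% Nv[i, ] + bmin * sin(phi) %o% c(0, 1, 0))
    uv[idx, 1] <- u[i]
    uv[idx, 2] <- phi / (2 * pi)
    ring[idx] <- i
  }
  c0 <- nrow(V) - 1L; c1 <- nrow(V)
  V[c0, ] <- C[1, ]; V[c1, ] <- C[n_rings, ]
  uv[c0, 1] <- 0; uv[c1, 1] <- 1
  ring[c0] <- 1L; ring[c1] <- n_rings

  vid <- function(i, j) (i - 1L) * n_around + ((j - 1L) %% n_around) + 1L
  side <- vector("list", n_rings - 1L)
  for (i in seq_len(n_rings - 1L)) {
    j <- seq_len(n_around)
    a <- vid(i, j); b <- vid(i, j + 1L)
    cc <- vid(i + 1L, j + 1L); d <- vid(i + 1L, j)
    side[[i]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  j <- seq_len(n_around)
  cap0 <- cbind(c0, vid(1L, j + 1L), vid(1L, j))
  cap1 <- cbind(c1, vid(n_rings, j), vid(n_rings, j + 1L))
  F_ <- rbind(do.call(rbind, side), cap0, cap1)

  if (jitter_sd > 0) {
    set.seed(seed)
    V <- V + matrix(rnorm(prod(dim(V)), sd = jitter_sd), ncol = 3)
  }
  mesh <- hm_mesh(V, F_)
  # enforce outward orientation (positive signed volume)
  sv <- signed_volume(mesh)
  if (sv < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  attr(mesh, "uv") <- uv
  attr(mesh, "centerline") <- C
  attr(mesh, "ring_index") <- ring
  mesh
}

#' Rounded-end tube radius profile
#'
#' Constant mid-tube radius with a smooth superelliptic taper toward both
#' ends, avoiding the sharp cap rim of a constant profile (end-cut
#' placement then changes the boundary-ring radius only gradually).
#'
#' @param r0 mid-tube effective radius (mm).
#' @param end_taper fractional squared-radius reduction at the very ends.
#' @param power evenness/sharpness of the taper (higher keeps the mid-tube
#'   longer at full radius).
#' @return A function of u in \[0,1\] returning radii.
#' @export
tube_radius_profile <- function(r0 = 5, end_taper = 0.5, power = 8) {
  function(u) r0 * sqrt(pmax(1 - end_taper * (2 * u - 1)^power, 0.1))
}

signed_volume <- function(mesh) {
  V <- mesh$vertices
  a <- V[mesh$faces[, 1], , drop = FALSE]
  b <- V[mesh$faces[, 2], , drop = FALSE]
  c_ <- V[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# area-weighted per-vertex outward normals
vertex_normals <- function(mesh) {
  V <- mesh$vertices; F_ <- mesh$faces
  e1 <- V[F_[, 2], ] - V[F_[, 1], ]
  e2 <- V[F_[, 3], ] - V[F_[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  N <- matrix(0, nrow(V), 3)
  for (c in 1:3) for (d in 1:3) {
    acc <- tapply(fn[, d], F_[, c], sum)
    N[as.integer(names(acc)), d] <- N[as.integer(names(acc)), d] + acc
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}
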