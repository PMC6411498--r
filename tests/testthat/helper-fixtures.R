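# Shared geometric fixtures, built in code.

# axis-aligned unit cube (8 vertices, 12 consistently outward faces)
unit_cube_mesh <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  F_ <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  m <- hm_mesh(V, F_)
  if (hippomorph:::signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# icosphere by subdividing an icosahedron and projecting to the sphere
icosphere_mesh <- function(radius = 1, subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  V <- V / sqrt(rowSums(V^2))
  F_ <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- hm_mesh(V, F_)
  for (s in seq_len(subdivisions)) {
    m <- hippomorph:::loop_subdivide(m)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
  }
  m$vertices <- m$vertices * radius
  if (hippomorph:::signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# open cylinder (no caps): n_rings x n_around structured tube
open_cylinder_mesh <- function(n_rings = 20, n_around = 16, radius = 1,
                               height = 2) {
  z <- seq(0, height, length.out = n_rings)
  phi <- 2 * pi * (seq_len(n_around) - 1) / n_around
  V <- cbind(rep(radius * cos(phi), n_rings),
             rep(radius * sin(phi), n_rings),
             rep(z, each = n_around))
  vid <- function(i, j) (i - 1L) * n_around + ((j - 1L) %% n_around) + 1L
  F_ <- NULL
  for (i in seq_len(n_rings - 1)) {
    j <- seq_len(n_around)
    F_ <- rbind(F_, cbind(vid(i, j), vid(i, j + 1), vid(i + 1, j + 1)),
                cbind(vid(i, j), vid(i + 1, j + 1), vid(i + 1, j)))
  }
  hm_mesh(V, F_)
}

# closed torus mesh
torus_mesh <- function(n_major = 24, n_minor = 12, R = 3, r = 1) {
  th <- 2 * pi * (seq_len(n_major) - 1) / n_major
  ph <- 2 * pi * (seq_len(n_minor) - 1) / n_minor
  V <- NULL
  for (i in seq_len(n_major))
    V <- rbind(V, cbind((R + r * cos(ph)) * cos(th[i]),
                        (R + r * cos(ph)) * sin(th[i]),
                        r * sin(ph)))
  vid <- function(i, j)
    ((i - 1L) %% n_major) * n_minor + ((j - 1L) %% n_minor) + 1L
  F_ <- NULL
  for (i in seq_len(n_major)) {
    j <- seq_len(n_minor)
    F_ <- rbind(F_, cbind(vid(i, j), vid(i, j + 1), vid(i + 1, j + 1)),
                cbind(vid(i, j), vid(i + 1, j + 1), vid(i + 1, j)))
  }
  hm_mesh(V, F_)
}

# a small, fast replicate-study cohort spec
small_cohort_spec <- function(...) {
  cohort_spec(group_sizes = c(NC = 4L, HT = 4L, HM = 4L),
              template_args = list(n_rings = 24, n_around = 16), ...)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
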