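# Per-vertex multivariate morphometry statistics: the 2x2 face Jacobian of
# the registration map in the parameter plane, its tensor-based summaries
# (sqrt(det J); the three unique entries of log sqrt(J J^T)), and the radial
# distance of the registered surface.

#' Jacobian of the linear map between two parameter-plane triangles
#'
#' `J = [w3 - w1, w2 - w1] [v3 - v1, v2 - v1]^-1` (columns as listed), the
#' unique linear map sending the source edge vectors to the target edge
#' vectors.
#'
#' @param source_face 3 x 2 matrix of source-triangle parameter coordinates
#'   (rows v1, v2, v3).
#' @param target_face 3 x 2 matrix of target-triangle coordinates (rows
#'   w1, w2, w3).
#' @return 2 x 2 Jacobian matrix.
#' @export
#' @examples
#' face_jacobian(rbind(c(0,0), c(1,0), c(0,1)),
#'               rbind(c(0,0), c(2,0), c(0,1)))  # diag(2, 1)
face_jacobian <- function(source_face, target_face) {
  Vm <- cbind(source_face[3, ] - source_face[1, ],
              source_face[2, ] - source_face[1, ])
  Wm <- cbind(target_face[3, ] - target_face[1, ],
              target_face[2, ] - target_face[1, ])
  if (abs(det(Vm)) < 1e-14 * max(abs(Vm), 1))
    stop("degenerate source triangle", call. = FALSE)
  Wm %*% solve(Vm)
}

#' Scalar tensor-based morphometry value of a face Jacobian
#'
#' `sqrt(det J)`; the raw determinant is attached as attribute `detJ` for
#' the directionality ratio map.
#'
#' @param J 2 x 2 Jacobian with positive determinant.
#' @return `sqrt(det J)` with attribute `detJ`.
#' @export
tbm <- function(J) {
  d <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (d <= 0) stop("flipped face: det J = ", signif(d, 4), call. = FALSE)
  structure(sqrt(d), detJ = d)
}

# symmetric 2x2 matrix log via eigendecomposition
sym_logm2 <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0)) stop("non-positive-definite tensor", call. = FALSE)
  e$vectors %*% diag(log(e$values)) %*% t(e$vectors)
}

#' Multivariate TBM components of a face Jacobian
#'
#' The deformation tensor `S = (J J^T)^(1/2)` is formed by eigendecomposition
#' and the unique entries of `log S` are returned in the fixed order
#' `(m11, m12, m22)` (the Log-Euclidean representation; rotations map to
#' zero).
#'
#' @param J 2 x 2 Jacobian with positive determinant.
#' @return numeric length-3 vector `(m11, m12, m22)`.
#' @export
mtbm <- function(J) {
  d <- det(J)
  if (d <= 0) stop("flipped face: det J = ", signif(d, 4), call. = FALSE)
  Lg <- 0.5 * sym_logm2(J %*% t(J))  # log sqrt(JJ^T) = 1/2 log(JJ^T)
  out <- c(Lg[1, 1], Lg[1, 2], Lg[2, 2])
  if (any(!is.finite(out))) stop("non-finite mTBM components", call. = FALSE)
  out
}

# grid-cell triangulation of the parameter grid (two triangles per cell,
# periodic in v).  Returns faces as n_face x 3 node indices (column-major
# node ids: node(i,j) = i + (j-1) n_u) and the per-face parameter coords.
grid_faces <- function(n_u, n_v) {
  i <- rep(seq_len(n_u - 1L), times = n_v)
  j <- rep(seq_len(n_v), each = n_u - 1L)
  jn <- j %% n_v + 1L
  a <- i + (j - 1L) * n_u
  b <- i + 1L + (j - 1L) * n_u
  cc <- i + 1L + (jn - 1L) * n_u
  d <- i + (jn - 1L) * n_u
  rbind(cbind(a, b, cc), cbind(a, cc, d))
}

# parameter coordinates of grid nodes, with the v wrap unrolled per face so
# every triangle has contiguous coordinates
grid_param_coords <- function(n_u, n_v) {
  du <- 1 / (n_u - 1)
  dv <- 1 / n_v
  i <- ((seq_len(n_u * n_v) - 1L) %% n_u) + 1L
  j <- ((seq_len(n_u * n_v) - 1L) %/% n_u) + 1L
  cbind((i - 1) * du, (j - 1) * dv)
}

#' Per-vertex multivariate morphometry statistics of a registered subject
#'
#' For each grid face the 2 x 2 Jacobian of the registration map is
#' computed as the linear map between corresponding embedded triangles:
#' the template face and its image on the subject surface (positions
#' sampled at the registered parameter coordinates), each expressed in its
#' own in-plane orthonormal frame anchored to the first edge. `det J`
#' therefore measures the true areal change of the surface map (atrophy
#' gives `det J < 1`) and `log sqrt(J J^T)` its Log-Euclidean deformation
#' tensor. Face tensors `J J^T` and determinants are aggregated to vertices
#' by area-weighted averaging (tensors before the matrix logarithm,
#' preserving positive-definiteness). Column 4 is the radial distance of
#' the registered subject surface sampled at template correspondence.
#'
#' @param subject `hm_grid_surface` of the subject.
#' @param template `hm_grid_surface` of the template (same shape).
#' @param field `hm_deformation` from [fluid_register()] `(subject, template)`.
#' @return An `hm_mms`: `features` (W x 4 matrix, columns m11, m12, m22,
#'   radial distance), `detj` (W vector), `radial` and grid shape, W =
#'   n_u * n_v with column-major node order.
#' @export
compute_mms <- function(subject, template, field) {
  n_u <- template$n_u; n_v <- template$n_v
  stopifnot(subject$n_u == n_u, subject$n_v == n_v,
            field$n_u == n_u, field$n_v == n_v)
  W <- n_u * n_v
  du <- 1 / (n_u - 1); dv <- 1 / n_v

  # target coordinates: template node + pullback displacement (cells -> uv)
  pu <- grid_param_coords(n_u, n_v)
  tu <- pu[, 1] + as.vector(field$pullback$du) * du
  tv <- pu[, 2] + as.vector(field$pullback$dv) * dv

  F_ <- grid_faces(n_u, n_v)

  # registered subject surface: subject positions at the pullback parameter
  # coordinates of every template node
  ru <- matrix(1 + tu / du, n_u, n_v)
  cv <- matrix(1 + tv / dv, n_u, n_v)
  spos <- matrix(0, W, 3)
  for (d in 1:3)
    spos[, d] <- as.vector(sample_bilinear(subject$pos[, , d], ru, cv))
  tpos <- matrix(template$pos, W, 3)

  # in-plane 2D coordinates of each embedded triangle, frame anchored to
  # the first edge: p1 -> (0,0), p2 -> (|e1|, 0), p3 -> (e2.x, e2.y)
  flatten <- function(P) {
    e1 <- P[F_[, 2], ] - P[F_[, 1], ]
    e2 <- P[F_[, 3], ] - P[F_[, 1], ]
    l1 <- sqrt(rowSums(e1^2))
    x2 <- rowSums(e2 * e1) / l1
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    y2 <- sqrt(rowSums(cr^2)) / l1
    list(p2x = l1, p3x = x2, p3y = y2)
  }
  src <- flatten(tpos)
  tgt <- flatten(spos)
  if (any(src$p3y <= 1e-12) || any(tgt$p3y <= 1e-12))
    stop("degenerate face in the registered correspondence", call. = FALSE)

  # J = [w3-w1, w2-w1] [v3-v1, v2-v1]^-1 with v1 = w1 = origin
  detV <- -src$p2x * src$p3y          # det of [v3, v2] columns
  iv11 <- 0 / detV
  iv12 <- -src$p2x / detV
  iv21 <- -src$p3y / detV
  iv22 <- src$p3x / detV
  J11 <- tgt$p3x * iv11 + tgt$p2x * iv21
  J12 <- tgt$p3x * iv12 + tgt$p2x * iv22
  J21 <- tgt$p3y * iv11
  J22 <- tgt$p3y * iv12
  detJ <- J11 * J22 - J12 * J21
  if (any(detJ <= 0))
    stop("diffeomorphism violated: ", sum(detJ <= 0),
         " flipped registration faces", call. = FALSE)

  # face tensors JJ^T, rotated into the frame aligned with the image of the
  # parameter-u direction so per-vertex aggregation is frame-consistent
  # (m11 ~ axial, m22 ~ circumferential)
  T11r <- J11^2 + J12^2
  T12r <- J11 * J21 + J12 * J22
  T22r <- J21^2 + J22^2
  unroll_v <- function(vals) {
    m <- cbind(vals[F_[, 1]], vals[F_[, 2]], vals[F_[, 3]])
    m[, 2] <- m[, 2] + round(m[, 1] - m[, 2])
    m[, 3] <- m[, 3] + round(m[, 1] - m[, 3])
    m
  }
  pum <- cbind(pu[F_[, 1], 1], pu[F_[, 2], 1], pu[F_[, 3], 1])
  pvm <- unroll_v(pu[, 2])
  pp21x <- (pum[, 2] - pum[, 1]) / du; pp21y <- (pvm[, 2] - pvm[, 1]) / dv
  pp31x <- (pum[, 3] - pum[, 1]) / du; pp31y <- (pvm[, 3] - pvm[, 1]) / dv
  detP <- pp21x * pp31y - pp31x * pp21y
  # target-frame angle of the parameter-u image: columns of
  # A = [w2, w3][p2, p3]^-1 applied to (1, 0)
  A11 <- (tgt$p2x * pp31y - tgt$p3x * pp21y) / detP
  A21 <- (0 * pp31y - tgt$p3y * pp21y) / detP
  th <- atan2(A21, A11)
  cth <- cos(th); sth <- sin(th)
  # T' = R(-th) T R(th)
  T11 <- cth^2 * T11r + 2 * cth * sth * T12r + sth^2 * T22r
  T22 <- sth^2 * T11r - 2 * cth * sth * T12r + cth^2 * T22r
  T12 <- cth * sth * (T22r - T11r) + (cth^2 - sth^2) * T12r
  area <- abs(detV) / 2

  # area-weighted aggregation of tensors and determinants to vertices
  acc <- function(x) {
    out <- numeric(W)
    for (c_ in 1:3) {
      s <- rowsum(x * area, F_[, c_])
      out[as.integer(rownames(s))] <- out[as.integer(rownames(s))] + s
    }
    out
  }
  wsum <- acc(rep(1, nrow(F_)))
  vT11 <- acc(T11) / wsum; vT12 <- acc(T12) / wsum; vT22 <- acc(T22) / wsum
  vdet <- acc(detJ) / wsum

  # closed-form log of the 2x2 SPD vertex tensors
  tr <- vT11 + vT22
  dt <- vT11 * vT22 - vT12^2
  disc <- pmax(tr^2 / 4 - dt, 0)
  l1 <- tr / 2 + sqrt(disc); l2 <- tr / 2 - sqrt(disc)
  if (any(l2 <= 0)) stop("non-SPD vertex tensor", call. = FALSE)
  m11 <- numeric(W); m12 <- numeric(W); m22 <- numeric(W)
  iso <- disc < 1e-24
  m11[iso] <- 0.5 * log(l1[iso]); m22[iso] <- m11[iso]
  ni <- !iso
  # eigenvector for l1: (vT12, l1 - vT11) unless vT12 ~ 0
  ex <- vT12[ni]; ey <- l1[ni] - vT11[ni]
  deg <- abs(ex) < 1e-30 & abs(ey) < 1e-30
  ex[deg] <- 1; ey[deg] <- 0
  nrm <- sqrt(ex^2 + ey^2)
  ex <- ex / nrm; ey <- ey / nrm
  a1 <- 0.5 * log(l1[ni]); a2 <- 0.5 * log(l2[ni])
  m11[ni] <- a1 * ex^2 + a2 * ey^2
  m22[ni] <- a1 * ey^2 + a2 * ex^2
  m12[ni] <- (a1 - a2) * ex * ey

  # radial distance of the registered subject surface at template nodes
  reg_grid <- structure(list(pos = array(spos, c(n_u, n_v, 3)),
                             n_u = n_u, n_v = n_v),
                        class = "hm_grid_surface")
  rad <- as.vector(radial_distances(reg_grid))
  if (any(rad <= 0)) stop("non-positive radial distance", call. = FALSE)

  feats <- cbind(m11 = m11, m12 = m12, m22 = m22, radial = rad)
  structure(list(features = feats, detj = vdet, radial = rad,
                 n_u = n_u, n_v = n_v, id = subject$id, side = subject$side),
            class = "hm_mms")
}

#' @export
print.hm_mms <- function(x, ...) {
  cat(sprintf("<hm_mms> W = %d vertices x 4 features\n", nrow(x$features)))
  invisible(x)
}

#' Serialize an MMS feature matrix (flat binary + JSON header)
#'
#' @param mms an `hm_mms`.
#' @param path output `.bin` path; a `.json` header is written next to it.
#' @return `path`, invisibly.
#' @export
write_mms <- function(mms, path) {
  con <- file(path, "wb")
  writeBin(as.vector(mms$features), con, size = 8, endian = "little")
  writeBin(as.vector(mms$detj), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(W = nrow(mms$features), columns = colnames(mms$features),
         n_u = mms$n_u, n_v = mms$n_v, id = mms$id, side = mms$side,
         layout = "features column-major, then detj"),
    sub("\\.bin$", ".json", path), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read an MMS feature matrix written by [write_mms()]
#' @param path `.bin` path.
#' @return An `hm_mms`.
#' @export
read_mms <- function(path) {
  hdr <- jsonlite::read_json(sub("\\.bin$", ".json", path))
  W <- hdr$W
  con <- file(path, "rb")
  feats <- matrix(readBin(con, "double", W * 4L, size = 8, endian = "little"),
                  ncol = 4, dimnames = list(NULL, unlist(hdr$columns)))
  detj <- readBin(con, "double", W, size = 8, endian = "little")
  close(con)
  structure(list(features = feats, detj = detj, radial = feats[, 4],
                 n_u = hdr$n_u, n_v = hdr$n_v, id = hdr$id, side = hdr$side),
            class = "hm_mms")
}
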