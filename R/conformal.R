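# Conformal tube parameterization by a harmonic 1-form: u is the harmonic
# function with Dirichlet data 0/1 on the two cut loops; v is its conjugate,
# obtained by least-squares integration of the Hodge-rotated gradient of u on
# the mesh cut open along a u-ascending path, normalized to period 1.

cotan_weights <- function(V, F_, floor_w = 1e-6) {
  cot3 <- function(a, b, c) {
    # cotangent at vertex a of triangle (a,b,c)
    u <- V[b, ] - V[a, ]; w <- V[c, ] - V[a, ]
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    rowSums(u * w) / pmax(sqrt(rowSums(cr^2)), 1e-300)
  }
  i <- F_[, 1]; j <- F_[, 2]; k <- F_[, 3]
  # edge (j,k) opposite i, etc.
  ii <- c(j, k, i); jj <- c(k, i, j)
  ww <- 0.5 * c(cot3(i, j, k), cot3(j, k, i), cot3(k, i, j))
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  agg <- rowsum(ww, paste(a, b))
  key <- rownames(agg)
  e <- matrix(as.integer(unlist(strsplit(key, " "))), ncol = 2, byrow = TRUE)
  list(edges = e, w = pmax(agg[, 1], floor_w))
}

cotan_laplacian <- function(V, F_, floor_w = 1e-6) {
  cw <- cotan_weights(V, F_, floor_w)
  e <- cw$edges; w <- cw$w
  nv <- nrow(V)
  L <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = c(-w, -w), dims = c(nv, nv))
  Matrix::Diagonal(nv, -Matrix::rowSums(L)) + L
}

solve_dirichlet <- function(L, fixed_idx, fixed_val) {
  nv <- nrow(L)
  free <- setdiff(seq_len(nv), fixed_idx)
  u <- numeric(nv)
  u[fixed_idx] <- fixed_val
  rhs <- -L[free, fixed_idx, drop = FALSE] %*% fixed_val
  sol <- tryCatch(Matrix::solve(L[free, free], rhs),
                  error = function(e) stop(
                    "harmonic system not solvable: ", conditionMessage(e),
                    call. = FALSE))
  u[free] <- as.vector(sol)
  u
}

face_geometry <- function(V, F_) {
  p1 <- V[F_[, 1], , drop = FALSE]
  p2 <- V[F_[, 2], , drop = FALSE]
  p3 <- V[F_[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(n^2))
  list(area = a2 / 2, normal = n / pmax(a2, 1e-300))
}

# per-face gradient basis: grad phi_c = (n x opposite_edge) / (2A)
grad_basis <- function(V, F_, geom) {
  p <- lapply(1:3, function(c) V[F_[, c], , drop = FALSE])
  opp <- list(p[[3]] - p[[2]], p[[1]] - p[[3]], p[[2]] - p[[1]])
  lapply(opp, function(e) {
    n <- geom$normal
    cr <- cbind(n[, 2] * e[, 3] - n[, 3] * e[, 2],
                n[, 3] * e[, 1] - n[, 1] * e[, 3],
                n[, 1] * e[, 2] - n[, 2] * e[, 1])
    cr / (2 * geom$area)
  })
}

# mean curvature (signed by outward normal) from the cotan Laplacian of the
# coordinates; boundary vertices inherit their interior-neighbour mean
mean_curvature <- function(V, F_) {
  L <- cotan_laplacian(V, F_, floor_w = 0)  # raw cotan for curvature
  geom <- face_geometry(V, F_)
  varea <- numeric(nrow(V))
  for (c in 1:3) {
    acc <- rowsum(geom$area / 3, F_[, c])
    varea[as.integer(rownames(acc))] <- varea[as.integer(rownames(acc))] + acc
  }
  Hn <- as.matrix(L %*% V) / (2 * pmax(varea, 1e-300))
  nrm <- vertex_normals(hm_mesh(V, F_, validate = FALSE))
  H <- -rowSums(Hn * nrm) / 2
  bl <- boundary_loops(F_)
  bverts <- unlist(bl)
  if (length(bverts)) {
    e <- mesh_edges(F_)
    interior <- setdiff(seq_len(nrow(V)), bverts)
    adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
    for (b in bverts) {
      nb <- setdiff(adj[[as.character(b)]], bverts)
      if (length(nb)) H[b] <- mean(H[nb])
    }
  }
  H
}

# cut the annulus open along a simple vertex path from loop0 to loop1.
# Returns new vertices/faces and the duplicate map.
cut_mesh_along_path <- function(V, F_, path) {
  dkey <- function(a, b) paste(a, b)
  fmap <- new.env(hash = TRUE, parent = emptyenv())
  for (f in seq_len(nrow(F_))) {
    assign(dkey(F_[f, 1], F_[f, 2]), f, envir = fmap)
    assign(dkey(F_[f, 2], F_[f, 3]), f, envir = fmap)
    assign(dkey(F_[f, 3], F_[f, 1]), f, envir = fmap)
  }
  getf <- function(a, b) {
    k <- dkey(a, b)
    if (exists(k, envir = fmap, inherits = FALSE)) get(k, envir = fmap) else NA_integer_
  }
  order_at <- function(f, v) {
    tr <- F_[f, ]
    i <- which(tr == v)
    tr[c(i, i %% 3 + 1, (i + 1) %% 3 + 1)]  # (v, next, prev)
  }
  m <- length(path)
  wedges <- vector("list", m)
  for (t in seq_len(m)) {
    v <- path[t]
    if (t < m) {
      f <- getf(v, path[t + 1])
      if (is.na(f)) stop("path edge has no left face", call. = FALSE)
      wedge <- integer(0)
      repeat {
        wedge <- c(wedge, f)
        ord <- order_at(f, v)
        y <- ord[3]
        if (t > 1 && y == path[t - 1]) break
        fn <- getf(v, y)
        if (is.na(fn)) break  # hit boundary (t == 1 case)
        f <- fn
        if (length(wedge) > nrow(F_)) stop("wedge walk failed", call. = FALSE)
      }
    } else {
      f <- getf(path[t - 1], v)
      if (is.na(f)) stop("path edge has no left face at end", call. = FALSE)
      wedge <- integer(0)
      repeat {
        wedge <- c(wedge, f)
        ord <- order_at(f, v)
        x <- ord[2]
        fn <- getf(x, v)
        if (is.na(fn)) break  # boundary reached
        f <- fn
        if (length(wedge) > nrow(F_)) stop("wedge walk failed", call. = FALSE)
      }
    }
    wedges[[t]] <- wedge
  }
  nv <- nrow(V)
  dup <- nv + seq_len(m)
  V2 <- rbind(V, V[path, , drop = FALSE])
  F2 <- F_
  for (t in seq_len(m)) {
    for (f in wedges[[t]]) {
      idx <- which(F2[f, ] == path[t])
      F2[f, idx] <- dup[t]
    }
  }
  list(vertices = V2, faces = F2, path = path, dup = dup,
       orig_of = c(seq_len(nv), path))
}

#' Conformal tube parameterization of a two-cut surface
#'
#' Computes `u` as the discrete harmonic function (cotangent Laplacian,
#' weights clamped at a small positive floor) with Dirichlet values 0 on the
#' posterior cut and 1 on the anterior cut, and `v` as its conjugate: the
#' rotated (in-plane 90 degree) gradient of `u` is integrated in least
#' squares over the mesh cut open along a u-ascending path from the gauge
#' anchor, then normalized to period 1. The gauge fixes v = 0 at the
#' posterior-loop vertex farthest from the principal axis.
#'
#' @param open_mesh an `hm_open_mesh` from [compute_cuts()].
#' @param floor_w clamping floor for cotangent edge weights.
#' @param max_flip_fraction tolerated fraction of orientation-flipped
#'   parameter triangles before a quality error is raised.
#' @return An `hm_param_surface`: the cut-open mesh (`vertices`, `faces`,
#'   parameter columns `u`, `v`), `orig_of` index map into the open mesh,
#'   per-vertex `log_lambda` (log conformal area factor) and `mean_curv`,
#'   and the flip count.
#' @export
conformal_parameterize <- function(open_mesh, floor_w = 1e-6,
                                   max_flip_fraction = 0.002) {
  V <- open_mesh$vertices
  F_ <- open_mesh$faces
  L <- cotan_laplacian(V, F_, floor_w)
  fixed <- c(open_mesh$loop_posterior, open_mesh$loop_anterior)
  fval <- c(rep(0, length(open_mesh$loop_posterior)),
            rep(1, length(open_mesh$loop_anterior)))
  u <- solve_dirichlet(L, fixed, fval)

  # gauge anchor on the posterior loop.  For bent tubes the bend plane gives
  # a noise-robust direction: the mesh centroid is offset from the chord
  # joining the two cut-loop centroids, toward the outer side of the bend.
  # Straight tubes (no measurable offset) fall back to the vertex farthest
  # from the principal axis.
  post <- V[open_mesh$loop_posterior, , drop = FALSE]
  p0 <- colMeans(post)
  p1 <- colMeans(V[open_mesh$loop_anterior, , drop = FALSE])
  chord <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  # bend direction from the centerline: slab centroids along the chord; the
  # largest perpendicular offset (the sagitta) is a robust global moment
  tproj <- as.vector(sweep(V, 2, p0) %*% chord)
  nslab <- 9L
  slab <- pmin(pmax(findInterval(tproj, seq(min(tproj), max(tproj),
                                            length.out = nslab + 1L),
                                 all.inside = TRUE), 1L), nslab)
  offs <- vapply(seq_len(nslab), function(s) {
    if (!any(slab == s)) return(c(0, 0, 0))
    sc <- colMeans(V[slab == s, , drop = FALSE]) - p0
    sc - sum(sc * chord) * chord
  }, numeric(3))
  # middle-third slabs carry the sagitta; end slabs are polluted by the
  # cap-removal asymmetry
  mid <- seq.int(ceiling(nslab / 3) + 1L, nslab - ceiling(nslab / 3))
  perp <- rowMeans(offs[, mid, drop = FALSE])
  ring_r <- sqrt(mean(rowSums(sweep(post, 2, p0)^2)))
  if (sqrt(sum(perp^2)) > 0.05 * ring_r) {
    perp <- perp / sqrt(sum(perp^2))
    anchor <- open_mesh$loop_posterior[
      which.max(sweep(post, 2, p0) %*% perp)]
  } else {
    ax <- open_mesh$axis
    rel <- sweep(post, 2, colMeans(V))
    par_ <- rel %*% ax
    perp2 <- rowSums(rel^2) - par_^2
    anchor <- open_mesh$loop_posterior[which.max(perp2)]
  }

  # u-ascending path from anchor to the anterior loop
  e <- mesh_edges(F_)
  adj <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  path <- anchor
  cur <- anchor
  ant <- rep(FALSE, nrow(V)); ant[open_mesh$loop_anterior] <- TRUE
  for (step in seq_len(nrow(V))) {
    if (ant[cur]) break
    nb <- adj[[as.character(cur)]]
    nb <- nb[!(nb %in% path)]
    if (length(nb) == 0L) stop("cut path walk stalled", call. = FALSE)
    cur <- nb[which.max(u[nb])]
    path <- c(path, cur)
  }
  if (!ant[cur]) stop("cut path did not reach the anterior loop", call. = FALSE)

  cm <- cut_mesh_along_path(V, F_, path)
  Vc <- cm$vertices; Fc <- cm$faces
  uc <- u[cm$orig_of]

  # rotated gradient of u per face (computed on cut mesh; same geometry)
  geom <- face_geometry(Vc, Fc)
  gb <- grad_basis(Vc, Fc, geom)
  gradu <- gb[[1]] * uc[Fc[, 1]] + gb[[2]] * uc[Fc[, 2]] + gb[[3]] * uc[Fc[, 3]]
  n <- geom$normal
  g <- cbind(n[, 2] * gradu[, 3] - n[, 3] * gradu[, 2],
             n[, 3] * gradu[, 1] - n[, 1] * gradu[, 3],
             n[, 1] * gradu[, 2] - n[, 2] * gradu[, 1])

  # least-squares integration: L_cut v = div(g)
  nvc <- nrow(Vc)
  iL <- integer(0); jL <- integer(0); xL <- numeric(0)
  b <- numeric(nvc)
  for (cA in 1:3) {
    b_acc <- rowsum(geom$area * rowSums(gb[[cA]] * g), Fc[, cA])
    b[as.integer(rownames(b_acc))] <- b[as.integer(rownames(b_acc))] + b_acc
    for (cB in 1:3) {
      iL <- c(iL, Fc[, cA]); jL <- c(jL, Fc[, cB])
      xL <- c(xL, geom$area * rowSums(gb[[cA]] * gb[[cB]]))
    }
  }
  Lc <- Matrix::sparseMatrix(i = iL, j = jL, x = xL, dims = c(nvc, nvc))
  free <- setdiff(seq_len(nvc), anchor)
  v <- numeric(nvc)
  sol <- tryCatch(Matrix::solve(Lc[free, free], b[free]),
                  error = function(e) stop(
                    "conjugate integration system not solvable: ",
                    conditionMessage(e), call. = FALSE))
  v[free] <- as.vector(sol)

  period <- median(v[cm$dup] - v[path])
  if (abs(period) < 1e-12)
    stop("degenerate conjugate period", call. = FALSE)
  # second pass: enforce an exactly constant jump across the cut so the
  # parameter domain closes to a true period (v_dup = v_orig + period)
  nv0 <- nrow(V)
  Pm <- Matrix::sparseMatrix(i = seq_len(nvc),
                             j = c(seq_len(nv0), path),
                             x = 1, dims = c(nvc, nv0))
  cvec <- numeric(nvc)
  cvec[cm$dup] <- period
  Lred <- Matrix::t(Pm) %*% Lc %*% Pm
  bred <- as.vector(Matrix::t(Pm) %*% (b - Lc %*% cvec))
  freer <- setdiff(seq_len(nv0), anchor)
  vred <- numeric(nv0)
  vred[freer] <- as.vector(Matrix::solve(Lred[freer, freer], bred[freer]))
  v <- as.vector(Pm %*% vred + cvec)
  v <- (v - v[anchor]) / period

  # orientation bookkeeping: parameter triangles must be consistently
  # oriented; flips counted on signed parameter area
  pa <- 0.5 * ((uc[Fc[, 2]] - uc[Fc[, 1]]) * (v[Fc[, 3]] - v[Fc[, 1]]) -
               (uc[Fc[, 3]] - uc[Fc[, 1]]) * (v[Fc[, 2]] - v[Fc[, 1]]))
  if (sum(pa > 0) < sum(pa < 0)) {  # majority negative: flip v globally
    v <- -v
    pa <- -pa
  }
  flips <- sum(pa <= 0)
  if (flips > max_flip_fraction * nrow(Fc))
    stop("parameterization quality: ", flips,
         " flipped parameter triangles", call. = FALSE)

  # conformal area factor: per-vertex 3D area over parameter area
  area3 <- numeric(nvc); areap <- numeric(nvc)
  for (c_ in 1:3) {
    a3 <- rowsum(geom$area / 3, Fc[, c_])
    ap <- rowsum(abs(pa) / 3, Fc[, c_])
    area3[as.integer(rownames(a3))] <- area3[as.integer(rownames(a3))] + a3
    areap[as.integer(rownames(ap))] <- areap[as.integer(rownames(ap))] + ap
  }
  log_lambda <- log(pmax(area3, 1e-300)) - log(pmax(areap, 1e-300))

  H <- mean_curvature(V, F_)[cm$orig_of]

  structure(list(vertices = Vc, faces = Fc, u = uc, v = v,
                 orig_of = cm$orig_of, anchor = anchor, path = path,
                 log_lambda = log_lambda, mean_curv = H,
                 n_flips = flips, period = period,
                 id = open_mesh$id, side = open_mesh$side),
            class = "hm_param_surface")
}

#' @export
print.hm_param_surface <- function(x, ...) {
  cat(sprintf("<hm_param_surface> %d vertices (%d duplicated along cut), %d faces, %d flips\n",
              nrow(x$vertices), length(x$path), nrow(x$faces), x$n_flips))
  invisible(x)
}

#' Quasi-conformal dilatation of a parameterized surface
#'
#' Per-face ratio of the singular values of the linear map from the
#' parameter triangle to the 3D triangle (1 = perfectly conformal).
#'
#' @param ps an `hm_param_surface`.
#' @return numeric vector of per-face dilatations.
#' @export
qc_dilatation <- function(ps) {
  F_ <- ps$faces
  p1 <- ps$vertices[F_[, 1], ]; p2 <- ps$vertices[F_[, 2], ]
  p3 <- ps$vertices[F_[, 3], ]
  q1 <- cbind(ps$u[F_[, 1]], ps$v[F_[, 1]])
  q2 <- cbind(ps$u[F_[, 2]], ps$v[F_[, 2]])
  q3 <- cbind(ps$u[F_[, 3]], ps$v[F_[, 3]])
  out <- numeric(nrow(F_))
  for (f in seq_len(nrow(F_))) {
    A <- cbind(q2[f, ] - q1[f, ], q3[f, ] - q1[f, ])  # 2x2 param edges
    B <- cbind(p2[f, ] - p1[f, ], p3[f, ] - p1[f, ])  # 3x2 world edges
    Jm <- B %*% solve(A)
    sv <- svd(Jm, nu = 0, nv = 0)$d
    out[f] <- sv[1] / max(sv[2], 1e-300)
  }
  out
}
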