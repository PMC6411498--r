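#' Triangle mesh constructor
#'
#' A `hm_mesh` is a list with an N x 3 vertex matrix (world mm) and an M x 3
#' face index matrix (1-based, consistent outward orientation for closed
#' meshes), plus optional `id` and `side` tags.
#'
#' @param vertices N x 3 numeric matrix.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param id optional subject identifier.
#' @param side optional side tag ("left"/"right").
#' @param validate check basic structural invariants (indices in range,
#'   no degenerate zero-area faces).
#' @return An object of class `hm_mesh`.
#' @export
hm_mesh <- function(vertices, faces, id = NULL, side = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be N x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be M x 3", call. = FALSE)
  if (validate && nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate faces (repeated vertex)", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces, id = id, side = side),
            class = "hm_mesh")
}

#' @export
print.hm_mesh <- function(x, ...) {
  cat(sprintf("<hm_mesh> %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (!is.null(x$id)) cat(sprintf(" [%s%s]", x$id,
                                  if (is.null(x$side)) "" else paste0(":", x$side)))
  cat("\n")
  invisible(x)
}

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Topology report for a triangle mesh
#'
#' Reports vertex/edge/face counts, Euler characteristic, boundary loop
#' count, closedness, and edge-manifoldness. A closed genus-zero mesh has
#' Euler characteristic 2 and no boundary loops.
#'
#' @param mesh a [hm_mesh()].
#' @return A list with fields `V`, `E`, `F`, `euler`, `n_boundary_loops`,
#'   `closed`, `edge_manifold`, `genus` (NA when open or non-manifold).
#' @export
check_topology <- function(mesh) {
  faces <- mesh$faces
  nv <- length(unique(as.vector(faces)))
  e <- mesh_edges(faces)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  ne <- length(cnt)
  nf <- nrow(faces)
  boundary_edges <- names(cnt)[cnt == 1L]
  manifold <- all(cnt <= 2L)
  chi <- nv - ne + nf
  loops <- 0L
  if (length(boundary_edges) > 0L) {
    be <- do.call(rbind, strsplit(boundary_edges, " "))
    be <- matrix(as.integer(be), ncol = 2)
    # walk boundary edges into loops
    adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
    seen <- character(0)
    verts <- unique(as.vector(be))
    visited <- setNames(rep(FALSE, length(verts)), verts)
    for (v0 in verts) {
      if (visited[as.character(v0)]) next
      loops <- loops + 1L
      stack <- v0
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        cv <- as.character(v)
        if (visited[cv]) next
        visited[cv] <- TRUE
        nb <- adj[[cv]]
        stack <- c(stack, nb[!visited[as.character(nb)]])
      }
    }
    seen <- NULL
  }
  closed <- length(boundary_edges) == 0L && manifold
  genus <- if (closed) as.integer((2L - chi) / 2L) else NA_integer_
  list(V = nv, E = ne, F = nf, euler = chi, n_boundary_loops = loops,
       closed = closed, edge_manifold = manifold, genus = genus)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed-tetrahedron summation over faces; the absolute value is returned so
#' the result is independent of global orientation. An optional affine is
#' applied to the vertices first (e.g. a stored voxel-to-MNI transform).
#'
#' @param mesh a closed [hm_mesh()].
#' @param affine optional 4 x 4 transform applied to vertices before
#'   integration.
#' @return Enclosed volume in mm^3 (or the affine target units).
#' @export
mesh_volume <- function(mesh, affine = NULL) {
  top <- check_topology(mesh)
  if (!top$closed)
    stop("mesh_volume requires a closed mesh (", top$n_boundary_loops,
         " boundary loops found)", call. = FALSE)
  V <- mesh$vertices
  if (!is.null(affine)) V <- apply_affine(V, affine)
  a <- V[mesh$faces[, 1], , drop = FALSE]
  b <- V[mesh$faces[, 2], , drop = FALSE]
  c_ <- V[mesh$faces[, 3], , drop = FALSE]
  svol <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
              a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
              a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  v <- abs(svol)
  stopifnot(v >= 0)
  v
}

apply_affine <- function(V, affine) {
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  sweep(V %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

#' Binary volume container
#'
#' Wraps a 3D logical occupancy array with its voxel-to-world affine; voxel
#' values are treated as cell-centred samples and world coordinates use
#' 0-based voxel indices through the affine (NIfTI convention).
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param affine 4 x 4 voxel-to-world transform (mm); default a scaled
#'   identity from `spacing`.
#' @param spacing voxel spacing in mm (length 3), used when `affine` missing.
#' @return An object of class `hm_volume`.
#' @export
hm_volume <- function(data, affine = NULL, spacing = c(1, 1, 1)) {
  data <- array(as.logical(data), dim = dim(data))
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
  }
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible", call. = FALSE)
  structure(list(data = data, affine = affine,
                 spacing = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "hm_volume")
}

#' @export
print.hm_volume <- function(x, ...) {
  cat(sprintf("<hm_volume> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

# 3x3x3 (26-neighbourhood) binary dilation/erosion via shifted copies
morph3d <- function(a, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(a)
  out <- if (op == "dilate") array(FALSE, d) else array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    sh <- array(FALSE, d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    sh[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
    out <- if (op == "dilate") out | sh else out & sh
  }
  out
}

binary_closing <- function(a) {
  # pad so dilation cannot touch the array border before eroding back
  d <- dim(a)
  p <- array(FALSE, d + 4L)
  p[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- a
  p <- morph3d(morph3d(p, "dilate"), "erode")
  p[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)]
}

#' Reconstruct a closed surface from a binary mask
#'
#' Morphological closing, largest 26-connected component selection (small
#' outlier clusters below `min_component` voxels are dropped), then
#' isosurface extraction at the 0.5 level of the binary grid by marching
#' tetrahedra. The output is checked to be closed and genus zero and is
#' returned in world coordinates via the volume affine.
#'
#' @param volume a [hm_volume()].
#' @param min_component drop foreground components smaller than this voxel
#'   count before meshing (outlier-cluster removal).
#' @param closing apply one binary closing pass before meshing.
#' @param supersample nearest-neighbour refinement factor of the binary
#'   grid before isosurfacing; 2 keeps the mesh close to the voxel
#'   boundary so enclosed volumes track voxel-count volumes.
#' @return A closed genus-zero [hm_mesh()].
#' @export
reconstruct_surface <- function(volume, min_component = 10L, closing = TRUE,
                                supersample = 2L) {
  stopifnot(inherits(volume, "hm_volume"), supersample >= 1L)
  a <- volume$data
  if (!any(a)) stop("empty mask: no foreground voxels", call. = FALSE)
  if (closing) a <- binary_closing(a)
  lab <- cpp_label_components(a, dim(a))
  if (max(lab) > 1L) {
    keep <- lab == 1L
    dropped <- sum(a) - sum(keep)
    if (dropped >= min_component && sum(lab == 2L) >= min_component)
      stop("mask has multiple large 26-connected components", call. = FALSE)
    a <- keep
  }
  s <- as.integer(supersample)
  b <- if (s > 1L) {
    d <- dim(a)
    a[rep(seq_len(d[1]), each = s), rep(seq_len(d[2]), each = s),
      rep(seq_len(d[3]), each = s)]
  } else a
  iso <- cpp_isosurface(array(as.double(b), dim(b)), dim(b), 0.5)
  # supersampled index i maps back to voxel index (i - (s-1)/2) / s
  verts <- sweep(iso$vertices, 2, (s - 1) / 2) / s
  mesh <- hm_mesh(apply_affine(verts, volume$affine), iso$faces)
  top <- check_topology(mesh)
  if (!top$closed)
    stop("isosurface is not closed (", top$n_boundary_loops, " loops)",
         call. = FALSE)
  if (top$euler != 2L)
    stop("residual topology after closing: Euler characteristic ", top$euler,
         " (expected 2)", call. = FALSE)
  mesh
}

#' Voxelize the interior of a closed mesh
#'
#' Scanline rasterization (ray-parity along the z axis of the voxel grid).
#' The grid extends one voxel beyond the mesh bounding box; the affine of the
#' result maps voxel indices (0-based) to world mm.
#'
#' @param mesh a closed [hm_mesh()].
#' @param voxel_size isotropic voxel edge length (mm).
#' @param affine optional 4 x 4 world transform applied to the mesh before
#'   voxelization.
#' @return A [hm_volume()].
#' @export
rasterize_mesh <- function(mesh, voxel_size = 1, affine = NULL) {
  stopifnot(voxel_size > 0)
  if (nrow(mesh$faces) == 0L) stop("empty mesh", call. = FALSE)
  top <- check_topology(mesh)
  if (!top$closed)
    stop("rasterize_mesh requires a closed mesh", call. = FALSE)
  V <- mesh$vertices
  if (!is.null(affine)) V <- apply_affine(V, affine)
  lo <- apply(V, 2, min) - voxel_size
  hi <- apply(V, 2, max) + voxel_size
  dims <- as.integer(ceiling((hi - lo) / voxel_size)) + 1L
  occ <- cpp_rasterize_mesh(V, mesh$faces, dims, lo, rep(voxel_size, 3))
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size
  aff[1:3, 4] <- lo
  hm_volume(occ, affine = aff)
}

#' Voxel-count volume of a binary volume
#'
#' @param volume a [hm_volume()].
#' @return foreground voxel count times voxel volume (mm^3).
#' @export
voxel_volume <- function(volume) {
  sum(volume$data) * abs(det(volume$affine[1:3, 1:3]))
}

# one Loop subdivision pass (closed meshes)
loop_subdivide <- function(mesh) {
  V <- mesh$vertices
  F_ <- mesh$faces
  nv <- nrow(V)
  e <- mesh_edges(F_)
  key <- paste(e[, 1], e[, 2])
  uk <- unique(key)
  eid <- match(key, uk)
  ne <- length(uk)
  ue <- e[!duplicated(key), , drop = FALSE]
  # opposite vertices per edge (two for interior edges of a closed mesh)
  opp_all <- as.vector(t(F_[, c(3, 1, 2)]))
  eidx <- matrix(eid, ncol = 3)  # by column: edges (1,2),(2,3),(3,1) per face
  opp1 <- integer(ne); opp2 <- integer(ne)
  ord <- order(eid)
  es <- eid[ord]; os <- c(F_[, 3], F_[, 1], F_[, 2])[ord]
  first <- !duplicated(es)
  opp1[es[first]] <- os[first]
  opp2[es[!first]] <- os[!first]
  # Loop edge points
  EP <- 0.375 * (V[ue[, 1], ] + V[ue[, 2], ]) +
        0.125 * (V[opp1, ] + V[opp2, ])
  # updated old vertices
  nb <- split(c(ue[, 2], ue[, 1]), c(ue[, 1], ue[, 2]))
  deg <- lengths(nb)[as.character(seq_len(nv))]
  deg[is.na(deg)] <- 0L
  beta <- ifelse(deg == 3, 3 / 16,
                 (1 / pmax(deg, 1)) * (5 / 8 - (3 / 8 + 0.25 * cos(2 * pi / pmax(deg, 1)))^2))
  nbsum <- matrix(0, nv, 3)
  idx <- as.integer(names(nb))
  for (d in 1:3) {
    s <- vapply(nb, function(ii) sum(V[ii, d]), numeric(1))
    nbsum[idx, d] <- s
  }
  Vnew <- (1 - deg * beta) * V + beta * nbsum
  # new faces: each face -> 4
  e12 <- eidx[, 1] + nv; e23 <- eidx[, 2] + nv; e31 <- eidx[, 3] + nv
  Fnew <- rbind(cbind(F_[, 1], e12, e31),
                cbind(F_[, 2], e23, e12),
                cbind(F_[, 3], e31, e23),
                cbind(e12, e23, e31))
  hm_mesh(rbind(Vnew, EP), Fnew, id = mesh$id, side = mesh$side)
}

# symmetric Hausdorff distance between meshes, by vertex sampling
hausdorff_distance <- function(mesh_a, mesh_b) {
  da <- cpp_closest_points(mesh_a$vertices, mesh_b$vertices, mesh_b$faces)$dist
  db <- cpp_closest_points(mesh_b$vertices, mesh_a$vertices, mesh_a$faces)$dist
  max(max(da), max(db))
}

#' Resample a closed mesh to a target vertex count
#'
#' Coarse-to-fine remeshing: quadric edge-collapse decimation when above
#' target; Loop subdivision with closest-point projection back onto the input
#' surface when below, followed by decimation to land within tolerance of the
#' target. Genus is preserved (collapses respect the link condition) and the
#' deviation from the input surface is bounded by a symmetric Hausdorff check.
#'
#' @param mesh closed genus-zero [hm_mesh()].
#' @param target_vertices requested vertex count (>= 100); default 15,000,
#'   the per-side analysis resolution.
#' @param count_tol acceptable relative deviation from the target count.
#' @param hausdorff_tol maximal allowed symmetric Hausdorff distance as a
#'   fraction of the input bounding-box diagonal.
#' @return A closed [hm_mesh()] with `abs(V - target)/target <= count_tol`.
#' @export
simplify_and_refine <- function(mesh, target_vertices = 15000L,
                                count_tol = 0.01, hausdorff_tol = 0.01) {
  stopifnot(target_vertices >= 100L)
  top <- check_topology(mesh)
  if (!top$closed || top$euler != 2L)
    stop("simplify_and_refine requires a closed genus-zero mesh", call. = FALSE)
  out <- mesh
  # refine while under target
  while (nrow(out$vertices) < target_vertices) {
    out <- loop_subdivide(out)
    proj <- cpp_closest_points(out$vertices, mesh$vertices, mesh$faces)
    out$vertices <- proj$points
  }
  if (nrow(out$vertices) > target_vertices * (1 + count_tol)) {
    dec <- cpp_decimate_qem(out$vertices, out$faces, as.integer(target_vertices))
    out <- hm_mesh(dec$vertices, dec$faces, id = mesh$id, side = mesh$side)
  }
  achieved <- nrow(out$vertices)
  if (abs(achieved - target_vertices) / target_vertices > count_tol)
    stop(sprintf("could not reach target vertex count: achieved %d for target %d",
                 achieved, target_vertices), call. = FALSE)
  bbox <- apply(mesh$vertices, 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  hd <- hausdorff_distance(out, mesh)
  if (hd > hausdorff_tol * diag_len)
    stop(sprintf(
      "remeshing quality: Hausdorff %.4g exceeds %.4g (%.1f%% of bbox diagonal)",
      hd, hausdorff_tol * diag_len, 100 * hausdorff_tol), call. = FALSE)
  topo <- check_topology(out)
  if (topo$euler != top$euler)
    stop("remeshing changed the Euler characteristic", call. = FALSE)
  out
}
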