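# Two-cut topology optimization: open a closed genus-zero tube surface into a
# topological annulus by removing a small cap at each end of its first
# principal axis of geometric moments.

boundary_loops <- function(faces) {
  e <- mesh_edges(faces)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(list())
  be <- matrix(as.integer(unlist(strsplit(bkey, " "))), ncol = 2, byrow = TRUE)
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  verts <- unique(as.vector(be))
  visited <- setNames(rep(FALSE, length(verts)), verts)
  loops <- list()
  for (v0 in verts) {
    if (visited[as.character(v0)]) next
    # walk the loop in order
    loop <- integer(0)
    v <- v0
    prev <- NA_integer_
    repeat {
      loop <- c(loop, v)
      visited[as.character(v)] <- TRUE
      nb <- adj[[as.character(v)]]
      nxt <- nb[is.na(prev) | nb != prev]
      nxt <- nxt[!visited[as.character(nxt)]]
      if (length(nxt) == 0L) break
      prev <- v
      v <- nxt[[1]]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Open a closed tube surface with two end cuts
#'
#' The first principal axis of the vertex second-moment tensor is found; the
#' extreme `cap_fraction` of vertices at each end (by projection quantile)
#' is removed together with their faces, leaving a topological annulus with
#' two boundary loops. The loop at the positive axis end is labelled
#' anterior. The axis sign is fixed deterministically (largest-magnitude
#' component positive).
#'
#' @param mesh closed genus-zero [hm_mesh()], elongated along one axis.
#' @param cap_fraction fraction of vertices removed at each end (default
#'   0.02).
#' @param axis_ratio_tol minimal required ratio between the top two moment
#'   eigenvalues; below `1 + axis_ratio_tol` the axis is ambiguous.
#' @param axis optional manual unit axis (length-3), overriding the moment
#'   computation when the shape is near-isotropic.
#' @return An `hm_open_mesh`: vertices/faces of the annulus, ordered boundary
#'   loops `loop_posterior` (u = 0 end) and `loop_anterior` (u = 1 end), the
#'   axis used, and the index map `orig_vertex` into the input mesh.
#' @export
compute_cuts <- function(mesh, cap_fraction = 0.02, axis_ratio_tol = 0.1,
                         axis = NULL) {
  stopifnot(cap_fraction > 0, cap_fraction < 0.5)
  V <- mesh$vertices
  if (is.null(axis)) {
    Vc <- sweep(V, 2, colMeans(V))
    mom <- crossprod(Vc) / nrow(Vc)
    eig <- eigen(mom, symmetric = TRUE)
    if (eig$values[1] < (1 + axis_ratio_tol) * eig$values[2])
      stop("principal axis of geometric moments is ambiguous ",
           sprintf("(eigenvalue ratio %.3f); supply `axis` manually",
                   eig$values[1] / eig$values[2]), call. = FALSE)
    axis <- eig$vectors[, 1]
    if (axis[which.max(abs(axis))] < 0) axis <- -axis
  } else {
    axis <- axis / sqrt(sum(axis^2))
  }
  t_ <- as.vector(sweep(V, 2, colMeans(V)) %*% axis)
  qlo <- quantile(t_, cap_fraction, names = FALSE)
  qhi <- quantile(t_, 1 - cap_fraction, names = FALSE)
  # each cap is the connected component of extreme vertices containing the
  # end pole, so stray extreme vertices elsewhere never open extra holes
  e <- mesh_edges(mesh$faces)
  cap_component <- function(ext, seed) {
    sub <- e[ext[e[, 1]] & ext[e[, 2]], , drop = FALSE]
    adj <- split(c(sub[, 2], sub[, 1]), c(sub[, 1], sub[, 2]))
    comp <- rep(FALSE, length(ext))
    stack <- seed
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v]) next
      comp[v] <- TRUE
      nb <- adj[[as.character(v)]]
      if (!is.null(nb)) stack <- c(stack, nb[!comp[nb]])
    }
    comp
  }
  drop_v <- cap_component(t_ <= qlo, which.min(t_)) |
            cap_component(t_ >= qhi, which.max(t_))
  keep_f <- !(drop_v[mesh$faces[, 1]] | drop_v[mesh$faces[, 2]] |
              drop_v[mesh$faces[, 3]])
  F_ <- mesh$faces[keep_f, , drop = FALSE]
  used <- sort(unique(as.vector(F_)))
  vmap <- integer(nrow(V)); vmap[used] <- seq_along(used)
  F2 <- matrix(vmap[F_], ncol = 3)
  V2 <- V[used, , drop = FALSE]
  loops <- boundary_loops(F2)
  if (length(loops) != 2L)
    stop("cutting produced ", length(loops),
         " boundary loops (expected 2); adjust cap_fraction", call. = FALSE)
  om <- hm_mesh(V2, F2, id = mesh$id, side = mesh$side)
  top <- check_topology(om)
  if (top$euler != 0L)
    stop("cut surface is not an annulus (Euler characteristic ", top$euler,
         ")", call. = FALSE)
  tload <- vapply(loops, function(l) mean(t_[used[l]]), numeric(1))
  anterior <- loops[[which.max(tload)]]
  posterior <- loops[[which.min(tload)]]
  structure(list(vertices = V2, faces = F2,
                 loop_posterior = posterior, loop_anterior = anterior,
                 axis = axis, orig_vertex = used,
                 id = mesh$id, side = mesh$side),
            class = c("hm_open_mesh", "hm_mesh"))
}

#' @export
print.hm_open_mesh <- function(x, ...) {
  cat(sprintf("<hm_open_mesh> %d vertices, %d faces, boundary loops %d + %d\n",
              nrow(x$vertices), nrow(x$faces), length(x$loop_posterior),
              length(x$loop_anterior)))
  invisible(x)
}
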