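#' Read a binary mask from a NIfTI-1 file
#'
#' Voxels above `threshold` are foreground; the qform/sform affine is kept as
#' the voxel-to-world transform (0-based voxel indices).
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param threshold foreground threshold on intensities.
#' @return A [hm_volume()].
#' @export
read_mask_nifti <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = "matrix")
  a <- array(as.array(img) > threshold, dim = dim(img)[1:3])
  hm_volume(a, affine = matrix(as.numeric(aff), 4, 4))
}

#' Write a binary mask to a NIfTI-1 file
#' @param volume a [hm_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(volume, path) {
  img <- RNifti::asNifti(array(as.integer(volume$data), dim(volume$data)))
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a triangle mesh (PLY, OFF, or VTK legacy polydata)
#'
#' Format is chosen by file extension. PLY supports ASCII and
#' binary-little-endian; OFF and VTK are ASCII.
#'
#' @param path mesh file.
#' @return A [hm_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         off = read_off(path),
         vtk = read_vtk_polydata(path),
         stop("unsupported mesh format: .", ext, call. = FALSE))
}

#' Write a triangle mesh (PLY, OFF, or VTK legacy polydata)
#'
#' @param mesh a [hm_mesh()].
#' @param path output path; extension selects the format.
#' @param binary for PLY, write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, binary = binary),
         off = write_off(mesh, path),
         vtk = write_vtk_polydata(mesh, path),
         stop("unsupported mesh format: .", ext, call. = FALSE))
  invisible(path)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- c("ply", paste("format", fmt, "1.0"),
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, 1)
    hdr <- c(hdr, ln)
    if (identical(ln, "end_header")) break
    if (length(hdr) > 100) stop("malformed PLY header", call. = FALSE)
  }
  fmt <- sub("^format ([a-z_]+).*", "\\1", grep("^format", hdr, value = TRUE))
  nv <- as.integer(sub(".*vertex (\\d+)", "\\1",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub(".*face (\\d+)", "\\1",
                       grep("^element face", hdr, value = TRUE)))
  vprops <- grep("^property (double|float)", hdr, value = TRUE)
  psize <- if (grepl("double", vprops[1])) 8L else 4L
  if (fmt == "binary_little_endian") {
    V <- matrix(readBin(con, "double", nv * length(vprops), size = psize,
                        endian = "little"), ncol = length(vprops),
                byrow = TRUE)[, 1:3, drop = FALSE]
    F_ <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      k <- as.integer(readBin(con, "raw", 1))
      idx <- readBin(con, "integer", k, size = 4, endian = "little")
      if (k != 3L) stop("non-triangular PLY face", call. = FALSE)
      F_[i, ] <- idx + 1L
    }
  } else {
    txt <- readLines(con)
    vv <- strsplit(trimws(txt[seq_len(nv)]), "\\s+")
    V <- matrix(as.numeric(unlist(vv)), ncol = length(vprops),
                byrow = TRUE)[, 1:3, drop = FALSE]
    ff <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    F_ <- t(vapply(ff, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  }
  hm_mesh(V, F_)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces), 0), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

read_off <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  stopifnot(grepl("OFF", txt[1]))
  counts <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  V <- matrix(as.numeric(unlist(strsplit(trimws(txt[2 + seq_len(nv)]), "\\s+"))),
              ncol = 3, byrow = TRUE)
  ff <- strsplit(trimws(txt[2 + nv + seq_len(nf)]), "\\s+")
  F_ <- t(vapply(ff, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  hm_mesh(V, F_)
}

write_vtk_polydata <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "hippomorph surface", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nv, "double")), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste("POLYGONS", nf, 4 * nf), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  if (!is.null(point_data)) {
    writeLines(paste("POINT_DATA", nv), con)
    for (nm in names(point_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
}

read_vtk_polydata <- function(path) {
  txt <- readLines(path)
  ip <- grep("^POINTS", txt)[1]
  nv <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  vals <- numeric(0)
  i <- ip + 1
  while (length(vals) < 3 * nv) {
    vals <- c(vals, as.numeric(strsplit(trimws(txt[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  V <- matrix(vals[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  ifc <- grep("^POLYGONS", txt)[1]
  nf <- as.integer(strsplit(txt[ifc], "\\s+")[[1]][2])
  ff <- strsplit(trimws(txt[ifc + seq_len(nf)]), "\\s+")
  F_ <- t(vapply(ff, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  hm_mesh(V, F_)
}
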