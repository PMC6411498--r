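# Mesh topology reports, enclosed volumes, mask-to-surface reconstruction,
# voxelization, and coarse-to-fine remeshing.

test_that("check_topology classifies sphere, open cylinder, and torus", {
  sph <- icosphere_mesh(1, 2)
  top <- check_topology(sph)
  expect_identical(top$euler, 2L)
  expect_identical(top$n_boundary_loops, 0L)
  expect_true(top$closed)
  expect_identical(top$genus, 0L)

  cyl <- open_cylinder_mesh()
  topc <- check_topology(cyl)
  expect_identical(topc$euler, 0L)
  expect_identical(topc$n_boundary_loops, 2L)
  expect_false(topc$closed)

  tor <- check_topology(torus_mesh())
  expect_identical(tor$euler, 0L)
  expect_identical(tor$n_boundary_loops, 0L)
  expect_identical(tor$genus, 1L)
})

test_that("mesh_volume: cube exact, orientation invariant, sphere analytic", {
  cube <- unit_cube_mesh()
  expect_equal(mesh_volume(cube), 1)
  flipped <- cube
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_equal(mesh_volume(flipped), 1)
  sph <- icosphere_mesh(1, 4)
  expect_equal(mesh_volume(sph), 4 * pi / 3, tolerance = 0.005)
  expect_error(mesh_volume(open_cylinder_mesh()), "closed")
  # affine scaling multiplies the volume by the determinant
  aff <- diag(c(2, 3, 1, 1))
  expect_equal(mesh_volume(cube, affine = aff), 6)
})

test_that("reconstruct_surface meshes digital masks at analytic volumes", {
  # single voxel
  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  m <- reconstruct_surface(hm_volume(a), closing = FALSE)
  expect_identical(check_topology(m)$euler, 2L)
  expect_lt(abs(mesh_volume(m) - 1), 0.3)
  # empty mask errors
  expect_error(reconstruct_surface(hm_volume(array(FALSE, c(4, 4, 4)))),
               "empty")
  # digital ball radius 10
  r <- 10
  n <- 2 * r + 5
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2,
                c(n, n, n))
  mb <- reconstruct_surface(hm_volume(ball), closing = FALSE)
  expect_identical(check_topology(mb)$euler, 2L)
  expect_equal(mesh_volume(mb), 4 * pi * r^3 / 3, tolerance = 0.02)
})

test_that("reconstruct_surface drops small outlier clusters", {
  a <- array(FALSE, c(20, 20, 20))
  a[5:15, 5:15, 5:15] <- TRUE   # main block
  a[18, 18, 18] <- TRUE         # stray voxel cluster
  m <- reconstruct_surface(hm_volume(a), min_component = 5, closing = FALSE)
  expect_identical(check_topology(m)$euler, 2L)
  expect_equal(mesh_volume(m), 11^3, tolerance = 0.1)
})

test_that("rasterize_mesh recovers analytic volumes and rejects open meshes", {
  cube <- unit_cube_mesh()
  vol <- rasterize_mesh(cube, voxel_size = 0.1)
  expect_equal(voxel_volume(vol), 1, tolerance = 0.05)
  sph <- icosphere_mesh(5, 3)
  vs <- rasterize_mesh(sph, voxel_size = 0.25)
  expect_equal(voxel_volume(vs), 4 * pi * 125 / 3, tolerance = 0.03)
  expect_error(rasterize_mesh(open_cylinder_mesh(), 0.5), "closed")
  expect_error(rasterize_mesh(hm_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)), 1),
               "empty")
})

test_that("voxelization and mesh volume agree in round trip", {
  tube <- make_template_tube(24, 16, length = 30, radius_profile = 4,
                             bend = 0.5)
  mv <- mesh_volume(tube)
  vol <- rasterize_mesh(tube, voxel_size = 0.4)
  expect_equal(voxel_volume(vol), mv, tolerance = 0.05)
  # reconstruct o rasterize o reconstruct is volume-stable
  m2 <- reconstruct_surface(vol, closing = FALSE)
  expect_equal(mesh_volume(m2), mv, tolerance = 0.1)
})

test_that("simplify_and_refine hits the target count and preserves topology", {
  sph <- icosphere_mesh(1, 4)  # 2562 vertices
  dec <- simplify_and_refine(sph, 1000L)
  expect_lt(abs(nrow(dec$vertices) - 1000) / 1000, 0.011)
  expect_identical(check_topology(dec)$euler, 2L)
  expect_equal(mesh_volume(dec), mesh_volume(sph), tolerance = 0.01)
  # refinement path: coarse sphere up to 2000
  coarse <- icosphere_mesh(1, 2)  # 162 vertices
  ref <- simplify_and_refine(coarse, 2000L)
  expect_lt(abs(nrow(ref$vertices) - 2000) / 2000, 0.011)
  expect_identical(check_topology(ref)$euler, 2L)
  expect_equal(mesh_volume(ref), mesh_volume(coarse), tolerance = 0.02)
  expect_error(simplify_and_refine(sph, 50L), "target")
})

test_that("mesh IO round-trips PLY (binary and ascii), OFF, and VTK", {
  tube <- make_template_tube(10, 8)
  for (ext in c("ply", "off", "vtk")) {
    path <- file.path(tempdir(), paste0("m.", ext))
    write_mesh(tube, path)
    m2 <- read_mesh(path)
    expect_equal(m2$vertices, tube$vertices, tolerance = 1e-12)
    expect_identical(m2$faces, tube$faces)
    unlink(path)
  }
  path <- file.path(tempdir(), "m_ascii.ply")
  write_mesh(tube, path, binary = FALSE)
  m3 <- read_mesh(path)
  expect_equal(m3$vertices, tube$vertices, tolerance = 1e-10)
  unlink(path)
})

test_that("NIfTI mask round-trip preserves occupancy and affine", {
  a <- array(FALSE, c(8, 9, 10)); a[3:6, 4:7, 2:8] <- TRUE
  aff <- diag(c(0.9, 1.1, 1.2, 1)); aff[1:3, 4] <- c(-4, 3, 7)
  vol <- hm_volume(a, affine = aff)
  path <- file.path(tempdir(), "mask.nii.gz")
  write_mask_nifti(vol, path)
  v2 <- read_mask_nifti(path)
  expect_identical(v2$data, vol$data)
  expect_equal(v2$affine, vol$affine, tolerance = 1e-5)
  unlink(path)
})
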