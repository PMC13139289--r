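test_that("single-voxel surface is closed; area pinned as regression fixture", {
  m <- binary_mask(array(1L, c(1, 1, 1)))
  mesh <- build_surface(m, sigma = 0)
  expect_true(is_watertight(mesh))
  expect_equal(nrow(mesh$faces), 24L)
  # the level-0.5 iso-surface bevels the voxel's corners, so its area is
  # below the 6 mm^2 of the axis-aligned voxel cube; pinned value for the
  # tetrahedral iso-surfacer:
  expect_equal(surface_area(mesh), 3.6213203, tolerance = 1e-6)
  # the default anti-aliased path falls back to the raw iso-surface for
  # sub-voxel deposits rather than losing them
  expect_true(is_watertight(build_surface(m)))
  expect_error(build_surface(binary_mask(array(0L, c(2, 2, 2)))), "no surface")
})

test_that("ball surface area converges to the analytic sphere area", {
  mesh <- build_surface(ball_mask(10, 0.5))
  expect_lt(abs(surface_area(mesh) / (4 * pi * 100) - 1), 0.03)
  expect_true(is_watertight(mesh))
})

test_that("face normals are unit length, outward, and flag degenerate faces", {
  mesh <- build_surface(ball_mask(4, 0.5))
  n <- face_normals(mesh)
  expect_equal(sqrt(rowSums(n^2)), rep(1, nrow(n)), tolerance = 1e-6)
  # outward on a convex solid: positive dot with centre-to-face vector
  cen <- face_centroids(mesh)
  ctr <- colMeans(mesh$vertices)
  outward <- rowSums(n * sweep(cen, 2, ctr)) > 0
  expect_true(all(outward))
  # CCW triangle in the z = 0 plane has normal (0, 0, 1)
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(face_normals(tri)), c(0, 0, 1))
  degen <- triangle_mesh(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                         matrix(c(1, 2, 3), 1))
  expect_error(face_normals(degen), "degenerate")
})

test_that("areas and centroids follow the closed-form triangle geometry", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                       matrix(c(1, 2, 3), 1))
  expect_equal(face_areas(tri), 6)
  eq <- triangle_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)),
                      matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(face_centroids(eq)),
               colMeans(eq$vertices))
})

test_that("surface area sums faces: cube, icosphere, permutation invariance", {
  cube <- unit_cube_mesh()
  expect_equal(surface_area(cube), 6)
  ico <- icosphere_mesh(r = 5, subdivisions = 3)
  expect_lt(abs(surface_area(ico) / (4 * pi * 25) - 1), 0.02)
  set.seed(1)
  shuffled <- triangle_mesh(cube$vertices, cube$faces[sample(12), ])
  expect_equal(surface_area(shuffled), surface_area(cube))
})

test_that("S is invariant under rigid motion and scales as k^2", {
  mesh <- build_surface(ball_mask(3, 0.5))
  S0 <- surface_area(mesh)
  R <- rotation_matrix("y", 37)
  moved <- triangle_mesh(mesh$vertices %*% t(R) +
                           matrix(c(5, -2, 1), nrow(mesh$vertices), 3,
                                  byrow = TRUE), mesh$faces)
  expect_equal(surface_area(moved), S0, tolerance = 1e-10)
  scaled <- triangle_mesh(mesh$vertices * 2.5, mesh$faces)
  expect_equal(surface_area(scaled), S0 * 2.5^2, tolerance = 1e-10)
})

test_that("constructed surfaces are watertight with every edge shared twice", {
  for (mask in list(ball_mask(3, 0.5),
                    make_annulus(phantom_spec(shape = "annulus", r1 = 1.5,
                                              r2 = 2.5, height = 3, arc = 200,
                                              spacing = 0.5))$truth$calc_mask)) {
    mesh <- build_surface(mask)
    e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(table(key) == 2L))
    expect_gt(min(face_areas(mesh)), 0)
  }
})

test_that("mesh export writes readable PLY and STL", {
  mesh <- unit_cube_mesh()
  fp <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, fp)
  lines <- readLines(fp)
  expect_equal(lines[1], "ply")
  expect_true(any(grepl("element vertex 8", lines)))
  fs <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, fs)
  expect_equal(sum(grepl("^facet", readLines(fs))), 12L)
})
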