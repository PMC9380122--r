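test_that("sphere meshes are watertight with accurate enclosed volume", {
  s <- sphere_mask(20)
  mesh <- extract_surface_mesh(s, meshing_params(1, 6))
  expect_true(is_watertight(mesh))
  vol_true <- 4 / 3 * pi * 20^3
  expect_lt(abs(mesh_volume(mesh) / vol_true - 1), 0.05)
  # mean edge within +-30% of the target
  expect_lt(abs(mean_edge_length(mesh) / 6 - 1), 0.3)
})

test_that("finer edge targets give more triangles", {
  s <- sphere_mask(20)
  n3 <- nrow(extract_surface_mesh(s, meshing_params(1, 3))$triangles)
  n12 <- nrow(extract_surface_mesh(s, meshing_params(1, 12))$triangles)
  expect_gt(n3, n12)
})

test_that("heavy smoothing keeps the mesh within the smoothed support", {
  cube <- predicate_mask(function(p)
    abs(p[, 1] - 23.5) <= 15 & abs(p[, 2] - 23.5) <= 15 &
      abs(p[, 3] - 23.5) <= 15)
  mesh <- extract_surface_mesh(cube, meshing_params(5, 6))
  support <- sum(gaussian_smooth(cube, 5 / 2)$data > 0) *
    voxel_volume_mm3(cube)
  expect_lt(mesh_volume(mesh), support)
})

test_that("meshing error paths: empty and too-small masks", {
  empty <- image_volume(array(FALSE, c(16, 16, 16)), 1, c(0, 0, 0))
  expect_error(extract_surface_mesh(empty), "empty")
  tiny <- sphere_mask(2, n = 16L)
  expect_error(extract_surface_mesh(tiny, meshing_params(1, 12)), "edge")
})

test_that("mesh-mask Dice: self, disjoint and concentric cases", {
  s20 <- sphere_mask(20)
  m20 <- extract_surface_mesh(s20, meshing_params(1, 3))
  expect_gte(mesh_mask_dice(m20, s20), 0.98)

  # disjoint translated sphere
  far <- sphere_mask(15, n = 48L, center = c(120, 23.5, 23.5))
  m15 <- extract_surface_mesh(sphere_mask(15), meshing_params(1, 3))
  expect_equal(mesh_mask_dice(
    structure(list(vertices = m15$vertices + matrix(c(120 - 23.5, 0, 0),
                                                    nrow(m15$vertices), 3,
                                                    byrow = TRUE),
                   triangles = m15$triangles, provenance = NULL),
              class = "surface_mesh"),
    sphere_mask(20)), 0)

  # concentric spheres: analytic 2 r1^3 / (r1^3 + r2^3)
  m10 <- extract_surface_mesh(sphere_mask(10), meshing_params(1, 2))
  d <- mesh_mask_dice(m10, s20)
  expect_lt(abs(d - 2 * 10^3 / (10^3 + 20^3)) / (2 / 9), 0.05)
})

test_that("dice is invariant to a world-frame translation", {
  s10 <- sphere_mask(10)
  m <- extract_surface_mesh(s10, meshing_params(1, 3))
  d0 <- mesh_mask_dice(m, s10)
  s10b <- image_volume(s10$data, s10$spacing, s10$origin + 50)
  mb <- extract_surface_mesh(s10b, meshing_params(1, 3))
  expect_equal(mesh_mask_dice(mb, s10b), d0, tolerance = 1e-6)
})

test_that("parameter selection returns the argmax with a full table", {
  s <- sphere_mask(20, n = 56L)
  single <- select_mesh_params(s, data.frame(smoothing_radius = 3,
                                             edge_length = 6))
  expect_equal(single$best$edge_length, 6)
  expect_equal(single$best$smoothing_radius, 3)

  two <- select_mesh_params(s, data.frame(smoothing_radius = 1,
                                          edge_length = c(6, 60)))
  expect_equal(two$best$edge_length, 6)
  expect_true(is.na(two$table$dice[2]) ||
                two$table$dice[2] < two$table$dice[1])

  grid <- select_mesh_params(s)
  expect_equal(nrow(grid$table), 12)
  best_dice <- max(grid$table$dice, na.rm = TRUE)
  chosen <- grid$table$dice[grid$table$edge_length == grid$best$edge_length &
    grid$table$smoothing_radius == grid$best$smoothing_radius]
  expect_equal(chosen, best_dice)
})

test_that("tet mesh conforms to its surface with positive volumes", {
  mesh <- extract_surface_mesh(sphere_mask(20), meshing_params())
  tm <- sphere_tet_mesh()
  expect_gt(nrow(tm$tets), 0)
  expect_gt(ablmargin:::min_tet_volume(tm$nodes, tm$tets), 0)
  expect_lt(abs(tet_mesh_volume(tm) / mesh_volume(mesh) - 1), 0.02)
  # boundary nodes are exactly the surface vertices (bijective)
  expect_equal(length(tm$surface_vertex_ids), nrow(mesh$vertices))
  expect_equal(tm$nodes[tm$surface_vertex_ids, , drop = FALSE],
               mesh$vertices)
})

test_that("build_tet_mesh rejects surfaces without an extraction field", {
  fake <- structure(list(vertices = matrix(rnorm(9), 3),
                         triangles = matrix(1:3, 1), provenance = NULL),
                    class = "surface_mesh")
  expect_error(build_tet_mesh(fake), "extraction field")
})
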