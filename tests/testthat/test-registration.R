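test_that("rigid transforms compose, invert and serialize consistently", {
  tf <- rigid_transform(euler_rotation(4, -3, 7), c(2, -1, 5), c(10, 10, 10))
  pts <- matrix(rnorm(30, sd = 20), 10, 3)
  back <- apply_rigid(invert_rigid(tf), apply_rigid(tf, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  m4 <- rigid_matrix4(tf)
  expect_equal(as.vector(m4 %*% c(pts[1, ], 1))[1:3],
               as.vector(apply_rigid(tf, pts[1, , drop = FALSE])),
               tolerance = 1e-9)
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
})

test_that("gray-level rigid registration recovers known motions", {
  case <- small_phantom()
  fx <- case$pre$volume
  msk <- case$pre$masks$liver

  # self-registration
  tf0 <- rigid_register(fx, fx, msk, msk)
  expect_lt(sqrt(sum(tf0$translation^2)), 0.1)
  expect_lt(rotation_angle_deg(tf0), 0.1)

  # pure translation, realized exactly by shifting the grid origin
  t_true <- c(6, -4, 2)
  mv <- image_volume(fx$data, fx$spacing, fx$origin + t_true)
  msk_mv <- image_volume(msk$data, msk$spacing, msk$origin + t_true)
  tf1 <- rigid_register(fx, mv, msk, msk_mv)
  expect_lt(sqrt(sum((tf1$translation - t_true)^2)), 0.5)
  expect_lt(rotation_angle_deg(tf1), 0.5)

  # pure rotation about z through the liver centroid
  cen <- mask_centroid(msk)
  tru <- rigid_transform(euler_rotation(rz = 5), c(0, 0, 0), cen)
  pts <- voxel_centers(fx)
  rot_data <- sample_trilinear(fx, apply_rigid(invert_rigid(tru), pts),
                               fill = -1000)
  mv2 <- image_volume(array(rot_data, dim(fx$data)), fx$spacing, fx$origin)
  msk2_d <- sample_trilinear(
    image_volume(msk$data * 1, msk$spacing, msk$origin),
    apply_rigid(invert_rigid(tru), pts), fill = 0) >= 0.5
  msk2 <- image_volume(array(msk2_d, dim(msk$data)), msk$spacing, msk$origin)
  tf2 <- rigid_register(fx, mv2, msk, msk2)
  dR <- tf2$rotation %*% t(tru$rotation)
  expect_lt(rotation_angle_deg(dR), 0.5)

  expect_error(rigid_register(fx, fx, image_volume(
    array(FALSE, dim(msk$data)), msk$spacing, msk$origin), msk), "empty")
})

test_that("surface correspondence handles rigid and similarity maps", {
  mesh <- extract_surface_mesh(sphere_mask(20), meshing_params())
  edge <- mean_edge_length(mesh)

  bc0 <- surface_correspondence(mesh, mesh, relax_iters = 10)
  expect_lt(max(abs(bc0$displacements)), 1e-6)

  t0 <- c(4, -2, 3)
  shifted <- structure(list(
    vertices = sweep(mesh$vertices, 2, t0, "+"),
    triangles = mesh$triangles, provenance = mesh$provenance),
    class = "surface_mesh")
  attr(shifted, "field") <- attr(mesh, "field")
  bc1 <- surface_correspondence(mesh, shifted, relax_iters = 50)
  err <- sweep(bc1$displacements, 2, t0, "-")
  expect_lt(max(sqrt(rowSums(err^2))), edge / 2)

  cen <- colMeans(mesh$vertices)
  scaled <- structure(list(
    vertices = sweep(sweep(mesh$vertices, 2, cen, "-") * 1.1, 2, cen, "+"),
    triangles = mesh$triangles, provenance = mesh$provenance),
    class = "surface_mesh")
  bc2 <- surface_correspondence(mesh, scaled, relax_iters = 50)
  expected <- 0.1 * sweep(mesh$vertices, 2, cen, "-")
  err2 <- bc2$displacements - expected
  expect_lt(max(sqrt(rowSums(err2^2))), edge / 2)

  far <- structure(list(vertices = mesh$vertices + 500,
                        triangles = mesh$triangles, provenance = NULL),
                   class = "surface_mesh")
  expect_error(surface_correspondence(mesh, far), "disjoint")
})

test_that("rasterized fields reproduce translation and affine solutions", {
  tm <- sphere_tet_mesh()
  roi <- sphere_mask(18)
  t0 <- c(2, 1, -3)
  u_t <- matrix(t0, nrow(tm$nodes), 3, byrow = TRUE)
  dvf <- rasterize_dvf(tm, u_t, roi)
  v <- matrix(dvf$v, ncol = 3)[which(roi$data), , drop = FALSE]
  expect_lt(max(abs(sweep(v, 2, t0, "-"))), 1e-6)

  A <- matrix(c(0.04, 0.01, 0, -0.02, 0.05, 0.01, 0, 0.02, 0.03), 3, 3)
  u_a <- tm$nodes %*% t(A)
  dvf_a <- rasterize_dvf(tm, u_a, roi)
  pts <- voxel_centers(roi, roi$data)
  expect_lt(max(abs(matrix(dvf_a$v, ncol = 3)[which(roi$data), ] -
                      pts %*% t(A))), 1e-6)
})

test_that("contour propagation: identity, shift and round trip", {
  case <- small_phantom()
  gtv <- case$pre$masks$gtv
  d <- dim(gtv$data)
  zero <- displacement_field(array(0, c(d, 3)), gtv$spacing, gtv$origin,
                             array(TRUE, d))
  same <- propagate_contour(gtv, zero, "forward", gtv)
  expect_gte(dice_coef(same, gtv), 0.99)

  t0 <- c(4.5, -3, 6)
  vt <- array(0, c(d, 3))
  for (c in 1:3) vt[, , , c] <- t0[c]
  shift_field <- displacement_field(vt, gtv$spacing, gtv$origin,
                                    array(TRUE, d))
  moved <- propagate_contour(gtv, shift_field, "forward", gtv)
  shifted_ref <- image_volume(gtv$data, gtv$spacing, gtv$origin + t0)
  ref_on_grid <- propagate_contour(shifted_ref,
                                   rigid_transform(), "forward", gtv)
  expect_gte(dice_coef(moved, ref_on_grid), 0.98)

  # forward-then-inverse round trip through the phantom warp
  fwd <- propagate_contour(gtv, case$truth$dvf, "forward",
                           case$post$masks$liver)
  back <- propagate_contour(fwd, case$truth$dvf, "inverse", gtv)
  expect_gte(dice_coef(back, gtv), 0.97)
})

test_that("field inversion signals non-convergence", {
  d <- c(24L, 24L, 24L)
  v <- array(0, c(d, 3))
  fld <- displacement_field(v, 1, c(0, 0, 0), array(TRUE, d))
  expect_silent(ablmargin:::invert_dvf_points(fld, matrix(5, 2, 3)))
  # an oscillating map: large positive displacement on one side, large
  # negative on the other, so the fixed point cycles between the bounds
  x <- seq(0, 23)
  v2 <- array(0, c(d, 3))
  v2[, , , 1] <- array(rep(40 * sign(x - 11.5), times = d[2] * d[3]), d)
  fld2 <- displacement_field(v2, 1, c(0, 0, 0), array(TRUE, d))
  expect_error(ablmargin:::invert_dvf_points(fld2, matrix(11, 1, 3),
                                             maxit = 10),
               "did not converge")
})
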