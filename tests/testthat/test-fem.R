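surface_bc <- function(tm, f) {
  boundary_conditions(tm$surface_vertex_ids,
                      f(tm$nodes[tm$surface_vertex_ids, , drop = FALSE]))
}

test_that("rigid-body boundary data is reproduced exactly", {
  tm <- sphere_tet_mesh()
  t0 <- c(3, -2, 1)
  u <- solve_linear_elastic(tm, surface_bc(tm, function(x)
    matrix(t0, nrow(x), 3, byrow = TRUE)))
  expect_lt(max(abs(sweep(u, 2, t0, "-"))), 1e-6)
  expect_lt(attr(u, "residual"), 1e-8)
})

test_that("affine boundary data is exact for linear elements", {
  tm <- sphere_tet_mesh()
  A <- matrix(c(0.05, 0.02, 0, -0.01, 0.03, 0.015, 0.005, 0, 0.04), 3, 3)
  b <- c(1, -2, 0.5)
  aff <- function(x) x %*% t(A) + matrix(b, nrow(x), 3, byrow = TRUE)
  u <- solve_linear_elastic(tm, surface_bc(tm, aff))
  expect_lt(max(abs(u - aff(tm$nodes))), 1e-6)
})

test_that("pure-Dirichlet solution is invariant to the Young's modulus", {
  tm <- sphere_tet_mesh()
  bc <- surface_bc(tm, function(x) {
    c0 <- colMeans(tm$nodes)
    d <- sweep(x, 2, c0, "-")
    cbind(0.1 * d[, 1]^2 / 20, -0.05 * d[, 2], 0.08 * d[, 3]) / 5
  })
  u1 <- solve_linear_elastic(tm, bc, elastic_params(1000, 0.45))
  u2 <- solve_linear_elastic(tm, bc, elastic_params(2000, 0.45))
  expect_lt(max(abs(u1 - u2)), 1e-9)
  # the Poisson ratio, by contrast, changes the interior distribution
  u3 <- solve_linear_elastic(tm, bc, elastic_params(1000, 0.2))
  expect_gt(max(abs(u1 - u3)), 1e-6)
})

test_that("boundary conditions are validated", {
  tm <- sphere_tet_mesh()
  expect_error(boundary_conditions(c(1, 1), matrix(0, 2, 3)), "exactly one")
  expect_error(boundary_conditions(1, matrix(c(1, NA, 0), 1, 3)), "finite")
  part <- boundary_conditions(tm$surface_vertex_ids[-1],
                              matrix(0, length(tm$surface_vertex_ids) - 1, 3))
  expect_error(solve_linear_elastic(tm, part), "cover")
})
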