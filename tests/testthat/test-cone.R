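cone_fixture <- function() cached("cone_fixture", {
  n <- 64L
  g <- image_volume(array(FALSE, c(n, n, n)), 1, c(0, 0, 0))
  pts <- voxel_centers(g)
  cen <- rep(32, 3)
  mk <- function(f) image_volume(array(f(pts), c(n, n, n)), 1, c(0, 0, 0))
  ang <- function(p) {
    d <- sweep(p, 2, cen, "-")
    r <- sqrt(rowSums(d^2))
    list(r = r, th = acos(pmin(pmax(d[, 3] / pmax(r, 1e-9), -1), 1)) *
           180 / pi)
  }
  list(cen = cen, mk = mk, ang = ang, pts = pts, n = n)
})

test_that("mask centroids equal the brute-force voxel-center mean", {
  fx <- cone_fixture()
  s <- sphere_mask(10, n = 64L, center = fx$cen)
  expect_lt(max(abs(mask_centroid(s) - fx$cen)), 0.5)

  two <- image_volume(array(FALSE, c(32, 32, 32)), 1, c(0, 0, 0))
  two$data[1, 1, 1] <- TRUE     # center (0, 0, 0)
  two$data[11, 1, 1] <- TRUE    # center (10, 0, 0)
  expect_equal(mask_centroid(two), c(5, 0, 0))

  set.seed(5)
  blob <- image_volume(array(runif(27e3) < 0.1, c(30, 30, 30)), 1.3,
                       c(2, -1, 4))
  expect_equal(mask_centroid(blob),
               unname(colMeans(voxel_centers(blob, blob$data))),
               tolerance = 1e-9)
  expect_error(mask_centroid(image_volume(array(FALSE, c(4, 4, 4)), 1,
                                          c(0, 0, 0))), "empty")
})

test_that("pole, axis and full-shell direction sets", {
  fx <- cone_fixture()
  rec_z <- fx$mk(function(p) abs(p[, 1] - 32) < 0.4 &
                   abs(p[, 2] - 32) < 0.4 & abs(p[, 3] - 42) < 0.4)
  ds <- build_direction_set(fx$cen, rec_z, 2)
  expect_true(all(ds[1, ]))

  rec_x <- fx$mk(function(p) abs(p[, 1] - 42) < 0.4 &
                   abs(p[, 2] - 32) < 0.4 & abs(p[, 3] - 32) < 0.4)
  ds2 <- build_direction_set(fx$cen, rec_x, 2)
  expect_true(ds2[46, 91])   # theta = 90 deg, phi = 0 deg

  shell <- fx$mk(function(p) {
    a <- fx$ang(p)
    a$r >= 14 & a$r <= 16
  })
  expect_true(all(build_direction_set(fx$cen, shell, 10)))

  # a voxel at the centroid has no direction: skipped with a warning
  rec_c <- rec_z
  rec_c$data[33, 33, 33] <- TRUE  # center (32,32,32) = centroid
  expect_warning(build_direction_set(fx$cen, rec_c, 2), "centroid")
})

test_that("aligned and opposed constructions give overlap yes/no", {
  fx <- cone_fixture()
  rec_cap <- fx$mk(function(p) {
    a <- fx$ang(p)
    a$r >= 20 & a$r <= 26 & a$th < 27
  })
  cap_up <- fx$mk(function(p) {
    a <- fx$ang(p)
    a$r >= 8 & a$r <= 12 & a$th < 25
  })
  cap_down <- fx$mk(function(p) {
    a <- fx$ang(p)
    a$r >= 8 & a$r <= 12 & a$th > 155
  })
  ds <- build_direction_set(fx$cen, rec_cap, 2)
  up <- cone_overlap(ds, fx$cen, cap_up)
  expect_true(up$overlap)
  expect_equal(up$overlap_volume_cc, mask_volume_cc(cap_up))
  down <- cone_overlap(ds, fx$cen, cap_down)
  expect_false(down$overlap)
  expect_equal(down$overlap_volume_cc, 0)
  # empty uncovered region is not an error
  none <- cone_overlap(ds, fx$cen, fx$mk(function(p) rep(FALSE, nrow(p))))
  expect_false(none$overlap)
})

test_that("sector overlap matches analytic volume and the voxel oracle", {
  fx <- cone_fixture()
  unc <- fx$mk(function(p) {
    a <- fx$ang(p)
    a$r >= 8 & a$r <= 14 & a$th <= 45
  })
  rec <- fx$mk(function(p) {
    a <- fx$ang(p)
    a$r >= 24 & a$r <= 28 & a$th <= 30
  })
  res <- cone_overlap(build_direction_set(fx$cen, rec, 2), fx$cen, unc)
  ana <- 2 * pi / 3 * (14^3 - 8^3) * (1 - cos(30 * pi / 180)) / 1000
  expect_lt(abs(res$overlap_volume_cc - ana) / ana, 0.05)

  # bin-free oracle with the same every-point (footprint) semantics
  ud <- sweep(voxel_centers(unc, unc$data), 2, fx$cen, "-")
  ud <- ud / sqrt(rowSums(ud^2))
  rd <- sweep(voxel_centers(rec, rec$data), 2, fx$cen, "-")
  rl <- sqrt(rowSums(rd^2))
  rdn <- rd / rl
  half <- atan2(0.5, rl)
  angm <- acos(pmin(pmax(rdn %*% t(ud), -1), 1))
  brute <- sum(colSums(angm <= half) > 0) / 1000
  expect_lt(abs(res$overlap_volume_cc - brute) / brute, 0.05)
  expect_true(all(res$overlap_mask$data <= unc$data))
})

test_that("overlap volume is rotation-equivariant and dilation-monotone", {
  fx <- cone_fixture()
  unc <- fx$mk(function(p) {
    a <- fx$ang(p)
    a$r >= 8 & a$r <= 14 & a$th <= 45
  })
  rec <- fx$mk(function(p) {
    a <- fx$ang(p)
    a$r >= 24 & a$r <= 28 & a$th <= 30
  })
  base <- cone_overlap(build_direction_set(fx$cen, rec, 2), fx$cen, unc)

  R <- euler_rotation(0, 0, 33)
  rot_mask <- function(m) {
    src <- sweep(sweep(fx$pts, 2, fx$cen, "-") %*% R, 2, fx$cen, "+")
    v <- sample_trilinear(image_volume(m$data * 1, m$spacing, m$origin),
                          src) >= 0.5
    image_volume(array(v, dim(m$data)), m$spacing, m$origin)
  }
  rot <- cone_overlap(build_direction_set(fx$cen, rot_mask(rec), 2),
                      fx$cen, rot_mask(unc))
  expect_lt(abs(rot$overlap_volume_cc - base$overlap_volume_cc) /
              base$overlap_volume_cc, 0.1)

  dil <- cone_overlap(build_direction_set(fx$cen, rec, 2,
                                          dilation_deg = 6), fx$cen, unc)
  expect_gte(dil$overlap_volume_cc, base$overlap_volume_cc)

  fine <- cone_overlap(build_direction_set(fx$cen, rec, 1), fx$cen, unc)
  expect_lt(abs(fine$overlap_volume_cc - base$overlap_volume_cc) /
              base$overlap_volume_cc, 0.1)
})

test_that("frame mapping rotates the direction set with the rigid rotation", {
  fx <- cone_fixture()
  # recurrence along +x in the recurrence frame; uncovered cap along the
  # direction that maps to +x under the post->recur rotation
  rec_x <- fx$mk(function(p) {
    a <- fx$ang(p)
    d <- sweep(p, 2, fx$cen, "-")
    a$r >= 20 & a$r <= 26 & d[, 1] / pmax(a$r, 1e-9) > 0.95
  })
  ds <- build_direction_set(fx$cen, rec_x, 2)
  rot <- rigid_transform(euler_rotation(rz = 60), c(5, 5, 5), fx$cen)
  # post-frame cap at R^-1 * (+x)
  dir_post <- as.vector(t(rot$rotation) %*% c(1, 0, 0))
  cap <- fx$mk(function(p) {
    d <- sweep(p, 2, fx$cen, "-")
    r <- sqrt(rowSums(d^2))
    r >= 8 & r <= 12 & (d %*% dir_post) / pmax(r, 1e-9) > 0.95
  })
  hit <- cone_overlap(ds, fx$cen, cap, rot)
  expect_true(hit$overlap)
  expect_gt(hit$overlap_volume_cc / mask_volume_cc(cap), 0.9)
  miss <- cone_overlap(ds, fx$cen, cap)   # identity rigid: should miss
  expect_false(miss$overlap)
})
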