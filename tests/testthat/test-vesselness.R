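make_tube_case <- function(with_blob = FALSE, noise_sd = 10) {
  n <- 64L
  g <- image_volume(array(FALSE, c(n, n, n)), 1, c(0, 0, 0))
  pts <- voxel_centers(g)
  cen <- rep(32, 3)
  liver <- image_volume(array(rowSums(sweep(pts, 2, cen, "-")^2) <= 28^2,
                              c(n, n, n)), 1, c(0, 0, 0))
  d2seg <- function(p, a, b) {
    ab <- b - a
    t <- pmin(pmax(sweep(p, 2, a, "-") %*% ab / sum(ab^2), 0), 1)
    rowSums((p - sweep(t %*% t(ab), 2, a, "+"))^2)
  }
  tube <- image_volume(array(d2seg(pts, c(12, 32, 32), c(52, 32, 36)) <= 4,
                             c(n, n, n)), 1, c(0, 0, 0))
  blob <- image_volume(array(rowSums(sweep(pts, 2, c(32, 20, 32), "-")^2) <=
                               100, c(n, n, n)), 1, c(0, 0, 0))
  img <- array(100, c(n, n, n))
  img[tube$data] <- 200
  if (with_blob) img[blob$data] <- 200
  set.seed(99)
  img <- img + rnorm(n^3, sd = noise_sd)
  list(volume = image_volume(img, 1, c(0, 0, 0)), liver = liver,
       tube = tube, blob = blob)
}

test_that("a uniform liver yields no vessels", {
  cs <- make_tube_case()
  set.seed(4)
  flat <- image_volume(array(100 + rnorm(64^3, sd = 5), c(64, 64, 64)),
                       1, c(0, 0, 0))
  expect_equal(sum(segment_vessels(flat, cs$liver)$data), 0)
  expect_error(segment_vessels(flat, image_volume(
    array(FALSE, c(64, 64, 64)), 1, c(0, 0, 0))), "empty")
})

test_that("a bright tube is segmented and localized", {
  cs <- make_tube_case()
  v <- segment_vessels(cs$volume, cs$liver)
  expect_gte(dice_coef(v$data, cs$tube$data & cs$liver$data), 0.5)
  dmap <- distance_map(cs$tube)
  expect_gte(mean(dmap$data[v$data] <= 2), 0.9)
})

test_that("vesselness is invariant to the absolute intensity scale", {
  cs <- make_tube_case()
  v1 <- segment_vessels(cs$volume, cs$liver)
  v2 <- segment_vessels(image_volume(cs$volume$data * 4.2, 1, c(0, 0, 0)),
                        cs$liver)
  expect_identical(v1$data, v2$data)
})

test_that("the interior of a bright blob is suppressed", {
  # an eigenvalue filter cannot reject the blob's edge-inflection shell
  # (its signature there equals a tube's); the interior must stay silent
  cs <- make_tube_case(with_blob = TRUE)
  v <- segment_vessels(cs$volume, cs$liver)
  interior <- erode_mask(cs$blob, 4)
  expect_lt(sum(v$data & interior$data) / max(sum(v$data), 1), 0.1)
  # the tube is still recovered alongside the blob
  expect_gte(dice_coef(v$data & !cs$blob$data,
                       cs$tube$data & cs$liver$data & !cs$blob$data), 0.5)
})

test_that("focused registration is exact for identical frames", {
  case <- small_phantom()
  pv <- segment_vessels(case$post$volume, case$post$masks$liver)
  tf <- focused_vessel_registration(pv, pv, case$post$masks$ablation,
                                    case$post$masks$ablation)
  expect_lt(sqrt(sum(tf$translation^2)), 0.2)
  expect_lt(rotation_angle_deg(tf), 0.2)
})

test_that("sparse vasculature raises the documented condition", {
  case <- small_phantom()
  pv <- segment_vessels(case$post$volume, case$post$masks$liver)
  tiny <- image_volume(array(FALSE, dim(pv$data)), pv$spacing, pv$origin)
  tiny$data[30:32, 30:32, 30] <- TRUE    # 9 voxels
  cnd <- tryCatch(
    focused_vessel_registration(tiny, pv, case$post$masks$ablation,
                                case$post$masks$ablation),
    insufficient_vasculature = function(e) e)
  expect_s3_class(cnd, "insufficient_vasculature")
  expect_equal(cnd$n_post, 9L)
  expect_gt(cnd$n_recur, 200)
})

test_that("a wide sphere of interest beats a narrow one when perivascular
          tissue near the cavity is sparse", {
  # vessels only far from the ablation: the 50 mm sphere sees too few
  spec <- phantom_spec(
    seed = 8L, grid_shape = c(96L, 96L, 96L), spacing = 1.25,
    deformation = list(amplitude = 0), noise_sd = 5,
    gtv = list(center = c(88, 62, 58), radius = 6),
    ablation = list(offset = c(0, 0, 0), radius = 10),
    vessels = list(
      list(from = c(27, 48, 52), to = c(37, 56, 55), radius = 2.5),
      list(from = c(29, 58, 50), to = c(36, 50, 58), radius = 2),
      list(from = c(28, 52, 58), to = c(38, 60, 52), radius = 2)))
  case <- generate_phantom(spec)
  pv <- segment_vessels(case$post$volume, case$post$masks$liver)
  rv <- segment_vessels(case$recur$volume, case$recur$masks$liver)
  err_of <- function(radius) {
    tf <- focused_vessel_registration(
      pv, rv, case$post$masks$ablation, case$recur$masks$ablation_shrunk,
      focused_reg_params(sphere_radius = radius))
    p0 <- mask_centroid(case$post$masks$ablation)
    sqrt(sum((apply_rigid(tf, p0) - apply_rigid(case$truth$rigid, p0))^2)) +
      rotation_angle_deg(tf$rotation %*% t(case$truth$rigid$rotation))
  }
  e50 <- tryCatch(err_of(50), insufficient_vasculature = function(e) Inf)
  e75 <- err_of(75)
  expect_lte(e75, e50)
  expect_lt(e75, 2)
})
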