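all_liver <- function(n = 48L) {
  image_volume(array(TRUE, c(n, n, n)), 1, c(0, 0, 0))
}

test_that("extrahepatic expansion follows its set definition", {
  liver <- all_liver()
  abl <- sphere_mask(9)
  # ablation deep inside the liver: nothing to add
  expect_identical(expand_outside_liver(abl, liver, 10)$data, abl$data)
  # zero expansion is the identity
  half <- predicate_mask(function(p) p[, 3] <= 23.5)
  abl_cap <- sphere_mask(5, center = c(23.5, 23.5, 19.5))
  expect_identical(expand_outside_liver(abl_cap, half, 0)$data,
                   abl_cap$data)
  expect_error(expand_outside_liver(abl, liver, -1), ">= 0")

  adj <- expand_outside_liver(abl_cap, half, 10)
  added <- adj$data & !abl_cap$data
  pts_added <- voxel_centers(adj, added)
  # added voxels lie outside the liver only ...
  expect_true(all(pts_added[, 3] > 23.5))
  # ... and within the dilation of the original ablation
  dmap <- distance_map(abl_cap)
  expect_true(all(dmap$data[added] <= 10 + 0.5))
  # inside the liver nothing changed
  expect_identical(adj$data & half$data, abl_cap$data & half$data)
})

test_that("concentric and overlapping spheres follow the margin convention", {
  liver <- all_liver()
  gtv <- sphere_mask(5)
  abl <- sphere_mask(9)
  m <- min_margin(gtv, abl, liver)
  expect_lt(abs(m$min_margin - 4), 1)
  expect_equal(m$pct_gtv_outside, 0)
  expect_gt(min(m$margin_samples), 0)

  gtv_off <- sphere_mask(5, center = c(29.5, 23.5, 23.5))
  m2 <- min_margin(gtv_off, abl, liver)
  expect_equal(m2$min_margin, 0)
  expect_gt(m2$pct_gtv_outside, 0)

  expect_error(min_margin(image_volume(array(FALSE, c(48, 48, 48)), 1,
                                       c(0, 0, 0)), abl, liver), "empty")
})

test_that("margin equals the brute-force surface-pair oracle", {
  liver <- all_liver()
  set.seed(21)
  # irregular blobby masks: union of random spheres
  rnd_blob <- function(k, rmax) {
    m <- array(FALSE, c(48, 48, 48))
    g <- image_volume(m, 1, c(0, 0, 0))
    pts <- voxel_centers(g)
    for (i in seq_len(k)) {
      c0 <- runif(3, 18, 30)
      r0 <- runif(1, 4, rmax)
      m <- m | array(rowSums(sweep(pts, 2, c0, "-")^2) <= r0^2, dim(m))
    }
    image_volume(m, 1, c(0, 0, 0))
  }
  for (rep in 1:3) {
    gtv <- rnd_blob(2, 6)
    abl <- dilate_mask(rnd_blob(3, 8), 4)
    if (!any(gtv$data)) next
    m <- min_margin(gtv, abl, liver, margin_params(10, 5))
    brute <- brute_margin(gtv, abl, liver, 10)
    expect_lt(abs(m$min_margin - min(brute)), sqrt(3) + 1e-9)
    expect_lt(max(abs(sort(m$margin_samples) - sort(brute))), sqrt(3))
  }
})

test_that("subcapsular expansion case matches its oracle and is monotone", {
  half <- predicate_mask(function(p) p[, 3] <= 23.5)
  gtv <- sphere_mask(3, center = c(23.5, 23.5, 20.5))
  abl <- sphere_mask(5, center = c(23.5, 23.5, 18.5))
  m_raw <- min_margin(gtv, abl, half, margin_params(0, 5))
  m_exp <- min_margin(gtv, abl, half, margin_params(10, 5))
  expect_equal(m_raw$min_margin, min(brute_margin(gtv, abl, half, 0)))
  expect_equal(m_exp$min_margin, min(brute_margin(gtv, abl, half, 10)))
  expect_gte(m_exp$min_margin, m_raw$min_margin)
})

test_that("enlarging the ablation never worsens any margin quantity", {
  liver <- all_liver()
  gtv <- sphere_mask(5)
  abl <- sphere_mask(8, center = c(25.5, 23.5, 23.5))
  abl_big <- dilate_mask(abl, 2)
  m1 <- min_margin(gtv, abl, liver)
  m2 <- min_margin(gtv, abl_big, liver)
  expect_gte(m2$min_margin, m1$min_margin)
  expect_lte(m2$pct_gtv_outside, m1$pct_gtv_outside)
  expect_lte(m2$cc_gtv_outside, m1$cc_gtv_outside)
  expect_lte(sum(m2$uncovered_region$data), sum(m1$uncovered_region$data))
})

test_that("GTV-outside-ablation percentages and volumes", {
  liver <- all_liver()
  gtv <- sphere_mask(5)
  expect_equal(gtv_outside_ablation(gtv, sphere_mask(9)),
               list(pct = 0, cc = 0))
  far <- sphere_mask(5, center = c(5.5, 5.5, 5.5))
  out <- gtv_outside_ablation(far, sphere_mask(9))
  expect_equal(out$pct, 100)
  expect_equal(out$cc, mask_volume_cc(far))

  cube <- predicate_mask(function(p)
    abs(p[, 1] - 23) <= 9.8 & abs(p[, 2] - 23.5) <= 9.8 &
      abs(p[, 3] - 23.5) <= 9.8)
  halfspace <- predicate_mask(function(p) p[, 1] <= 23)
  res <- gtv_outside_ablation(cube, halfspace)
  expect_lt(abs(res$pct - 50), 3)
  expect_lt(abs(res$cc - mask_volume_cc(cube) / 2), 0.3)
  # cc and pct are consistent
  expect_equal(res$cc, res$pct * mask_volume_cc(cube) / 100,
               tolerance = 1e-9)
})

test_that("uncovered intended-margin region: empty, shell and subcapsular", {
  liver <- all_liver()
  gtv <- sphere_mask(5)
  expect_equal(sum(uncovered_margin_region(gtv, sphere_mask(12), liver,
                                           5)$data), 0)
  shell <- uncovered_margin_region(gtv, sphere_mask(8), liver, 5)
  ana <- 4 / 3 * pi * (10^3 - 8^3) / 1000
  expect_lt(abs(mask_volume_cc(shell) - ana) / ana, 0.05)

  half <- predicate_mask(function(p) p[, 3] <= 23.5)
  gtv_cap <- sphere_mask(3, center = c(23.5, 23.5, 20.5))
  big_abl <- predicate_mask(function(p)
    rowSums(sweep(p, 2, c(23.5, 23.5, 20.5), "-")^2) <= 81 & p[, 3] <= 23.5)
  expect_equal(sum(uncovered_margin_region(gtv_cap, big_abl, half,
                                           5)$data), 0)
})
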