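test_that("phantom generation is deterministic and validates its spec", {
  spec <- phantom_spec(seed = 11L, grid_shape = c(48L, 48L, 48L),
                       spacing = 2, noise_sd = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$pre$volume$data, b$pre$volume$data)
  expect_identical(a$recur$masks$recurrence$data, b$recur$masks$recurrence$data)

  expect_error(phantom_spec(shrink_factor = 0), "shrink_factor")
  expect_error(phantom_spec(spacing = -1), "spacing")
  # gtv partially outside the liver
  expect_error(phantom_spec(gtv = list(center = c(200, 200, 200))),
               "inside the liver")
})

test_that("zero-amplitude warp gives the identity case", {
  spec <- phantom_spec(seed = 3L, grid_shape = c(48L, 48L, 48L), spacing = 2,
                       deformation = list(amplitude = 0), noise_sd = 0)
  case <- generate_phantom(spec)
  expect_true(all(case$truth$dvf$v == 0))
  expect_identical(case$pre$masks$liver$data, case$post$masks$liver$data)
  expect_identical(case$pre$masks$vessels$data, case$post$masks$vessels$data)
})

test_that("truth warp maps the pre liver onto the post liver", {
  case <- small_phantom()
  expect_gt(case$truth$min_jacobian, 0)
  warped <- propagate_contour(case$pre$masks$liver, case$truth$dvf,
                              "forward", case$post$masks$liver)
  expect_gte(dice_coef(warped, case$post$masks$liver), 0.97)
})

test_that("masks share geometry and stay inside the liver", {
  case <- small_phantom()
  for (tp in c("pre", "post", "recur")) {
    for (m in case[[tp]]$masks)
      expect_true(same_geometry(m, case[[tp]]$volume))
  }
  expect_true(all(case$pre$masks$gtv$data <= case$pre$masks$liver$data))
  expect_true(all(case$pre$masks$vessels$data <= case$pre$masks$liver$data))
})

test_that("recurrence-frame vessels are the post vessels under truth_rigid", {
  case <- small_phantom()
  moved <- propagate_contour(case$post$masks$vessels, case$truth$rigid,
                             "forward", case$recur$masks$vessels)
  expect_gte(dice_coef(moved, case$recur$masks$vessels), 0.80)
})

test_that("ablation shrinkage is a centroid-preserving volume contraction", {
  abl <- sphere_mask(10, n = 48L)
  expect_identical(simulate_ablation_shrinkage(abl, 1)$data, abl$data)
  expect_error(simulate_ablation_shrinkage(abl, 0), "shrink_factor")

  sh <- simulate_ablation_shrinkage(abl, 0.63)
  ratio <- sum(sh$data) / sum(abl$data)
  expect_lt(abs(ratio - 0.63), 0.63 * 0.02)
  # radius contracts by the cube root of the volume factor
  r_eff <- (3 * sum(sh$data) / (4 * pi))^(1 / 3)
  expect_lt(abs(r_eff - 10 * 0.63^(1 / 3)), 0.2)
  expect_lt(max(abs(mask_centroid(sh) - mask_centroid(abl))), 0.5)

  cube <- predicate_mask(function(p)
    abs(p[, 1] - 23.5) <= 10 & abs(p[, 2] - 23.5) <= 10 &
      abs(p[, 3] - 23.5) <= 10)
  half <- simulate_ablation_shrinkage(cube, 0.5)
  expect_lt(abs(sum(half$data) / sum(cube$data) - 0.5), 0.03)
})

test_that("shrunken recurrence-frame cavity matches the shrink factor", {
  case <- small_phantom()
  # compare in-frame: move the post cavity into the recurrence frame first
  moved <- propagate_contour(case$post$masks$ablation, case$truth$rigid,
                             "forward", case$recur$masks$ablation_shrunk)
  ratio <- sum(case$recur$masks$ablation_shrunk$data) / sum(moved$data)
  expect_lt(abs(ratio - case$spec$shrink_factor), 0.05)
})
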