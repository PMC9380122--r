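#' Specification of a synthetic liver phantom
#'
#' Defines the geometry, deformation and imaging parameters of a synthetic
#' three-time-point case (pre-treatment, post-ablation, recurrence) with
#' analytically known ground truth: a superellipsoid liver containing a
#' spherical tumor (GTV), an ablation zone overlapping the tumor, tubular
#' vessels, a smooth nonrigid pre-to-post warp, a rigid post-to-recurrence
#' offset, and isotropic ablation-cavity shrinkage at recurrence time
#' (default volume ratio 0.63, i.e. a 37\% cavity-volume decrease).
#'
#' Intensities are piecewise-constant tissue classes (background -1000,
#' liver 100, vessels 200, ablation 40, tumor 60) plus Gaussian noise.
#'
#' @param seed integer RNG seed; the phantom is bit-identical for a fixed
#'   seed.
#' @param grid_shape voxel counts per axis.
#' @param spacing voxel spacing in mm (scalar or length 3; anisotropy
#'   supported).
#' @param liver list: \code{center} (mm; default grid center),
#'   \code{semiaxes} (mm), \code{exponent} (superellipsoid exponent).
#' @param gtv list: \code{center} (mm; default offset from liver center),
#'   \code{radius} (mm).
#' @param ablation list: \code{offset} (mm, applied to the warped GTV center
#'   in the post frame), \code{radius} (mm), or explicit \code{center}.
#' @param vessels list of segments, each \code{list(from, to, radius)} in mm;
#'   defaults to three tubes spanning the liver.
#' @param deformation list: \code{amplitude} (max displacement, mm) and
#'   \code{scale} (control-grid spacing / smoothness, mm).
#' @param rigid_offset list: \code{translation} (mm), \code{angle_deg}
#'   (rotation about z through the liver center); the post-to-recurrence
#'   motion.
#' @param recurrence list: \code{radius} (mm) and unit \code{direction}
#'   (post-frame; default toward the thinnest margin).
#' @param shrink_factor ablation-cavity volume ratio at recurrence, in (0,1].
#' @param noise_sd intensity noise standard deviation.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(seed = 1L,
                         grid_shape = c(96L, 96L, 96L),
                         spacing = 1,
                         liver = list(),
                         gtv = list(),
                         ablation = list(),
                         vessels = NULL,
                         deformation = list(),
                         rigid_offset = list(),
                         recurrence = list(),
                         shrink_factor = 0.63,
                         noise_sd = 10) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("invalid spec: spacing must be > 0")
  if (shrink_factor <= 0 || shrink_factor > 1)
    stop("invalid spec: shrink_factor must be in (0, 1]")
  extent <- (grid_shape - 1) * spacing
  cen <- extent / 2
  liver <- modifyList(list(center = cen, semiaxes = c(38, 33, 28),
                           exponent = 2.2,
                           lobe = list(center_offset = c(-28, 16, 5),
                                       semiaxes = c(16, 13, 12))), liver)
  gtv <- modifyList(list(center = liver$center + c(12, 5, 3), radius = 8),
                    gtv)
  ablation <- modifyList(list(center = NULL, offset = c(2, 0, 0),
                              radius = 13), ablation)
  if (is.null(vessels)) vessels <- default_vessel_tree(liver)
  deformation <- modifyList(list(amplitude = 8, scale = 48), deformation)
  rigid_offset <- modifyList(list(translation = c(2.31, 2.31, 2.31),
                                  angle_deg = 3), rigid_offset)
  recurrence <- modifyList(list(radius = 5, direction = NULL), recurrence)
  spec <- structure(list(seed = as.integer(seed), grid_shape = grid_shape,
                         spacing = spacing, liver = liver, gtv = gtv,
                         ablation = ablation, vessels = vessels,
                         deformation = deformation,
                         rigid_offset = rigid_offset,
                         recurrence = recurrence,
                         shrink_factor = shrink_factor,
                         noise_sd = noise_sd),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

inside_superellipsoid <- function(pts, center, semiaxes, exponent) {
  u <- abs(sweep(sweep(pts, 2, center, "-"), 2, semiaxes, "/"))
  rowSums(u^exponent) <= 1
}

# Deterministic branching vasculature: a portal-like tree entering
# inferiorly and a hepatic-venous-like tree converging superiorly, with
# tapering radii, plus one lobe branch -- the vessel density a portal-venous
# contrast CT shows, which gray-level and vessel-focused registration rely
# on. Coordinates are fractions of the main-body semi-axes.
default_vessel_tree <- function(liver) {
  lc <- liver$center
  sa <- liver$semiaxes
  seg <- function(f0, f1, r) list(from = lc + f0 * sa, to = lc + f1 * sa,
                                  radius = r)
  p0 <- c(0, -0.10, -0.15)     # portal bifurcation
  h0 <- c(0, -0.05, 0.55)      # hepatic confluence
  vessels <- list(
    # portal tree
    seg(c(0.10, -0.55, -0.50), p0, 3.0),
    seg(p0, c(0.55, 0.25, -0.10), 2.2),
    seg(p0, c(-0.50, 0.20, -0.25), 2.2),
    seg(c(0.28, 0.08, -0.12), c(0.45, -0.30, 0.30), 1.6),
    seg(c(-0.25, 0.05, -0.20), c(-0.45, -0.35, 0.15), 1.6),
    seg(c(0.40, 0.18, -0.10), c(0.30, 0.55, 0.10), 1.5),
    # hepatic-venous tree
    seg(h0, c(0, 0.02, 0.78), 3.0),
    seg(h0, c(0.50, 0.15, 0.15), 2.0),
    seg(h0, c(-0.45, 0.10, 0.10), 2.0),
    seg(h0, c(0.10, 0.45, 0.20), 2.0),
    seg(c(0.25, 0.08, 0.35), c(0.45, -0.25, 0.45), 1.5),
    seg(c(-0.22, 0.05, 0.32), c(-0.40, -0.28, 0.42), 1.5))
  if (!is.null(liver$lobe))
    vessels <- c(vessels, list(
      list(from = lc + liver$lobe$center_offset + c(8, -4, -3),
           to = lc + liver$lobe$center_offset + c(-4, 2, 3), radius = 1.8)))
  vessels
}

# liver = main superellipsoid body plus an offset smaller lobe; the union is
# rotationally asymmetric, as a liver is, which anchors gray-level rigid
# registration
inside_liver <- function(pts, liver) {
  inside <- inside_superellipsoid(pts, liver$center, liver$semiaxes,
                                  liver$exponent)
  if (!is.null(liver$lobe))
    inside <- inside | inside_superellipsoid(
      pts, liver$center + liver$lobe$center_offset, liver$lobe$semiaxes,
      liver$exponent)
  inside
}

inside_sphere <- function(pts, center, radius) {
  rowSums(sweep(pts, 2, center, "-")^2) <= radius^2
}

# squared distance from points to a segment
dist2_segment <- function(pts, a, b) {
  ab <- b - a
  t <- pmin(pmax(sweep(pts, 2, a, "-") %*% ab / sum(ab^2), 0), 1)
  foot <- sweep(t %*% t(ab), 2, a, "+")
  rowSums((pts - foot)^2)
}

inside_vessels <- function(pts, vessels) {
  inside <- rep(FALSE, nrow(pts))
  for (v in vessels)
    inside <- inside | dist2_segment(pts, v$from, v$to) <= v$radius^2
  inside
}

validate_phantom_spec <- function(spec) {
  # deterministic direction sampling on the unit sphere
  n <- 200
  i <- seq_len(n)
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  margin <- spec$deformation$amplitude + 1
  gp <- sweep(dirs * spec$gtv$radius, 2, spec$gtv$center, "+")
  if (!all(inside_superellipsoid(
        gp, spec$liver$center,
        pmax(spec$liver$semiaxes - margin, 1), spec$liver$exponent)))
    stop("invalid spec: gtv does not lie entirely inside the liver ",
         "(with room for the deformation)")
  for (v in spec$vessels) {
    for (tt in seq(0, 1, length.out = 9)) {
      p <- v$from + tt * (v$to - v$from)
      sp <- sweep(dirs * v$radius, 2, p, "+")
      if (!all(inside_liver(sp, spec$liver)))
        stop("invalid spec: vessels must lie inside the liver")
    }
  }
  invisible(spec)
}

# cubic B-spline kernel (support 4 cells) and its derivative
bspline3 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, (4 - 6 * ax^2 + 3 * ax^3) / 6,
         ifelse(ax < 2, (2 - ax)^3 / 6, 0))
}

bspline3_d <- function(x) {
  ax <- abs(x)
  s <- sign(x)
  s * ifelse(ax < 1, (-12 * ax + 9 * ax^2) / 6,
             ifelse(ax < 2, -3 * (2 - ax)^2 / 6, 0))
}

# evaluate a control-grid scalar field (or its first derivative along one
# axis, deriv in 0..3) on fine axis coordinates via separable cubic kernels
tensor_bspline <- function(ctrl, ctrl_axes, fine_axes, deriv = 0L) {
  W <- lapply(1:3, function(a) {
    h <- diff(ctrl_axes[[a]][1:2])
    if (deriv == a)
      outer(fine_axes[[a]], ctrl_axes[[a]],
            function(x, c) bspline3_d((x - c) / h) / h)
    else
      outer(fine_axes[[a]], ctrl_axes[[a]],
            function(x, c) bspline3((x - c) / h))
  })
  arr <- ctrl
  for (a in 1:3) {
    d <- dim(arr)
    perm <- c(a, setdiff(1:3, a))
    m <- matrix(aperm(arr, perm), nrow = d[a])
    res <- W[[a]] %*% m
    arr <- aperm(array(res, c(nrow(W[[a]]), d[perm][2:3])), order(perm))
  }
  arr
}

# Smooth random warp as the curl of a random vector potential on the
# control grid: div v = 0 analytically, so local volume is preserved to
# first order -- liver deformation between scans is nearly isochoric (the
# same physics the elastic model's Poisson ratio 0.45 encodes).
make_warp_field <- function(spec) {
  amp <- spec$deformation$amplitude
  sc <- spec$deformation$scale
  extent <- (spec$grid_shape - 1) * spec$spacing
  fine_axes <- lapply(1:3, function(a)
    (seq_len(spec$grid_shape[a]) - 1) * spec$spacing[a])
  v <- array(0, c(spec$grid_shape, 3))
  if (amp > 0) {
    ctrl_axes <- lapply(1:3, function(a)
      seq(-2 * sc, extent[a] + 2 * sc, by = sc))
    nc <- vapply(ctrl_axes, length, 1L)
    pot <- array(rnorm(prod(nc) * 3), c(nc, 3))
    dA <- function(comp, axis)
      tensor_bspline(array(pot[, , , comp], nc), ctrl_axes, fine_axes,
                     deriv = axis)
    v[, , , 1] <- dA(3, 2) - dA(2, 3)
    v[, , , 2] <- dA(1, 3) - dA(3, 1)
    v[, , , 3] <- dA(2, 1) - dA(1, 2)
    vmax <- max(sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2))
    if (vmax > 0) v <- v * (amp / vmax)
  }
  v
}

# smallest Jacobian determinant of x + v(x) by central differences
min_jacobian_det <- function(v, spacing) {
  d <- dim(v)[1:3]
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  g <- function(c, a) {
    if (a == 1) (v[ix + 1, iy, iz, c] - v[ix - 1, iy, iz, c]) / (2 * spacing[1])
    else if (a == 2) (v[ix, iy + 1, iz, c] - v[ix, iy - 1, iz, c]) / (2 * spacing[2])
    else (v[ix, iy, iz + 1, c] - v[ix, iy, iz - 1, c]) / (2 * spacing[3])
  }
  a11 <- 1 + g(1, 1); a12 <- g(1, 2); a13 <- g(1, 3)
  a21 <- g(2, 1); a22 <- 1 + g(2, 2); a23 <- g(2, 3)
  a31 <- g(3, 1); a32 <- g(3, 2); a33 <- 1 + g(3, 3)
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  min(det)
}

#' Generate a synthetic three-time-point ablation case
#'
#' Builds pre-treatment, post-ablation and recurrence-time volumes and masks
#' with analytically known ground truth. The pre-to-post deformation is a
#' smooth displacement field from a coarse control grid (cubic kernels); the
#' ground-truth field at pre-grid voxel centers is stored as
#' \code{truth$dvf}. The recurrence frame is the post frame under a known
#' rigid offset (\code{truth$rigid}, mapping post to recurrence) with the
#' ablation cavity isotropically shrunk by \code{shrink_factor} and a
#' spherical recurrence lesion adjacent to the cavity.
#'
#' @param spec a \code{phantom_spec}.
#' @return object of class \code{phantom_case}: lists \code{pre},
#'   \code{post}, \code{recur} (each \code{volume} plus \code{masks}), and
#'   \code{truth} (\code{dvf}, \code{rigid}, \code{gtv_post},
#'   \code{min_jacobian}).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  d <- spec$grid_shape
  sp <- spec$spacing
  geom <- image_volume(array(FALSE, d), sp, c(0, 0, 0))
  pts <- voxel_centers(geom)

  # ground-truth pre -> post displacement field on the pre grid
  v <- make_warp_field(spec)
  if (spec$deformation$amplitude > 0) {
    mj <- min_jacobian_det(v, sp)
    if (mj <= 0)
      stop("invalid spec: warp folds (Jacobian determinant <= 0)")
  } else mj <- 1
  roi <- array(TRUE, d)
  dvf <- displacement_field(v, sp, c(0, 0, 0), roi)

  masks_from_points <- function(p) {
    list(liver = inside_liver(p, spec$liver),
         gtv = inside_sphere(p, spec$gtv$center, spec$gtv$radius),
         vessels = inside_vessels(p, spec$vessels))
  }
  as_mask <- function(x) image_volume(array(x, d), sp, c(0, 0, 0))

  pre_in <- masks_from_points(pts)
  pre_masks <- list(liver = as_mask(pre_in$liver),
                    gtv = as_mask(pre_in$gtv & pre_in$liver),
                    vessels = as_mask(pre_in$vessels & pre_in$liver))

  # post frame: voxel y corresponds to pre position x with x + v(x) = y
  x_post <- if (spec$deformation$amplitude > 0)
    invert_dvf_points(dvf, pts, tol = 0.01, maxit = 100) else pts
  post_in <- masks_from_points(x_post)
  gtv_center_post <- spec$gtv$center +
    as.vector(sample_dvf(dvf, matrix(spec$gtv$center, 1)))
  abl_center <- if (!is.null(spec$ablation$center)) spec$ablation$center
    else gtv_center_post + spec$ablation$offset
  post_abl <- inside_sphere(pts, abl_center, spec$ablation$radius)
  post_masks <- list(liver = as_mask(post_in$liver),
                     ablation = as_mask(post_abl & post_in$liver),
                     vessels = as_mask(post_in$vessels & post_in$liver))
  gtv_post <- as_mask(post_in$gtv & post_in$liver)

  # recurrence frame: post frame under the rigid offset, shrunken cavity
  truth_rigid <- rigid_transform(
    euler_rotation(rz = spec$rigid_offset$angle_deg),
    spec$rigid_offset$translation, spec$liver$center)
  x_rec_in_post <- apply_rigid(invert_rigid(truth_rigid), pts)
  rec_in <- masks_from_points(
    if (spec$deformation$amplitude > 0)
      invert_dvf_points(dvf, x_rec_in_post, tol = 0.01, maxit = 100)
    else x_rec_in_post)
  r_shrunk <- spec$ablation$radius * spec$shrink_factor^(1 / 3)
  rec_abl <- inside_sphere(x_rec_in_post, abl_center, r_shrunk)
  dir_rec <- spec$recurrence$direction
  if (is.null(dir_rec)) {
    dir_rec <- gtv_center_post - abl_center
    if (sqrt(sum(dir_rec^2)) < 1e-6) dir_rec <- c(0, 0, 1)
  }
  dir_rec <- dir_rec / sqrt(sum(dir_rec^2))
  rec_center_post <- abl_center +
    dir_rec * (r_shrunk + 0.6 * spec$recurrence$radius)
  rec_lesion <- inside_sphere(x_rec_in_post, rec_center_post,
                              spec$recurrence$radius)
  recur_masks <- list(liver = as_mask(rec_in$liver),
                      ablation_shrunk = as_mask(rec_abl & rec_in$liver),
                      recurrence = as_mask(rec_lesion & rec_in$liver),
                      vessels = as_mask(rec_in$vessels & rec_in$liver))

  render <- function(masks, classes) {
    img <- array(-1000, d)
    for (nm in names(classes)) img[masks[[nm]]$data] <- classes[[nm]]
    img + array(rnorm(prod(d), sd = spec$noise_sd), d)
  }
  pre_vol <- image_volume(render(
    list(liver = pre_masks$liver, gtv = pre_masks$gtv,
         vessels = pre_masks$vessels),
    c(liver = 100, gtv = 60, vessels = 200)), sp, c(0, 0, 0))
  post_vol <- image_volume(render(
    list(liver = post_masks$liver, ablation = post_masks$ablation,
         vessels = post_masks$vessels),
    c(liver = 100, ablation = 40, vessels = 200)), sp, c(0, 0, 0))
  recur_vol <- image_volume(render(
    list(liver = recur_masks$liver,
         ablation_shrunk = recur_masks$ablation_shrunk,
         recurrence = recur_masks$recurrence,
         vessels = recur_masks$vessels),
    c(liver = 100, ablation_shrunk = 40, recurrence = 60, vessels = 200)),
    sp, c(0, 0, 0))

  structure(list(
    pre = list(volume = pre_vol, masks = pre_masks),
    post = list(volume = post_vol, masks = post_masks),
    recur = list(volume = recur_vol, masks = recur_masks),
    truth = list(dvf = dvf, rigid = truth_rigid, gtv_post = gtv_post,
                 ablation_center = abl_center,
                 recurrence_direction = dir_rec,
                 min_jacobian = mj),
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case> grid %s, warp %.1f mm, shrink %.2f, seed %d\n",
    paste(x$spec$grid_shape, collapse = "x"),
    x$spec$deformation$amplitude, x$spec$shrink_factor, x$spec$seed))
  invisible(x)
}

#' Simulate post-ablation cavity shrinkage
#'
#' Centroid-preserving isotropic contraction of a binary mask: the mask is
#' rescaled about its centroid by \code{shrink_factor^(1/3)} so that the
#' volume ratio equals \code{shrink_factor} (cavity volumes decrease by
#' about 37\% between the post-ablation and recurrence scans; factor 0.63).
#'
#' @param ablation_mask logical \code{image_volume}.
#' @param shrink_factor volume ratio in (0, 1].
#' @return shrunken mask on the same grid.
#' @export
simulate_ablation_shrinkage <- function(ablation_mask, shrink_factor) {
  if (shrink_factor <= 0 || shrink_factor > 1)
    stop("shrink_factor must be in (0, 1]")
  if (shrink_factor == 1) return(ablation_mask)
  cen <- mask_centroid(ablation_mask)
  s <- shrink_factor^(1 / 3)
  pts <- voxel_centers(ablation_mask)
  src <- sweep(sweep(pts, 2, cen, "-") / s, 2, cen, "+")
  # sample the interpolated signed distance of the mask rather than the
  # binary labels: sub-voxel surface placement keeps the volume ratio
  # accurate to well under the voxelization tolerance
  m <- ablation_mask$data
  d_in <- sqrt(cpp_edt_sq(as.logical(!m), dim(m), ablation_mask$spacing))
  d_out <- sqrt(cpp_edt_sq(as.logical(m), dim(m), ablation_mask$spacing))
  sdf <- image_volume(array(d_in - d_out, dim(m)), ablation_mask$spacing,
                      ablation_mask$origin)
  vals <- sample_trilinear(sdf, src, fill = -1e6)
  # small positive threshold: the interpolated EDT zero level sits slightly
  # outside the voxel set's surface (calibrated on analytic spheres)
  image_volume(array(vals > 0.1 * mean(ablation_mask$spacing), dim(m)),
               ablation_mask$spacing, ablation_mask$origin)
}
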