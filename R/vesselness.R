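#' Vesselness-segmentation parameters
#'
#' @param scales Gaussian scales in mm (approximate tube radii), positive
#'   ascending; default \code{c(1, 2, 3)}.
#' @param response_threshold fraction of the maximum tubularity response
#'   (inside the liver) kept as vessel, in (0, 1); default 0.25.
#' @param min_component_voxels connected components smaller than this are
#'   discarded; default 50.
#' @return object of class \code{vesselness_params}.
#' @export
vesselness_params <- function(scales = c(1, 2, 3), response_threshold = 0.25,
                              min_component_voxels = 50L) {
  if (any(scales <= 0) || is.unsorted(scales))
    stop("scales must be positive ascending")
  if (response_threshold <= 0 || response_threshold >= 1)
    stop("response_threshold must be in (0, 1)")
  structure(list(scales = scales, response_threshold = response_threshold,
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "vesselness_params")
}

# Gaussian (derivative) kernel taps, order 0/1/2, sigma in voxels
deriv_kernel <- function(sigma_vox, order) {
  r <- max(2L, ceiling(4 * sigma_vox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  switch(order + 1L,
         g,
         -x / sigma_vox^2 * g,
         (x^2 - sigma_vox^2) / sigma_vox^4 * g)
}

# separable Gaussian-derivative filter with per-axis derivative orders;
# output in physical units (1/mm^order per axis)
gaussian_filter3 <- function(vol, sigma_mm, orders) {
  arr <- vol$data
  storage.mode(arr) <- "double"
  for (a in 1:3) {
    sv <- sigma_mm / vol$spacing[a]
    k <- deriv_kernel(sv, orders[a])
    arr <- if (orders[a] == 0) conv_axis(arr, k, a)
           else conv_axis_raw(arr, k, a) / vol$spacing[a]^orders[a]
  }
  arr
}

# eigenvalues of a field of symmetric 3x3 matrices, ordered |l1|<=|l2|<=|l3|
# (closed-form trigonometric method, fully vectorized)
sym_eigen3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  ok <- p > 1e-12
  b11 <- ifelse(ok, (a11 - q) / p, 0)
  b22 <- ifelse(ok, (a22 - q) / p, 0)
  b33 <- ifelse(ok, (a33 - q) / p, 0)
  b12 <- ifelse(ok, a12 / p, 0)
  b13 <- ifelse(ok, a13 / p, 0)
  b23 <- ifelse(ok, a23 / p, 0)
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  # sort by absolute value (3-element bubble, vectorized)
  e <- cbind(l1, l2, l3)
  for (pass in 1:2) for (c in 1:2) {
    sw <- abs(e[, c]) > abs(e[, c + 1])
    tmp <- e[sw, c]
    e[sw, c] <- e[sw, c + 1]
    e[sw, c + 1] <- tmp
  }
  e
}

#' Multiscale Hessian vesselness segmentation of liver vasculature
#'
#' Computes a Frangi-style tubularity response (bright tubes on a darker
#' background) from the eigenvalues of the scale-normalized image Hessian at
#' each scale, takes the maximum over scales, thresholds it at
#' \code{response_threshold} times the maximum response inside the liver,
#' and removes small connected components. The response is normalized per
#' volume, so the result is invariant to the absolute intensity scale.
#'
#' @param volume \code{image_volume}.
#' @param liver_mask mask on the same grid (nonempty).
#' @param params \code{vesselness_params}.
#' @return vessel mask \code{image_volume} with attribute \code{response}.
#' @export
segment_vessels <- function(volume, liver_mask,
                            params = vesselness_params()) {
  stop_if_geometry_mismatch(volume, liver_mask)
  if (!any(liver_mask$data)) stop("empty liver mask")
  alpha <- 0.5; beta <- 0.5
  inliver <- liver_mask$data
  best <- array(0, dim(volume$data))
  for (s in params$scales) {
    hxx <- gaussian_filter3(volume, s, c(2, 0, 0)) * s^2
    hyy <- gaussian_filter3(volume, s, c(0, 2, 0)) * s^2
    hzz <- gaussian_filter3(volume, s, c(0, 0, 2)) * s^2
    hxy <- gaussian_filter3(volume, s, c(1, 1, 0)) * s^2
    hxz <- gaussian_filter3(volume, s, c(1, 0, 1)) * s^2
    hyz <- gaussian_filter3(volume, s, c(0, 1, 1)) * s^2
    e <- sym_eigen3(as.vector(hxx), as.vector(hyy), as.vector(hzz),
                    as.vector(hxy), as.vector(hxz), as.vector(hyz))
    l1 <- e[, 1]; l2 <- e[, 2]; l3 <- e[, 3]
    S <- sqrt(l1^2 + l2^2 + l3^2)
    gam <- max(S[inliver]) / 2
    if (gam <= 0) next
    Ra <- abs(l2) / pmax(abs(l3), 1e-12)
    Rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), 1e-12)
    v <- (1 - exp(-Ra^2 / (2 * alpha^2))) * exp(-Rb^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * gam^2)))
    v[l2 > 0 | l3 > 0] <- 0   # bright-on-dark polarity
    best <- pmax(best, array(v, dim(best)))
  }
  best[!inliver] <- 0
  mx <- max(best)
  mask <- if (mx > 0) best >= params$response_threshold * mx
          else array(FALSE, dim(best))
  out <- image_volume(mask, volume$spacing, volume$origin)
  out <- drop_small_components(out, params$min_component_voxels)
  attr(out, "response") <- best
  out
}

# remove 6-connected components below a voxel-count threshold
drop_small_components <- function(mask, min_voxels) {
  if (!any(mask$data) || min_voxels <= 1) return(mask)
  m <- mask$data
  d <- dim(m)
  lab <- array(0L, d)
  cur <- 0L
  nxy <- d[1] * d[2]
  for (seed in which(m)) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      ai <- arrayInd(frontier, d)
      nb <- integer(0)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        aj <- ai
        aj[, ax] <- aj[, ax] + s
        ok <- aj[, ax] >= 1L & aj[, ax] <= d[ax]
        nb <- c(nb, aj[ok, 1] + d[1] * (aj[ok, 2] - 1L) + nxy * (aj[ok, 3] - 1L))
      }
      nb <- unique(nb)
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  image_volume(array(lab %in% keep & m, d), mask$spacing, mask$origin)
}

#' Focused-registration parameters
#'
#' @param sphere_radius radius (mm) of the sphere of interest centered on
#'   the ablation-zone centroid within which vasculature drives the
#'   registration; the investigated radii are 50, 75 and 100 mm and 75 mm is
#'   the default.
#' @param min_vessel_voxels smallest vessel-voxel count (within the sphere)
#'   for which automatic registration is attempted; below it the
#'   insufficient-vasculature condition is signalled so that a manually
#'   determined transform can be supplied instead.
#' @return object of class \code{focused_reg_params}.
#' @export
focused_reg_params <- function(sphere_radius = 75, min_vessel_voxels = 200L) {
  if (sphere_radius <= 0) stop("sphere_radius must be > 0")
  structure(list(sphere_radius = sphere_radius,
                 min_vessel_voxels = as.integer(min_vessel_voxels)),
            class = "focused_reg_params")
}

sphere_crop <- function(mask, center, radius) {
  pts <- voxel_centers(mask)
  inside <- rowSums(sweep(pts, 2, center, "-")^2) <= radius^2
  image_volume(array(mask$data & inside, dim(mask$data)),
               mask$spacing, mask$origin)
}

#' Sphere-of-interest rigid registration on liver vasculature
#'
#' Registers the post-ablation and recurrence frames using only the
#' segmented vessels inside spheres of interest centered on the two
#' ablation-zone centroids. The cropped vessel masks are Gaussian-smoothed
#' and the rigid transform maximizing their correlation is found by a
#' deterministic pattern search initialized at the centroid offset.
#'
#' If either sphere contains fewer than \code{params$min_vessel_voxels}
#' vessel voxels, a condition of class \code{insufficient_vasculature}
#' (carrying both counts) is signalled: the documented trigger for supplying
#' a manual registration.
#'
#' @param post_vessels,recur_vessels vessel masks in the two frames.
#' @param post_ablation_mask,recur_ablation_mask ablation masks defining the
#'   sphere centers.
#' @param params \code{focused_reg_params}.
#' @return a \code{rigid_transform} mapping post-frame positions to
#'   recurrence-frame positions.
#' @export
focused_vessel_registration <- function(post_vessels, recur_vessels,
                                        post_ablation_mask,
                                        recur_ablation_mask,
                                        params = focused_reg_params()) {
  cen_post <- mask_centroid(post_ablation_mask)
  cen_rec <- mask_centroid(recur_ablation_mask)
  crop_post <- sphere_crop(post_vessels, cen_post, params$sphere_radius)
  crop_rec <- sphere_crop(recur_vessels, cen_rec, params$sphere_radius)
  n_post <- sum(crop_post$data)
  n_rec <- sum(crop_rec$data)
  if (n_post < params$min_vessel_voxels || n_rec < params$min_vessel_voxels)
    stop(errorCondition(
      sprintf(paste0("insufficient vasculature within %.0f mm spheres ",
                     "(post: %d, recurrence: %d vessel voxels; need %d); ",
                     "supply a manual registration"),
              params$sphere_radius, n_post, n_rec,
              params$min_vessel_voxels),
      n_post = n_post, n_recur = n_rec,
      class = "insufficient_vasculature"))

  # two passes over decreasing smoothing: a wide basin first, then a
  # sharper correlation peak for sub-degree alignment
  supp <- dilate_mask(crop_post, 4)
  pts <- voxel_centers(supp, supp$data)
  t0 <- cen_rec - cen_post
  par <- c(t0, 0, 0, 0)
  for (sig in c(2, 1)) {
    sm_post <- gaussian_smooth(
      image_volume(crop_post$data * 1, crop_post$spacing,
                   crop_post$origin), sig)
    sm_rec <- gaussian_smooth(
      image_volume(crop_rec$data * 1, crop_rec$spacing, crop_rec$origin),
      sig)
    fv <- sample_trilinear(sm_post, pts)
    obj <- function(p) ncc_objective(fv, sm_rec, pts,
                                     param_to_rigid(p, cen_post))
    r <- pattern_search(obj, par, step_t = if (sig > 1) 2 else 0.5,
                        step_r = if (sig > 1) 2 else 0.5,
                        min_t = 0.02, min_r = 0.02)
    par <- r$par
  }
  tf <- param_to_rigid(par, cen_post)
  attr(tf, "ncc") <- r$value
  tf
}
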