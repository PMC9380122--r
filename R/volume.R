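#' Image volume container
#'
#' A minimal 3D scalar or binary voxel grid with physical geometry. All
#' geometry in the package is expressed in world millimetres: the voxel at
#' (1-based) index \code{(i, j, k)} has its center at
#' \code{origin + (c(i, j, k) - 1) * spacing}. Axis directions are the
#' identity (RAS-style axis-aligned grids).
#'
#' @param data 3D numeric or logical array.
#' @param spacing voxel spacing in mm (length 3, or scalar recycled).
#' @param origin world position (mm) of the center of voxel (1,1,1).
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  structure(list(data = data, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin %s mm, %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              if (is.logical(x$data)) sprintf("mask (%d on)", sum(x$data))
              else sprintf("range [%.3g, %.3g]", min(x$data), max(x$data))))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

vol_dims <- function(vol) dim(vol$data)

#' Voxel volume in mm^3
#' @param vol an \code{image_volume}.
#' @return scalar mm^3.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' Geometry equality check between two volumes
#' @param a,b \code{image_volume} objects.
#' @param tol tolerance in mm.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-3) {
  all(dim(a$data) == dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b))
    stop("geometry mismatch: volumes differ in dims, spacing or origin ",
         "beyond 1e-3 mm", call. = FALSE)
  invisible(TRUE)
}

#' Axis coordinate vectors (world mm) of a volume grid
#' @param vol an \code{image_volume}.
#' @return list of three numeric vectors (x, y, z voxel-center coordinates).
#' @export
grid_axes <- function(vol) {
  d <- vol_dims(vol)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' World coordinates of voxel centers
#'
#' @param vol an \code{image_volume}.
#' @param mask optional logical array (or mask volume) selecting voxels;
#'   default all voxels.
#' @return N x 3 matrix of world mm coordinates.
#' @export
voxel_centers <- function(vol, mask = NULL) {
  if (inherits(mask, "image_volume")) mask <- mask$data
  d <- vol_dims(vol)
  if (is.null(mask)) {
    idx <- arrayInd(seq_len(prod(d)), d)
  } else {
    idx <- which(mask, arr.ind = TRUE)
  }
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Trilinear sampling of a volume at world points
#'
#' @param vol an \code{image_volume} (numeric or logical data).
#' @param pts N x 3 matrix of world mm coordinates.
#' @param fill value returned outside the grid.
#' @return numeric vector of length N.
#' @export
sample_trilinear <- function(vol, pts, fill = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- vol_dims(vol)
  # continuous 0-based index
  u <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
  i0 <- floor(u)
  f <- u - i0
  inb <- u[, 1] >= 0 & u[, 2] >= 0 & u[, 3] >= 0 &
    u[, 1] <= d[1] - 1 & u[, 2] <= d[2] - 1 & u[, 3] <= d[3] - 1
  out <- rep(fill, nrow(pts))
  if (!any(inb)) return(out)
  i0 <- i0[inb, , drop = FALSE]
  f <- f[inb, , drop = FALSE]
  i1 <- pmin(i0 + 1, matrix(d - 1, nrow(i0), 3, byrow = TRUE))
  arr <- vol$data
  storage.mode(arr) <- "double"
  lin <- function(ix, iy, iz) arr[1 + ix + d[1] * (iy + d[2] * iz)]
  v <- (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) * lin(i0[, 1], i0[, 2], i0[, 3]) +
       f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) * lin(i1[, 1], i0[, 2], i0[, 3]) +
       (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) * lin(i0[, 1], i1[, 2], i0[, 3]) +
       f[, 1] * f[, 2] * (1 - f[, 3]) * lin(i1[, 1], i1[, 2], i0[, 3]) +
       (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] * lin(i0[, 1], i0[, 2], i1[, 3]) +
       f[, 1] * (1 - f[, 2]) * f[, 3] * lin(i1[, 1], i0[, 2], i1[, 3]) +
       (1 - f[, 1]) * f[, 2] * f[, 3] * lin(i0[, 1], i1[, 2], i1[, 3]) +
       f[, 1] * f[, 2] * f[, 3] * lin(i1[, 1], i1[, 2], i1[, 3])
  out[inb] <- v
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve a 3D array along one axis with a 1D kernel (renormalized at edges)
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  # band matrix with truncated-kernel renormalization at the boundaries
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    tgt <- idx + o
    ok <- tgt >= 1 & tgt <= n
    K[cbind(idx[ok], tgt[ok])] <- kernel[o + r + 1]
  }
  K <- K / rowSums(K)
  res <- K %*% m
  aperm(array(res, d[perm]), order(perm))
}

#' Gaussian smoothing of a volume (separable, edge-renormalized)
#'
#' @param vol an \code{image_volume}; logical data is treated as 0/1.
#' @param sigma_mm Gaussian standard deviation in mm (scalar or length 3).
#' @return smoothed \code{image_volume} (numeric).
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  sigma_mm <- rep_len(sigma_mm, 3L)
  arr <- vol$data
  storage.mode(arr) <- "double"
  for (a in 1:3)
    arr <- conv_axis(arr, gaussian_kernel_1d(sigma_mm[a] / vol$spacing[a]), a)
  image_volume(arr, vol$spacing, vol$origin)
}

# convolve along one axis without edge renormalization (for derivative
# kernels, whose taps sum to ~0); implicit zero padding
conv_axis_raw <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr * kernel)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    tgt <- idx + o
    ok <- tgt >= 1 & tgt <= n
    K[cbind(idx[ok], tgt[ok])] <- kernel[o + r + 1]
  }
  res <- K %*% m
  aperm(array(res, d[perm]), order(perm))
}

#' Dice similarity coefficient between two masks
#'
#' @param a,b logical arrays or mask \code{image_volume}s on the same grid.
#' @return DSC in [0, 1] (1 when both masks are empty).
#' @export
dice_coef <- function(a, b) {
  if (inherits(a, "image_volume")) a <- a$data
  if (inherits(b, "image_volume")) b <- b$data
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Mask volume in cubic centimetres
#' @param mask a logical \code{image_volume}.
#' @return volume in cc.
#' @export
mask_volume_cc <- function(mask) sum(mask$data) * voxel_volume_mm3(mask) / 1000

#' Binary dilation of a mask by a physical radius
#'
#' Uses the exact Euclidean distance transform, so the structuring element is
#' a true sphere in mm even on anisotropic grids. The distance transform
#' measures center-to-center distances; a quarter-voxel is added to the
#' radius to compensate for the half-voxel extent of the mask's own surface
#' (the Minkowski sum is taken with the voxel set, not its center cloud),
#' which makes dilated volumes of smooth shapes accurate to a few percent.
#' @param mask logical \code{image_volume}.
#' @param radius_mm dilation radius in mm (>= 0).
#' @return dilated mask volume.
#' @export
dilate_mask <- function(mask, radius_mm) {
  if (radius_mm < 0) stop("dilation radius must be >= 0")
  if (radius_mm == 0 || !any(mask$data)) return(mask)
  d2 <- cpp_edt_sq(as.logical(mask$data), dim(mask$data), mask$spacing)
  r_eff <- radius_mm + 0.25 * mean(mask$spacing)
  image_volume(array(d2 <= r_eff^2, dim(mask$data)),
               mask$spacing, mask$origin)
}

#' Binary erosion of a mask by a physical radius
#' @param mask logical \code{image_volume}.
#' @param radius_mm erosion radius in mm (>= 0).
#' @return eroded mask volume.
#' @export
erode_mask <- function(mask, radius_mm) {
  if (radius_mm < 0) stop("erosion radius must be >= 0")
  if (radius_mm == 0 || !any(mask$data)) return(mask)
  inv <- image_volume(!mask$data, mask$spacing, mask$origin)
  image_volume(mask$data & !dilate_mask(inv, radius_mm)$data,
               mask$spacing, mask$origin)
}

#' Euclidean distance map (mm) to a mask
#' @param mask logical \code{image_volume} (the feature set).
#' @return numeric \code{image_volume} of distances in mm (Inf if empty mask).
#' @export
distance_map <- function(mask) {
  d2 <- cpp_edt_sq(as.logical(mask$data), dim(mask$data), mask$spacing)
  image_volume(array(sqrt(d2), dim(mask$data)), mask$spacing, mask$origin)
}

# boundary voxels of a mask under 6-connectivity (member voxels with a
# non-member face neighbour, including the grid edge)
mask_boundary <- function(mask) {
  m <- mask$data
  d <- dim(m)
  shift <- function(a, ax, by) {
    out <- array(FALSE, dim(a))
    src <- dst <- lapply(dim(a), seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  interior <- m
  for (ax in 1:3) for (s in c(-1, 1))
    interior <- interior & shift(m, ax, s)
  image_volume(m & !interior, mask$spacing, mask$origin)
}

# largest 6-connected component of a mask
largest_component <- function(mask) {
  m <- mask$data
  d <- dim(m)
  lab <- array(0L, d)
  cur <- 0L
  idx_all <- which(m)
  if (length(idx_all) == 0) return(mask)
  nxy <- d[1] * d[2]
  neighbours <- function(ii) {
    ai <- arrayInd(ii, d)
    res <- integer(0)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      aj <- ai
      aj[, ax] <- aj[, ax] + s
      ok <- aj[, ax] >= 1L & aj[, ax] <= d[ax]
      res <- c(res, aj[ok, 1] + d[1] * (aj[ok, 2] - 1L) + nxy * (aj[ok, 3] - 1L))
    }
    res
  }
  for (seed in idx_all) {
    if (lab[seed] != 0L || !m[seed]) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      nb <- unique(neighbours(frontier))
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  image_volume(array(lab == keep, d), mask$spacing, mask$origin)
}
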