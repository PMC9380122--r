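#' Direction set of a recurrence in spherical coordinates
#'
#' Binary occupancy over an equiangular (theta, phi) grid: polar angle theta
#' in [0, 180] degrees from the world +z (superior) axis and azimuth phi in
#' [-180, 180) degrees from +x in the axial plane. One bin is occupied for
#' every recurrence voxel as seen from the ablation-zone centroid; the union
#' of the corresponding rays is the "cone" radiating from the centroid
#' through every point of the contoured recurrence: every bin overlapped by
#' a voxel's angular footprint (half a voxel across the line of sight) is
#' marked, not only the bin of the voxel-center direction. At the poles all phi
#' bins are merged (a direction at theta = 0 occupies the whole first theta
#' row). A voxel exactly on a bin edge belongs to the lower bin.
#'
#' @param centroid length-3 world point (mm): the ablation-zone centroid in
#'   the recurrence frame.
#' @param recurrence_mask nonempty mask \code{image_volume}.
#' @param bin_deg angular bin width in degrees (default 2).
#' @param dilation_deg optional angular dilation of the occupied set in
#'   degrees (default 0).
#' @return object of class \code{direction_set}: logical occupancy matrix
#'   (theta rows x phi columns) with attributes \code{bin_deg} and
#'   \code{skipped} (count of voxels coincident with the centroid, which
#'   have no defined direction and are skipped with a warning).
#' @export
build_direction_set <- function(centroid, recurrence_mask, bin_deg = 2,
                                dilation_deg = 0) {
  if (!any(recurrence_mask$data)) stop("empty recurrence mask")
  pts <- voxel_centers(recurrence_mask, recurrence_mask$data)
  d <- sweep(pts, 2, centroid, "-")
  len <- sqrt(rowSums(d^2))
  skipped <- sum(len < 1e-9)
  if (skipped > 0) {
    warning(skipped, " recurrence voxel(s) coincide with the centroid; ",
            "skipped (undefined direction)")
    d <- d[len >= 1e-9, , drop = FALSE]
    len <- len[len >= 1e-9]
  }
  # angular half-width subtended by each voxel (half a voxel across the
  # line of sight): the cone intersects every point of the voxel
  half_deg <- atan2(0.5 * mean(recurrence_mask$spacing), len) * 180 / pi
  occ <- direction_bins(d, len, bin_deg, half_deg)
  occ <- merge_poles(occ)
  if (dilation_deg > 0) occ <- dilate_direction_set(occ, bin_deg, dilation_deg)
  structure(occ, bin_deg = bin_deg, skipped = skipped,
            class = "direction_set")
}

# occupancy matrix from direction vectors (rows) and their norms.
# half_deg (per direction) is the angular half-width of the voxel footprint:
# the cone must intersect every point of a voxel, not just its center, so
# all bins overlapped by [theta +- half, phi +- half/sin(theta)] are marked.
direction_bins <- function(d, len, bin_deg, half_deg = NULL) {
  ntheta <- ceiling(180 / bin_deg)
  nphi <- ceiling(360 / bin_deg)
  theta <- acos(pmin(pmax(d[, 3] / len, -1), 1)) * 180 / pi
  phi <- atan2(d[, 2], d[, 1]) * 180 / pi       # [-180, 180]
  it <- pmin(floor(theta / bin_deg) + 1, ntheta)  # floor convention
  ip <- floor((phi + 180) / bin_deg) + 1
  ip[ip > nphi] <- 1                               # phi wrap-around
  occ <- matrix(FALSE, ntheta, nphi)
  if (is.null(half_deg)) {
    occ[cbind(it, ip)] <- TRUE
    return(occ)
  }
  # bins whose center lies inside the footprint interval (unbiased
  # quantization); the voxel's own bin is always marked
  sin_t <- pmax(sin(theta * pi / 180), 0.05)
  half_phi <- pmin(half_deg / sin_t, 15 * bin_deg)
  r0 <- pmax(ceiling((theta - half_deg) / bin_deg + 0.5), 1)
  r1 <- pmin(floor((theta + half_deg) / bin_deg + 0.5), ntheta)
  c0 <- ceiling((phi + 180 - half_phi) / bin_deg + 0.5)
  c1 <- floor((phi + 180 + half_phi) / bin_deg + 0.5)
  for (i in seq_along(it)) {
    occ[it[i], ip[i]] <- TRUE
    if (r1[i] < r0[i] || c1[i] < c0[i]) next
    cols <- ((c0[i]:c1[i]) - 1L) %% nphi + 1L
    occ[r0[i]:r1[i], cols] <- TRUE
  }
  occ
}

merge_poles <- function(occ) {
  if (any(occ[1, ])) occ[1, ] <- TRUE
  n <- nrow(occ)
  if (any(occ[n, ])) occ[n, ] <- TRUE
  occ
}

# binary dilation on the angular grid: square structuring element of
# radius ceiling(deg / bin) bins, phi wrap-around, theta clamped
dilate_direction_set <- function(occ, bin_deg, dilation_deg) {
  r <- ceiling(dilation_deg / bin_deg)
  nt <- nrow(occ); np <- ncol(occ)
  out <- occ
  for (dt in -r:r) for (dp in -r:r) {
    if (dt == 0 && dp == 0) next
    rows <- pmin(pmax(seq_len(nt) + dt, 1), nt)
    cols <- ((seq_len(np) - 1 + dp) %% np) + 1
    out <- out | occ[rows, cols, drop = FALSE]
  }
  merge_poles(out)
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("<direction_set> %dx%d bins (%g deg), %d occupied\n",
              nrow(x), ncol(x), attr(x, "bin_deg"), sum(x)))
  invisible(x)
}

#' Cone-tracing overlap between a recurrence and the uncovered margin
#'
#' Maps the recurrence direction set (built around the recurrence-frame
#' ablation centroid) onto the post-treatment ablation centroid and measures
#' which part of the uncovered-margin region lies inside the cone: an
#' uncovered voxel overlaps when its direction from the post-frame centroid,
#' rotated into the recurrence frame by the post-to-recurrence rigid
#' rotation, falls into an occupied bin. Translation plays no role for
#' directions.
#'
#' @param direction_set a \code{direction_set} built in the recurrence frame.
#' @param post_ablation_centroid length-3 point (mm) in the post frame.
#' @param uncovered_region_mask mask of the uncovered intended-margin region
#'   (post frame); may be empty (no overlap, not an error).
#' @param rigid_post_to_recur \code{rigid_transform} aligning the frames
#'   (identity if already aligned).
#' @return object of class \code{cone_result}: \code{overlap} (logical),
#'   \code{overlap_volume_cc}, \code{overlap_mask}.
#' @export
cone_overlap <- function(direction_set, post_ablation_centroid,
                         uncovered_region_mask,
                         rigid_post_to_recur = rigid_transform()) {
  bin_deg <- attr(direction_set, "bin_deg")
  d <- dim(uncovered_region_mask$data)
  overlap_arr <- array(FALSE, d)
  if (any(uncovered_region_mask$data)) {
    pts <- voxel_centers(uncovered_region_mask, uncovered_region_mask$data)
    dir <- sweep(pts, 2, post_ablation_centroid, "-")
    len <- sqrt(rowSums(dir^2))
    ok <- len > 1e-9
    # rotate post-frame directions into the recurrence frame
    dir <- dir %*% t(rigid_post_to_recur$rotation)
    hit <- rep(FALSE, nrow(pts))
    if (any(ok)) {
      ntheta <- nrow(direction_set)
      theta <- acos(pmin(pmax(dir[ok, 3] / len[ok], -1), 1)) * 180 / pi
      phi <- atan2(dir[ok, 2], dir[ok, 1]) * 180 / pi
      it <- pmin(floor(theta / bin_deg) + 1, ntheta)
      ip <- floor((phi + 180) / bin_deg) + 1
      ip[ip > ncol(direction_set)] <- 1
      hit[ok] <- direction_set[cbind(it, ip)]
    }
    lin <- which(uncovered_region_mask$data)
    overlap_arr[lin[hit]] <- TRUE
  }
  vol_cc <- sum(overlap_arr) *
    voxel_volume_mm3(uncovered_region_mask) / 1000
  structure(list(overlap = vol_cc > 0,
                 overlap_volume_cc = vol_cc,
                 overlap_mask = image_volume(
                   overlap_arr, uncovered_region_mask$spacing,
                   uncovered_region_mask$origin)),
            class = "cone_result")
}

#' @export
print.cone_result <- function(x, ...) {
  cat(sprintf("<cone_result> overlap: %s (%.2f cc)\n",
              if (x$overlap) "yes" else "no", x$overlap_volume_cc))
  invisible(x)
}
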