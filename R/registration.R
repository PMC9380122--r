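#' Dense displacement field on a reference grid
#'
#' Per-voxel 3-vectors (mm) on the pre-treatment liver region of interest,
#' with mapping direction \code{"pre->post"}: a position x on the pre grid
#' corresponds to x + v(x) in the post-treatment world frame. The field is
#' zero outside the ROI dilated by one support layer.
#'
#' @param v 4D array (nx, ny, nz, 3) of displacements in mm.
#' @param spacing,origin grid geometry (mm).
#' @param roi logical 3D array marking where the field is defined.
#' @param direction mapping direction tag.
#' @return object of class \code{displacement_field}.
#' @export
displacement_field <- function(v, spacing, origin, roi,
                               direction = "pre->post") {
  if (length(dim(v)) != 4L || dim(v)[4] != 3L)
    stop("v must be an (nx, ny, nz, 3) array")
  if (!all(is.finite(v))) stop("displacement field must be finite")
  structure(list(v = v, spacing = rep_len(as.numeric(spacing), 3L),
                 origin = rep_len(as.numeric(origin), 3L),
                 roi = roi, direction = direction),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$v, ncol = 3)^2))
  cat(sprintf("<displacement_field> %s grid, direction %s, |v| max %.2f mm\n",
              paste(dim(x$v)[1:3], collapse = "x"), x$direction, max(mag)))
  invisible(x)
}

#' Sample a displacement field at world points (trilinear)
#' @param field a \code{displacement_field}.
#' @param pts N x 3 matrix of world mm points.
#' @return N x 3 matrix of displacements (0 outside the grid).
#' @export
sample_dvf <- function(field, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3) {
    comp <- image_volume(array(field$v[, , , c], dim(field$v)[1:3]),
                         field$spacing, field$origin)
    out[, c] <- sample_trilinear(comp, pts, fill = 0)
  }
  out
}

# fixed-point inversion: find x with x + v(x) = y for each row of y.
# Query coordinates are clamped to the grid (nearest-edge extension) so the
# iteration map stays continuous at the field border.
invert_dvf_points <- function(field, y, tol = 0.05, maxit = 50) {
  d <- dim(field$v)[1:3]
  lo <- field$origin
  hi <- field$origin + (d - 1) * field$spacing
  clamp <- function(p) {
    for (c in 1:3) p[, c] <- pmin(pmax(p[, c], lo[c]), hi[c])
    p
  }
  x <- y
  active <- seq_len(nrow(y))
  for (it in seq_len(maxit)) {
    v <- sample_dvf(field, clamp(x[active, , drop = FALSE]))
    xn <- y[active, , drop = FALSE] - v
    err <- sqrt(rowSums((xn - x[active, , drop = FALSE])^2))
    x[active, ] <- xn
    active <- active[err >= tol]
    if (length(active) == 0) return(x)
  }
  stop("displacement-field inversion did not converge (", maxit,
       " iterations at ", tol, " mm)")
}

#' Centroid of a binary mask in world coordinates
#'
#' Unweighted mean of the world coordinates of member-voxel centers.
#' @param mask logical \code{image_volume} (nonempty).
#' @return length-3 world point (mm).
#' @export
mask_centroid <- function(mask) {
  if (!any(mask$data)) stop("empty mask")
  unname(colMeans(voxel_centers(mask, mask$data)))
}

# normalized cross-correlation of fixed-voxel values against the moving
# volume sampled at transformed positions
ncc_objective <- function(fixed_vals, moving, pts, tf) {
  mv <- sample_trilinear(moving, apply_rigid(tf, pts), fill = NA)
  ok <- !is.na(mv)
  if (sum(ok) < 10) return(-1)
  f <- fixed_vals[ok]; m <- mv[ok]
  sf <- stats::sd(f); sm <- stats::sd(m)
  if (sf == 0 || sm == 0) return(-1)
  stats::cor(f, m)
}

# deterministic coordinate pattern search over (tx, ty, tz, rx, ry, rz)
pattern_search <- function(objective, p0, step_t, step_r, min_t, min_r) {
  p <- p0
  best <- objective(p)
  st <- c(rep(step_t, 3), rep(step_r, 3))
  smin <- c(rep(min_t, 3), rep(min_r, 3))
  repeat {
    improved <- FALSE
    for (k in 1:6) for (s in c(1, -1)) {
      q <- p
      q[k] <- q[k] + s * st[k]
      val <- objective(q)
      if (val > best + 1e-12) {
        best <- val
        p <- q
        improved <- TRUE
      }
    }
    if (!improved) {
      if (all(st <= smin)) break
      st <- pmax(st / 2, smin)
    }
  }
  list(par = p, value = best)
}

param_to_rigid <- function(p, center) {
  rigid_transform(euler_rotation(p[4], p[5], p[6]), p[1:3], center)
}

# downsample a volume by an integer factor (block mean)
downsample_volume <- function(vol, factor) {
  d <- dim(vol$data)
  nd <- floor(d / factor)
  arr <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  storage.mode(arr) <- "double"
  dim(arr) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(arr, c(2, 4, 6), mean)
  image_volume(out, vol$spacing * factor,
               vol$origin + (factor - 1) / 2 * vol$spacing)
}

#' Automated gray-level rigid registration of two liver volumes
#'
#' Maximizes the normalized cross-correlation of the fixed liver ROI against
#' the moving volume, with a deterministic multi-resolution strategy:
#' centroid initialization, exhaustive coarse translation search on
#' 4x-downsampled volumes, then pattern-search refinement of translation and
#' rotation at increasing resolution.
#'
#' The returned transform maps fixed-frame anatomy positions to the
#' corresponding moving-frame positions.
#'
#' @param fixed_volume,moving_volume \code{image_volume}s.
#' @param fixed_liver_mask,moving_liver_mask nonempty mask volumes.
#' @param max_shift_mm half-width of the coarse translation search (mm).
#' @param window intensity clamp applied before correlation (a soft-tissue
#'   window): balances the organ/background edge against the internal
#'   vasculature, which carries the rotational information. \code{NULL}
#'   disables windowing.
#' @return a \code{rigid_transform} with attribute \code{ncc}.
#' @export
rigid_register <- function(fixed_volume, moving_volume, fixed_liver_mask,
                           moving_liver_mask, max_shift_mm = 12,
                           window = c(-50, 250)) {
  if (!any(fixed_liver_mask$data) || !any(moving_liver_mask$data))
    stop("empty mask")
  cen_f <- mask_centroid(fixed_liver_mask)
  cen_m <- mask_centroid(moving_liver_mask)
  t0 <- cen_m - cen_f

  clampv <- function(v) {
    if (is.null(window)) return(v)
    image_volume(pmin(pmax(v$data, window[1]), window[2]), v$spacing,
                 v$origin)
  }
  # the correlation ROI is the liver dilated by 6 mm: the organ/background
  # edge carries most of the gray-level signal, the vasculature refines it
  roi <- dilate_mask(fixed_liver_mask, 6)
  f_s <- gaussian_smooth(clampv(fixed_volume), 2)
  m_s <- gaussian_smooth(clampv(moving_volume), 2)

  f4 <- downsample_volume(f_s, 4L)
  m4 <- downsample_volume(m_s, 4L)
  msk4 <- downsample_volume(roi, 4L)
  pts4 <- voxel_centers(msk4, msk4$data > 0.25)
  fv4 <- sample_trilinear(f4, pts4)
  if (stats::sd(fv4) == 0) stop("flat correlation surface: constant image")

  # coarse exhaustive translation search
  step <- min(f4$spacing)
  offs <- seq(-max_shift_mm, max_shift_mm, by = step)
  best <- c(-Inf, 0, 0, 0)
  for (dz in offs) {
    # vectorize the inner two axes per dz to keep call count moderate
    for (dy in offs) for (dx in offs) {
      tf <- rigid_transform(diag(3), t0 + c(dx, dy, dz), cen_f)
      val <- ncc_objective(fv4, m4, pts4, tf)
      if (val > best[1]) best <- c(val, dx, dy, dz)
    }
  }
  t1 <- t0 + best[2:4]

  # refinement: rotation and translation, half resolution then full
  f2 <- downsample_volume(f_s, 2L)
  m2 <- downsample_volume(m_s, 2L)
  msk2 <- downsample_volume(roi, 2L)
  pts2 <- voxel_centers(msk2, msk2$data > 0.25)
  fv2 <- sample_trilinear(f2, pts2)
  obj2 <- function(p) ncc_objective(fv2, m2, pts2, param_to_rigid(p, cen_f))
  r2 <- pattern_search(obj2, c(t1, 0, 0, 0), step_t = 2, step_r = 2,
                       min_t = 0.1, min_r = 0.1)

  pts1 <- voxel_centers(roi, roi$data)
  if (nrow(pts1) > 40000) {
    keep <- seq(1, nrow(pts1), length.out = 40000)
    pts1 <- pts1[round(keep), , drop = FALSE]
  }
  fv1 <- sample_trilinear(f_s, pts1)
  obj1 <- function(p) ncc_objective(fv1, m_s, pts1,
                                    param_to_rigid(p, cen_f))
  r1 <- pattern_search(obj1, r2$par, step_t = 0.4, step_r = 0.4,
                       min_t = 0.02, min_r = 0.02)

  # final polish on the liver interior only: under deformation the organ
  # outline can mimic a rotation, while the internal gray-level structures
  # (vasculature) follow the material motion. Two passes with decreasing
  # smoothing sharpen the correlation peak.
  interior <- erode_mask(fixed_liver_mask, 8)
  if (sum(interior$data) >= 500) {
    ptsi <- voxel_centers(interior, interior$data)
    if (nrow(ptsi) > 30000) {
      keep <- seq(1, nrow(ptsi), length.out = 30000)
      ptsi <- ptsi[round(keep), , drop = FALSE]
    }
    fvi <- sample_trilinear(f_s, ptsi)
    obji <- function(p) ncc_objective(fvi, m_s, ptsi,
                                      param_to_rigid(p, cen_f))
    r1 <- pattern_search(obji, r1$par, step_t = 1, step_r = 1,
                         min_t = 0.05, min_r = 0.05)
    f_f <- gaussian_smooth(clampv(fixed_volume), 1)
    m_f <- gaussian_smooth(clampv(moving_volume), 1)
    fvf <- sample_trilinear(f_f, ptsi)
    objf <- function(p) ncc_objective(fvf, m_f, ptsi,
                                      param_to_rigid(p, cen_f))
    r1 <- pattern_search(objf, r1$par, step_t = 0.5, step_r = 0.5,
                         min_t = 0.02, min_r = 0.02)
  }
  tf <- param_to_rigid(r1$par, cen_f)
  attr(tf, "ncc") <- r1$value
  tf
}

#' Mean-curvature feature of a surface mesh
#'
#' Discrete mean-curvature estimate per vertex: the signed offset of the
#' vertex from its one-ring centroid along the outward vertex normal,
#' normalized by the mean squared edge length, Laplacian-smoothed over the
#' mesh. Used as a matching feature by
#' \code{\link{surface_correspondence}}: curvature patterns move with the
#' material and therefore carry tangential information that pure distance
#' does not.
#'
#' @param mesh a \code{surface_mesh}.
#' @param smooth_iters Laplacian smoothing sweeps of the raw estimate.
#' @return numeric vector (one value per vertex, units 1/mm).
#' @export
mesh_vertex_curvature <- function(mesh, smooth_iters = 3) {
  v <- mesh$vertices
  tr <- mesh$triangles
  nv <- nrow(v)
  # area-weighted outward vertex normals
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nv, 3)
  for (k in 1:3) for (c in 1:3)
    n[, c] <- n[, c] + unname(tapply(fn[, c], tr[, k], sum)[as.character(seq_len(nv))])
  n[is.na(n)] <- 0
  len <- sqrt(rowSums(n^2))
  n <- n / pmax(len, 1e-12)
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = 1, dims = c(nv, nv))
  A@x[] <- 1
  deg <- pmax(Matrix::rowSums(A), 1)
  cent <- as.matrix(A %*% v) / deg
  r2 <- as.numeric(Matrix::rowSums(A %*% (v^2)) / deg) - rowSums(cent^2) +
    rowSums((cent - v)^2)
  r2 <- pmax(r2, 1e-9)
  kappa <- 2 * rowSums(n * (v - cent)) / r2
  for (it in seq_len(smooth_iters))
    kappa <- as.numeric(A %*% kappa) / deg
  kappa
}

#' Surface correspondence between two liver meshes
#'
#' Maps every source-mesh vertex to a point on the target surface. The
#' initial guess is the closest point on the target; it is then refined by
#' relaxation: the displacement field is repeatedly replaced by its
#' neighborhood (Laplacian) average and the moved vertices are reprojected
#' onto the target surface. The reprojection uses a curvature-augmented
#' metric (geometric distance plus a penalty on the mismatch between the
#' source vertex's curvature and the target's), so that curvature landmarks
#' -- lobes, ridges, creases -- anchor the tangential component of the map,
#' which pure closest-point matching cannot see; the averaging propagates
#' that information across featureless regions.
#'
#' @param source,target watertight \code{surface_mesh}es of the same organ,
#'   already rigidly aligned.
#' @param relax_iters relaxation sweeps (default 150; 0 gives the plain
#'   closest-point correspondence).
#' @param feature_weight tangential pull of the curvature feature, in mm per
#'   standard deviation of the target's curvature distribution (0 disables
#'   feature matching).
#' @return \code{boundary_conditions} with one displacement per source
#'   vertex (node ids are source-vertex indices).
#' @export
surface_correspondence <- function(source, target, relax_iters = 300,
                                   feature_weight = 0) {
  bb_s <- apply(source$vertices, 2, range)
  bb_t <- apply(target$vertices, 2, range)
  if (any(bb_s[2, ] < bb_t[1, ]) || any(bb_t[2, ] < bb_s[1, ]))
    stop("mesh bounding boxes are disjoint; rigid alignment required first")
  nv <- nrow(source$vertices)
  use_feat <- feature_weight > 0 && relax_iters > 0
  if (use_feat) {
    ks <- mesh_vertex_curvature(source)
    kt <- mesh_vertex_curvature(target)
    mu <- mean(kt); sdv <- stats::sd(kt)
    if (sdv < 1e-9) use_feat <- FALSE else {
      ks <- (ks - mu) / sdv
      kt <- (kt - mu) / sdv
    }
  }
  proj_plain <- function(x)
    cpp_closest_point_mesh(x, target$vertices, target$triangles)$point
  proj <- if (use_feat) {
    function(x) cpp_closest_point_feature(x, ks, target$vertices, kt,
                                          target$triangles, feature_weight)$point
  } else proj_plain

  disp <- proj_plain(source$vertices) - source$vertices
  ed <- rbind(source$triangles[, 1:2], source$triangles[, 2:3],
              source$triangles[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]),
                            j = c(ed[, 2], ed[, 1]),
                            x = 1, dims = c(nv, nv))
  A@x[] <- 1  # duplicates collapsed; unit weights
  deg <- pmax(Matrix::rowSums(A), 1)
  for (it in seq_len(relax_iters)) {
    disp <- as.matrix(A %*% disp) / deg
    disp <- proj(source$vertices + disp) - source$vertices
  }
  # final plain projection guarantees the map lands on the target surface
  disp <- proj_plain(source$vertices + disp) - source$vertices
  boundary_conditions(seq_len(nv), disp)
}

#' Resample finite-element node displacements onto a voxel grid
#'
#' Barycentric interpolation of the solved node displacements at every voxel
#' center of the region of interest that lies inside the tetrahedral mesh;
#' ROI voxels just outside the mesh surface take the value at their closest
#' surface point.
#'
#' @param mesh the \code{tet_mesh} of the solve.
#' @param node_displacements N x 3 matrix from
#'   \code{\link{solve_linear_elastic}}.
#' @param roi_grid logical \code{image_volume}: the liver ROI defining the
#'   output grid and support.
#' @return a \code{displacement_field} on the ROI grid (direction
#'   \code{"pre->post"}).
#' @export
rasterize_dvf <- function(mesh, node_displacements, roi_grid) {
  support <- dilate_mask(roi_grid, max(roi_grid$spacing))
  pts <- voxel_centers(support, support$data)
  if (nrow(pts) == 0) stop("ROI grid disjoint from mesh")
  ip <- cpp_interp_tet(mesh$nodes, mesh$tets, node_displacements, pts)
  vals <- ip$values
  out_idx <- which(!ip$inside)
  if (length(out_idx)) {
    cp <- cpp_closest_point_mesh(pts[out_idx, , drop = FALSE], mesh$nodes,
                                 mesh$boundary_tris)
    tri_nodes <- mesh$boundary_tris[cp$tri, , drop = FALSE]
    for (c in 1:3)
      vals[out_idx, c] <-
        rowSums(cp$bary * cbind(node_displacements[tri_nodes[, 1], c],
                                node_displacements[tri_nodes[, 2], c],
                                node_displacements[tri_nodes[, 3], c]))
  }
  d <- dim(roi_grid$data)
  v <- array(0, c(d, 3))
  lin <- which(support$data)
  for (c in 1:3) {
    comp <- array(0, d)
    comp[lin] <- vals[, c]
    v[, , , c] <- comp
  }
  displacement_field(v, roi_grid$spacing, roi_grid$origin, support$data)
}

#' Propagate a contour (mask) through a rigid transform or displacement field
#'
#' Label structures are mapped through the surface-vertex pathway: the mask's
#' surface is extracted at voxel resolution, its vertices are moved through
#' the transform, and the moved surface is revoxelized on the target grid.
#' No intensity interpolation of labels takes place.
#'
#' @param mask logical \code{image_volume} (or a \code{surface_mesh}).
#' @param transform a \code{rigid_transform} or \code{displacement_field}.
#' @param direction \code{"forward"} maps pre-frame structures to the post
#'   frame; \code{"inverse"} maps post-frame structures back (for a
#'   displacement field this uses fixed-point inversion, tolerance 0.05 mm,
#'   at most 50 iterations).
#' @param target_grid \code{image_volume} supplying the output geometry.
#' @return mapped mask on \code{target_grid}.
#' @export
propagate_contour <- function(mask, transform, direction = c("forward", "inverse"),
                              target_grid) {
  direction <- match.arg(direction)
  if (inherits(mask, "surface_mesh")) {
    mesh <- mask
  } else {
    if (!any(mask$data)) stop("empty mask")
    fld <- mask$data
    storage.mode(fld) <- "double"
    res <- cpp_mesh_field(fld, dim(mask$data), mask$origin, mask$spacing, 0.5)
    sidx <- which(res$is_surface)
    remap <- integer(nrow(res$nodes))
    remap[sidx] <- seq_along(sidx)
    mesh <- structure(list(vertices = res$nodes[sidx, , drop = FALSE],
                           triangles = matrix(remap[res$tris], ncol = 3),
                           provenance = list(source = "mask")),
                      class = "surface_mesh")
  }
  vv <- mesh$vertices
  if (inherits(transform, "rigid_transform")) {
    tf <- if (direction == "forward") transform else invert_rigid(transform)
    vv <- apply_rigid(tf, vv)
  } else if (inherits(transform, "displacement_field")) {
    if (direction == "forward") {
      vv <- vv + sample_dvf(transform, vv)
    } else {
      vv <- invert_dvf_points(transform, vv)
    }
  } else stop("transform must be a rigid_transform or displacement_field")
  moved <- structure(list(vertices = vv, triangles = mesh$triangles,
                          provenance = mesh$provenance),
                     class = "surface_mesh")
  voxelize_mesh(moved, target_grid)
}

# polish a rigid transform on the gray levels within a sphere around a
# point of interest (intersected with the eroded liver)
refine_rigid_local <- function(fixed_volume, moving_volume, fixed_liver_mask,
                               rigid, center, radius, window = c(-50, 250)) {
  clampv <- function(v) image_volume(pmin(pmax(v$data, window[1]),
                                          window[2]), v$spacing, v$origin)
  er <- erode_mask(fixed_liver_mask, 4)
  pts <- voxel_centers(er, er$data)
  keep <- rowSums(sweep(pts, 2, center, "-")^2) <= radius^2
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 500) return(rigid)
  f_s <- gaussian_smooth(clampv(fixed_volume), 1.5)
  m_s <- gaussian_smooth(clampv(moving_volume), 1.5)
  fv <- sample_trilinear(f_s, pts)
  cen <- mask_centroid(fixed_liver_mask)
  R <- rigid$rotation
  p0 <- c(rigid$translation + as.vector((diag(3) - R) %*%
                                          (rigid$center - cen)),
          atan2(R[3, 2], R[3, 3]) * 180 / pi,
          asin(pmin(pmax(-R[3, 1], -1), 1)) * 180 / pi,
          atan2(R[2, 1], R[1, 1]) * 180 / pi)
  obj <- function(p) ncc_objective(fv, m_s, pts, param_to_rigid(p, cen))
  r <- pattern_search(obj, p0, step_t = 1, step_r = 1,
                      min_t = 0.02, min_r = 0.02)
  tf <- param_to_rigid(r$par, cen)
  attr(tf, "ncc") <- r$value
  tf
}

#' Biomechanical model-based deformable registration
#'
#' The full pipeline: gray-level rigid registration of the liver ROIs,
#' surface meshing of both livers, closest-point surface correspondence of
#' the rigidly aligned pre-treatment mesh onto the post-treatment mesh,
#' a linear-elastic finite-element solve on the pre-treatment liver volume
#' mesh with the total (rigid + residual) surface displacements imposed as
#' Dirichlet conditions, and resampling of the node displacements to a dense
#' field on the pre-treatment liver ROI. Because affine fields are exact in
#' the element space, imposing the total displacement in one solve is
#' equivalent to composing the rigid map with an elastic correction.
#'
#' @param pre_volume,post_volume \code{image_volume}s.
#' @param pre_liver,post_liver liver masks on the corresponding grids.
#' @param meshing \code{meshing_params}.
#' @param elastic \code{elastic_params}.
#' @param rigid optional precomputed \code{rigid_transform} (skips the
#'   gray-level registration stage).
#' @param focus optional mask (e.g. the tumor) around whose centroid the
#'   rigid alignment is additionally polished on local gray levels within
#'   \code{focus_radius}: the margin question is local, and a smooth organ
#'   deformation is locally close to rigid.
#' @param focus_radius radius (mm) of the local polish region.
#' @return list with \code{rigid} (pre -> post \code{rigid_transform}),
#'   \code{dvf} (total pre -> post \code{displacement_field}),
#'   \code{mesh} (the pre-liver \code{tet_mesh}),
#'   \code{node_displacements}, \code{surface_mesh_pre},
#'   \code{surface_mesh_post}.
#' @export
biomech_register <- function(pre_volume, pre_liver, post_volume, post_liver,
                             meshing = meshing_params(),
                             elastic = elastic_params(),
                             rigid = NULL, focus = NULL, focus_radius = 35) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.null(rigid)) {
    rigid <- stage("rigid_register",
                   rigid_register(pre_volume, post_volume, pre_liver,
                                  post_liver))
    if (!is.null(focus))
      rigid <- stage("rigid_register(focus)",
                     refine_rigid_local(pre_volume, post_volume, pre_liver,
                                        rigid, mask_centroid(focus),
                                        focus_radius))
  }
  mesh_pre <- stage("extract_surface_mesh(pre)",
                    extract_surface_mesh(pre_liver, meshing))
  mesh_post <- stage("extract_surface_mesh(post)",
                     extract_surface_mesh(post_liver, meshing))
  aligned <- structure(list(vertices = apply_rigid(rigid, mesh_pre$vertices),
                            triangles = mesh_pre$triangles,
                            provenance = mesh_pre$provenance),
                       class = "surface_mesh")
  corr <- stage("surface_correspondence",
                surface_correspondence(aligned, mesh_post))
  tm <- stage("build_tet_mesh", build_tet_mesh(mesh_pre))
  # total displacement at each pre-surface vertex: rigid motion plus the
  # residual correspondence displacement measured after rigid alignment
  total <- aligned$vertices + corr$displacements - mesh_pre$vertices
  bc <- boundary_conditions(tm$surface_vertex_ids, total)
  u <- stage("solve_linear_elastic", solve_linear_elastic(tm, bc, elastic))
  dvf <- stage("rasterize_dvf", rasterize_dvf(tm, u, pre_liver))
  list(rigid = rigid, dvf = dvf, mesh = tm, node_displacements = u,
       surface_mesh_pre = mesh_pre, surface_mesh_post = mesh_post)
}
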