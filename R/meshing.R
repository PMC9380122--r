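#' Mesh-creation parameters
#'
#' The two tunable parameters of liver surface meshing: the smoothing radius
#' applied to the binary mask before iso-surface extraction and the target
#' triangle edge length. The investigated grids are smoothing radii
#' \{1, 3, 5\} mm (default 1) and edge lengths \{3, 6, 9, 12\} mm (default 6),
#' but any positive values are accepted.
#'
#' @param smoothing_radius smoothing kernel radius in mm (> 0).
#' @param edge_length target mean triangle edge length in mm (> 0).
#' @return object of class \code{meshing_params}.
#' @export
meshing_params <- function(smoothing_radius = 1, edge_length = 6) {
  if (smoothing_radius <= 0 || edge_length <= 0)
    stop("smoothing_radius and edge_length must be > 0")
  structure(list(smoothing_radius = smoothing_radius,
                 edge_length = edge_length),
            class = "meshing_params")
}

# ratio of target edge length to extraction-grid spacing. The measured mean
# surface-edge / cell ratio of the Freudenthal extractor is 0.55-0.60;
# 0.65 is used so that default-parameter meshes of organ-scale smooth shapes
# also conserve enclosed volume to ~5% (inscribed-polyhedron sag ~ edge^2)
EDGE_PER_CELL <- 0.65

min_tet_volume <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  dets <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
          e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
          e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  min(dets) / 6
}

# project boundary nodes onto the surface, backing the step off (globally,
# deterministic) if it would invert an interior element; used identically by
# surface extraction and tetrahedralization so the two stay conforming
project_nodes_safely <- function(res, sdf, indicator, h) {
  sv <- which(res$is_surface)
  proj <- project_to_sdf(res$nodes, sdf, max_step = 0.45 * h, only = sv)
  proj <- project_to_sdf(proj, indicator, max_step = 0.45 * h, only = sv)
  # tangential relaxation with reprojection: equalizes the irregular
  # marching triangles (the reprojection cancels Laplacian shrinkage)
  nv <- nrow(res$nodes)
  ed <- rbind(res$tris[, 1:2], res$tris[, 2:3], res$tris[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = 1, dims = c(nv, nv))
  A@x[] <- 1
  deg <- pmax(Matrix::rowSums(A), 1)
  for (it in 1:3) {
    cent <- as.matrix(A %*% proj) / deg
    proj[sv, ] <- 0.5 * proj[sv, ] + 0.5 * cent[sv, ]
    proj <- project_to_sdf(proj, sdf, max_step = h, only = sv, iters = 2)
    proj <- project_to_sdf(proj, indicator, max_step = h, only = sv,
                           iters = 2)
  }
  cand <- proj
  for (scale in c(1, 0.5, 0.25, 0)) {
    cand <- res$nodes + scale * (proj - res$nodes)
    if (min_tet_volume(cand, res$tets) > 1e-9) break
  }
  cand
}

# Newton projection of vertices onto the zero level of a signed distance
# volume: x <- x - sdf(x) * grad/|grad|^2, step clamped to max_step. Central
# differences at half the native spacing estimate the gradient.
project_to_sdf <- function(nodes, sdf, max_step, only = NULL, iters = 3) {
  idx <- if (is.null(only)) seq_len(nrow(nodes)) else only
  if (length(idx) == 0) return(nodes)
  x <- nodes[idx, , drop = FALSE]
  eps <- sdf$spacing / 2
  for (it in seq_len(iters)) {
    f <- sample_trilinear(sdf, x, fill = 0)
    g <- matrix(0, nrow(x), 3)
    for (c in 1:3) {
      dp <- x; dp[, c] <- dp[, c] + eps[c]
      dm <- x; dm[, c] <- dm[, c] - eps[c]
      g[, c] <- (sample_trilinear(sdf, dp, fill = 0) -
                 sample_trilinear(sdf, dm, fill = 0)) / (2 * eps[c])
    }
    g2 <- pmax(rowSums(g^2), 2.5e-3)
    step <- -f / g2
    step <- pmin(pmax(step, -max_step), max_step)
    x <- x + g * step
  }
  nodes[idx, ] <- x
  nodes
}

#' Extract a triangulated surface mesh from a binary mask
#'
#' The mask (largest connected component) is Gaussian-smoothed with
#' sigma = smoothing_radius / 2, and the 0.5 iso-surface is extracted with
#' marching tetrahedra on a grid whose spacing is chosen so that the mean
#' triangle edge length matches \code{params$edge_length}. The resulting mesh
#' is closed, 2-manifold and consistently oriented (outward normals).
#'
#' @param mask logical \code{image_volume}; must be nonempty.
#' @param params a \code{meshing_params} object.
#' @return object of class \code{surface_mesh}: \code{vertices} (world mm),
#'   \code{triangles} (1-based index triples), \code{provenance}. Carries the
#'   implicit field used for extraction so that \code{\link{build_tet_mesh}}
#'   can build a conforming interior mesh.
#' @export
extract_surface_mesh <- function(mask, params = meshing_params()) {
  if (!inherits(mask, "image_volume")) stop("mask must be an image_volume")
  if (!any(mask$data)) stop("empty mask")
  mask <- largest_component(mask)
  ext_vox <- apply(which(mask$data, arr.ind = TRUE), 2, range)
  ext_mm <- (ext_vox[2, ] - ext_vox[1, ] + 1) * mask$spacing
  if (any(ext_mm < params$edge_length))
    stop("mask smaller than one edge length in some dimension")

  # smooth the binary mask, re-threshold, and build a signed distance field
  # (positive inside): its linearly interpolated zero level localizes the
  # smoothed surface to second order even on a coarse extraction grid.
  # sigma is floored at 0.7 voxels so the 0.5 level set is well resolved
  sigma <- pmax(params$smoothing_radius / 2, 0.7 * mask$spacing)
  smoothed <- gaussian_smooth(mask, sigma)
  msk_s <- smoothed$data >= 0.5
  if (!any(msk_s)) stop("mask vanishes under this smoothing radius")
  d_in <- sqrt(cpp_edt_sq(as.logical(!msk_s), dim(msk_s), mask$spacing))
  d_out <- sqrt(cpp_edt_sq(as.logical(msk_s), dim(msk_s), mask$spacing))
  sdf <- image_volume(array(d_in - d_out, dim(msk_s)), mask$spacing,
                      mask$origin)
  h <- params$edge_length / EDGE_PER_CELL
  pad <- 2 * h + params$smoothing_radius
  lo <- mask$origin + (ext_vox[1, ] - 1) * mask$spacing - pad
  hi <- mask$origin + (ext_vox[2, ] - 1) * mask$spacing + pad
  nc <- pmax(4L, ceiling((hi - lo) / h) + 1L)
  axc <- lapply(1:3, function(a) lo[a] + (seq_len(nc[a]) - 1) * h)
  pts <- as.matrix(expand.grid(axc[[1]], axc[[2]], axc[[3]]))
  fld <- array(sample_trilinear(sdf, pts, fill = -pad), nc)
  res <- cpp_mesh_field(fld, nc, lo, rep(h, 3), 0)
  # two-stage vertex refinement: the distance field pulls far vertices near
  # the surface (gradient ~ 1 everywhere); the smoothed indicator's 0.5
  # level then localizes it without the discrete-EDT voxel bias
  pfield <- image_volume(smoothed$data - 0.5, mask$spacing, mask$origin)
  res$nodes <- project_nodes_safely(res, sdf, pfield, h)
  if (nrow(res$tris) == 0)
    stop("iso-surface extraction produced no triangles; ",
         "edge_length too coarse for this mask")
  sidx <- which(res$is_surface)
  remap <- integer(nrow(res$nodes))
  remap[sidx] <- seq_along(sidx)
  mesh <- structure(list(
    vertices = res$nodes[sidx, , drop = FALSE],
    triangles = matrix(remap[res$tris], ncol = 3),
    provenance = list(params = params, mask_dim = dim(mask$data))),
    class = "surface_mesh")
  attr(mesh, "field") <- list(field = fld, dims = nc, origin = lo,
                              spacing = rep(h, 3), level = 0, sdf = sdf,
                              indicator = pfield, h = h)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, volume %.1f mm^3\n",
              nrow(x$vertices), nrow(x$triangles), mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed surface mesh (divergence theorem)
#' @param mesh a \code{surface_mesh}.
#' @return volume in mm^3 (positive for outward-oriented meshes).
#' @export
mesh_volume <- function(mesh) {
  v0 <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  v1 <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  v2 <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  sum(rowSums(v0 * cr)) / 6
}

#' Mean triangle edge length of a surface mesh
#' @param mesh a \code{surface_mesh}.
#' @return mean unique-edge length in mm.
#' @export
mean_edge_length <- function(mesh) {
  ed <- rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
              mesh$triangles[, c(3, 1)])
  ed <- t(apply(ed, 1, sort))
  ed <- unique(ed)
  mean(sqrt(rowSums((mesh$vertices[ed[, 1], , drop = FALSE] -
                     mesh$vertices[ed[, 2], , drop = FALSE])^2)))
}

#' Watertightness check
#'
#' A mesh is watertight and consistently oriented when every undirected edge
#' is used by exactly two triangles and every directed edge by exactly one.
#' @param mesh a \code{surface_mesh}.
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  dkey <- paste(ed[, 1], ed[, 2])
  if (any(duplicated(dkey))) return(FALSE)
  ukey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(ukey) == 2L)
}

#' Dice similarity between a surface mesh and a binary mask
#'
#' The mesh interior is voxelized on the mask's grid (a voxel belongs to the
#' mesh iff its center is inside the closed surface) and the Dice coefficient
#' 2|A n B| / (|A| + |B|) is computed against the mask.
#'
#' @param mesh a watertight \code{surface_mesh} in the mask's world frame.
#' @param mask logical \code{image_volume}.
#' @return Dice coefficient in [0, 1].
#' @export
mesh_mask_dice <- function(mesh, mask) {
  if (!is_watertight(mesh)) stop("mesh is not watertight (open surface)")
  vox <- voxelize_mesh(mesh, mask)
  dice_coef(vox$data, mask$data)
}

#' Voxelize a closed surface mesh onto a reference grid
#' @param mesh a watertight \code{surface_mesh}.
#' @param grid an \code{image_volume} supplying the target geometry.
#' @return logical mask \code{image_volume}.
#' @export
voxelize_mesh <- function(mesh, grid) {
  v <- cpp_voxelize_mesh(mesh$vertices, mesh$triangles, dim(grid$data),
                         grid$origin, grid$spacing)
  image_volume(array(v, dim(grid$data)), grid$spacing, grid$origin)
}

#' Select mesh-creation parameters by Dice against the source mask
#'
#' Runs surface extraction for every candidate parameter pair and scores each
#' mesh by \code{\link{mesh_mask_dice}} against the mask, mirroring
#' patient-by-patient parameter selection. Ties break toward the smaller edge
#' length, then the smaller smoothing radius.
#'
#' @param mask logical \code{image_volume}.
#' @param candidates data frame with columns \code{smoothing_radius} and
#'   \code{edge_length}; defaults to the investigated 3 x 4 grid.
#' @return list with \code{best} (a \code{meshing_params}) and \code{table}
#'   (per-candidate Dice, NA where meshing failed).
#' @export
select_mesh_params <- function(mask,
                               candidates = expand.grid(
                                 smoothing_radius = c(1, 3, 5),
                                 edge_length = c(3, 6, 9, 12))) {
  if (nrow(candidates) < 1) stop("need at least one candidate")
  dice <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    p <- meshing_params(candidates$smoothing_radius[i],
                        candidates$edge_length[i])
    dice[i] <- tryCatch(mesh_mask_dice(extract_surface_mesh(mask, p), mask),
                        error = function(e) NA_real_)
  }
  if (all(is.na(dice))) stop("all candidate parameter sets failed meshing")
  tab <- cbind(candidates, dice = dice)
  ord <- order(-dice, candidates$edge_length, candidates$smoothing_radius,
               na.last = TRUE)
  best <- ord[1]
  list(best = meshing_params(candidates$smoothing_radius[best],
                             candidates$edge_length[best]),
       table = tab)
}

#' Build a tetrahedral interior mesh conforming to a surface mesh
#'
#' Clips the background tetrahedral lattice used during surface extraction
#' against the same iso-surface, producing a positive-volume tetrahedral mesh
#' whose boundary faces are exactly the surface triangles: every surface
#' vertex is a boundary node (bijective map in \code{surface_vertex_ids}).
#'
#' @param surface a \code{surface_mesh} from \code{\link{extract_surface_mesh}}
#'   (carries its implicit extraction field).
#' @return object of class \code{tet_mesh}: \code{nodes} (mm),
#'   \code{tets} (1-based quadruples, positive signed volume),
#'   \code{boundary_node_ids}, \code{boundary_tris},
#'   \code{surface_vertex_ids} (node id of each surface vertex).
#' @export
build_tet_mesh <- function(surface) {
  fld <- attr(surface, "field")
  if (is.null(fld))
    stop("surface mesh carries no extraction field; ",
         "build_tet_mesh requires a mesh from extract_surface_mesh")
  res <- cpp_mesh_field(fld$field, fld$dims, fld$origin, fld$spacing,
                        fld$level)
  if (nrow(res$tets) == 0) stop("degenerate surface: no interior tetrahedra")
  if (!is.null(fld$sdf))
    res$nodes <- project_nodes_safely(res, fld$sdf, fld$indicator, fld$h)
  structure(list(nodes = res$nodes,
                 tets = res$tets,
                 boundary_node_ids = which(res$is_surface),
                 boundary_tris = res$tris,
                 surface_vertex_ids = which(res$is_surface)),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes (%d boundary), %d tets\n",
              nrow(x$nodes), length(x$boundary_node_ids), nrow(x$tets)))
  invisible(x)
}

#' Total volume of a tetrahedral mesh
#' @param tm a \code{tet_mesh}.
#' @return summed signed tet volume in mm^3.
#' @export
tet_mesh_volume <- function(tm) {
  a <- tm$nodes[tm$tets[, 1], , drop = FALSE]
  e1 <- tm$nodes[tm$tets[, 2], , drop = FALSE] - a
  e2 <- tm$nodes[tm$tets[, 3], , drop = FALSE] - a
  e3 <- tm$nodes[tm$tets[, 4], , drop = FALSE] - a
  dets <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
          e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
          e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  sum(dets) / 6
}
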