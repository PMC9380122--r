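# shared fixtures, memoized so expensive phantoms are built once per run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# voxelized sphere mask on an n^3 grid (spacing sp mm, origin 0)
sphere_mask <- function(r, n = 48L, sp = 1, center = NULL) {
  if (is.null(center)) center <- rep((n - 1) * sp / 2, 3)
  g <- image_volume(array(FALSE, c(n, n, n)), sp, c(0, 0, 0))
  pts <- voxel_centers(g)
  image_volume(array(rowSums(sweep(pts, 2, center, "-")^2) <= r^2,
                     c(n, n, n)), sp, c(0, 0, 0))
}

# mask from a predicate over world points
predicate_mask <- function(f, n = 48L, sp = 1) {
  g <- image_volume(array(FALSE, c(n, n, n)), sp, c(0, 0, 0))
  pts <- voxel_centers(g)
  image_volume(array(f(pts), c(n, n, n)), sp, c(0, 0, 0))
}

# the workhorse synthetic case: 64^3, 1.5 mm spacing, default 8 mm warp
small_phantom <- function() cached("phantom64", {
  generate_phantom(phantom_spec(seed = 1L, grid_shape = c(64L, 64L, 64L),
                                spacing = 1.5))
})

# study-scale case for registration recovery (80^3 at 1.25 mm)
study_phantom <- function() cached("phantom80", {
  generate_phantom(phantom_spec(seed = 1L, grid_shape = c(80L, 80L, 80L),
                                spacing = 1.25))
})

study_registration <- function() cached("reg80", {
  case <- study_phantom()
  biomech_register(case$pre$volume, case$pre$masks$liver,
                   case$post$volume, case$post$masks$liver,
                   focus = case$pre$masks$gtv)
})

# tet mesh of a 20 mm sphere at default meshing parameters
sphere_tet_mesh <- function() cached("tet_sphere", {
  build_tet_mesh(extract_surface_mesh(sphere_mask(20), meshing_params()))
})

# brute-force minimum distance between two surface-voxel point sets
brute_min_surface_distance <- function(pts_a, pts_b) {
  d2 <- outer(rowSums(pts_a^2), rep(1, nrow(pts_b))) -
    2 * pts_a %*% t(pts_b) +
    outer(rep(1, nrow(pts_a)), rowSums(pts_b^2))
  sqrt(pmax(d2, 0))
}

# brute-force margin oracle: per GTV-surface voxel, distance to the
# adjusted-ablation surface if encompassed, else 0
brute_margin <- function(gtv, ablation, liver, expansion) {
  adj <- expand_outside_liver(ablation, liver, expansion)
  gb <- ablmargin:::mask_boundary(gtv)
  gp <- voxel_centers(gb, gb$data)
  if (!any(adj$data)) return(rep(0, nrow(gp)))
  ab <- ablmargin:::mask_boundary(adj)
  ap <- voxel_centers(ab, ab$data)
  d <- brute_min_surface_distance(gp, ap)
  inside <- adj$data[gb$data]
  ifelse(inside, apply(d, 1, min), 0)
}
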