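#' Elastic material parameters for the biomechanical liver model
#'
#' The liver is modelled as a single homogeneous linear-elastic material with
#' a Young's modulus of 1000 Pa and a Poisson's ratio of 0.45 (soft,
#' nearly incompressible tissue). Under the pure-Dirichlet boundary
#' conditions used here the displacement solution is independent of the
#' Young's modulus; it only scales the stresses.
#'
#' @param young_modulus Young's modulus in Pa (> 0), default 1000.
#' @param poisson_ratio Poisson's ratio in [0, 0.5), default 0.45.
#' @return object of class \code{elastic_params}.
#' @export
elastic_params <- function(young_modulus = 1000, poisson_ratio = 0.45) {
  if (young_modulus <= 0) stop("young_modulus must be > 0")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must be in [0, 0.5)")
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio),
            class = "elastic_params")
}

#' Dirichlet boundary conditions on a tetrahedral mesh
#'
#' One prescribed displacement vector per boundary node.
#'
#' @param node_ids integer node indices (into the tet-mesh node table).
#' @param displacements N x 3 matrix of displacements in mm.
#' @return object of class \code{boundary_conditions}.
#' @export
boundary_conditions <- function(node_ids, displacements) {
  displacements <- matrix(as.numeric(displacements), ncol = 3)
  if (length(node_ids) != nrow(displacements))
    stop("one displacement per node required")
  if (anyDuplicated(node_ids))
    stop("each boundary node must have exactly one prescription")
  if (!all(is.finite(displacements)))
    stop("boundary displacements must be finite")
  structure(list(node_ids = as.integer(node_ids),
                 displacements = displacements),
            class = "boundary_conditions")
}

# assemble the global stiffness matrix for linear (P1) tetrahedral elements,
# homogeneous isotropic material (Lame parameters lambda, mu)
assemble_stiffness <- function(tm, lambda, mu) {
  nodes <- tm$nodes
  tets <- tm$tets
  M <- nrow(tets)
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  cross3 <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  detE <- rowSums(e1 * cross3(e2, e3))
  if (any(abs(detE) < 1e-12))
    stop("degenerate element: singular system")
  V <- detE / 6
  # rows of inv(E): gradients of barycentric coordinates of vertices 2..4
  r1 <- cross3(e2, e3) / detE
  r2 <- cross3(e3, e1) / detE
  r3 <- cross3(e1, e2) / detE
  # g[[a]][, i] = dN_a / dx_i for each tet (M x 3)
  g <- list(-(r1 + r2 + r3), r1, r2, r3)

  nT <- 144L * M
  ii <- integer(nT); jj <- integer(nT); xx <- numeric(nT)
  pos <- 0L
  for (av in 1:4) for (bv in 1:4) {
    ga <- g[[av]]; gb <- g[[bv]]
    dot <- rowSums(ga * gb)
    na <- tets[, av]; nb <- tets[, bv]
    for (i in 1:3) for (j in 1:3) {
      k <- V * (lambda * ga[, i] * gb[, j] + mu * ga[, j] * gb[, i] +
                (if (i == j) mu * dot else 0))
      idx <- pos + seq_len(M)
      ii[idx] <- 3L * (na - 1L) + i
      jj[idx] <- 3L * (nb - 1L) + j
      xx[idx] <- k
      pos <- pos + M
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(3 * nrow(nodes), 3 * nrow(nodes)))
}

#' Solve static linear elasticity with prescribed boundary displacements
#'
#' Assembles linear tetrahedral elements for a homogeneous isotropic
#' material and solves the equilibrium equations (no body force) with the
#' boundary displacements imposed as Dirichlet conditions. Rigid-body and
#' affine boundary data are reproduced exactly (constant-strain fields are
#' in the P1 space), and the solution is invariant to the Young's modulus
#' because the problem is purely Dirichlet.
#'
#' @param mesh a \code{tet_mesh}.
#' @param bc \code{boundary_conditions} covering every boundary node of
#'   \code{mesh}.
#' @param params \code{elastic_params}.
#' @return N x 3 matrix of node displacements (mm), with attribute
#'   \code{residual}: the relative algebraic residual of the interior solve.
#' @export
solve_linear_elastic <- function(mesh, bc, params = elastic_params()) {
  if (!inherits(mesh, "tet_mesh")) stop("mesh must be a tet_mesh")
  if (!setequal(bc$node_ids, mesh$boundary_node_ids))
    stop("boundary conditions must cover exactly the boundary nodes")
  E <- params$young_modulus
  nu <- params$poisson_ratio
  mu <- E / (2 * (1 + nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  K <- assemble_stiffness(mesh, lambda, mu)

  n <- nrow(mesh$nodes)
  u <- matrix(0, n, 3)
  u[bc$node_ids, ] <- bc$displacements
  bdof <- as.vector(t(outer(3 * (bc$node_ids - 1), 1:3, "+")))
  ub <- as.vector(t(bc$displacements))
  idof <- setdiff(seq_len(3 * n), bdof)
  if (length(idof)) {
    rhs <- -K[idof, bdof, drop = FALSE] %*% ub
    Kii <- K[idof, idof, drop = FALSE]
    ui <- tryCatch(Matrix::solve(Kii, rhs),
                   error = function(e) stop("singular system: ", e$message))
    res <- sqrt(sum((Kii %*% ui - rhs)^2))
    den <- sqrt(sum(rhs^2))
    rel <- if (den > 0) res / den else res
    full <- numeric(3 * n)
    full[bdof] <- ub
    full[idof] <- as.numeric(ui)
    u <- matrix(full, n, 3, byrow = TRUE)
  } else rel <- 0
  attr(u, "residual") <- rel
  u
}
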