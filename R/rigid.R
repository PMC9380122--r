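#' Rigid transform (rotation about a center plus translation)
#'
#' Maps a world point x to \code{rotation \%*\% (x - center) + center +
#' translation}. Used with the convention that the transform carries
#' fixed-frame anatomy coordinates into the moving frame.
#'
#' @param rotation 3 x 3 rotation matrix (det +1).
#' @param translation length-3 translation in mm.
#' @param center length-3 rotation center in mm.
#' @return object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation,
                 translation = rep_len(as.numeric(translation), 3L),
                 center = rep_len(as.numeric(center), 3L)),
            class = "rigid_transform")
}

#' Rotation matrix from extrinsic XYZ Euler angles (degrees)
#' @param rx,ry,rz rotations about the world x, y, z axes in degrees,
#'   applied in that order (R = Rz Ry Rx).
#' @return 3 x 3 rotation matrix.
#' @export
euler_rotation <- function(rx = 0, ry = 0, rz = 0) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#' @param tf a \code{rigid_transform}.
#' @param pts N x 3 matrix of world mm points.
#' @return transformed N x 3 matrix.
#' @export
apply_rigid <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, tf$center, "-") %*% t(tf$rotation), 2,
        tf$center + tf$translation, "+")
}

#' Invert a rigid transform
#' @param tf a \code{rigid_transform}.
#' @return the inverse \code{rigid_transform} (same center).
#' @export
invert_rigid <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% tf$translation), tf$center)
}

#' Rotation angle of a rigid transform in degrees
#' @param tf a \code{rigid_transform} (or 3 x 3 rotation matrix).
#' @return rotation angle in degrees.
#' @export
rotation_angle_deg <- function(tf) {
  R <- if (inherits(tf, "rigid_transform")) tf$rotation else tf
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

#' 4 x 4 homogeneous matrix of a rigid transform
#' @param tf a \code{rigid_transform}.
#' @return 4 x 4 matrix acting on column vectors (x; 1).
#' @export
rigid_matrix4 <- function(tf) {
  m <- diag(4)
  m[1:3, 1:3] <- tf$rotation
  m[1:3, 4] <- tf$center + tf$translation - as.vector(tf$rotation %*% tf$center)
  m
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> angle %.3f deg, translation (%.2f, %.2f, %.2f) mm\n",
    rotation_angle_deg(x), x$translation[1], x$translation[2],
    x$translation[3]))
  invisible(x)
}
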