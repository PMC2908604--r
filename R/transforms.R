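## Rigid-body pose arithmetic.
##
## Conventions used throughout the package:
##   * all public angle I/O is in degrees, all lengths in centimetres;
##   * rotations are intrinsic x-then-y-then-z, i.e. the matrix acting on
##     column vectors is Rz(rz) %*% Ry(ry) %*% Rx(rx);
##   * reported Euler angles lie in (-180, 180].

.DEG <- pi / 180

.check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

#' Rotation matrix from Euler angles
#'
#' Builds the 3x3 rotation matrix for an intrinsic x-then-y-then-z rotation
#' sequence: `Rz(rz) %*% Ry(ry) %*% Rx(rx)` acting on column vectors, with
#' the x rotation applied first. All angles in degrees, right-handed axes.
#'
#' @param rx,ry,rz rotation angles about the x, y and z axes (degrees).
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' euler_matrix(90, 0, 0) %*% c(0, 1, 0)  # unit-y maps onto unit-z
#' @export
euler_matrix <- function(rx, ry, rz) {
  .check_finite(c(rx, ry, rz), "Euler angles")
  cx <- cos(rx * .DEG); sx <- sin(rx * .DEG)
  cy <- cos(ry * .DEG); sy <- sin(ry * .DEG)
  cz <- cos(rz * .DEG); sz <- sin(rz * .DEG)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

.is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_matrix()]: decomposes an orthonormal rotation matrix
#' into intrinsic x-then-y-then-z Euler angles, reported in degrees within
#' `(-180, 180]`.
#'
#' At the gimbal-lock configuration `|ry| = 90` degrees the x and z
#' rotations act about the same world axis and only their combination is
#' determined; the canonical branch returned here sets `rx = 0` and folds
#' the whole remaining rotation into `rz`.
#'
#' @param R a 3x3 orthonormal rotation matrix.
#' @return Named numeric vector `c(rx, ry, rz)` in degrees.
#' @export
euler_angles <- function(R) {
  if (!.is_rotation(R, tol = 1e-6))
    stop("R is not an orthonormal rotation matrix", call. = FALSE)
  sy <- -R[3, 1]
  if (abs(sy) >= 1 - 1e-10) {           # singular: |ry| = 90 deg
    ry <- if (sy > 0) 90 else -90
    rx <- 0
    rz <- if (sy > 0) atan2(R[2, 3], R[1, 3]) / .DEG
          else        atan2(-R[2, 3], -R[1, 3]) / .DEG
  } else {
    ry <- asin(sy) / .DEG
    rx <- atan2(R[3, 2], R[3, 3]) / .DEG
    rz <- atan2(R[2, 1], R[1, 1]) / .DEG
  }
  ang <- c(rx = rx, ry = ry, rz = rz)
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang[ang > 180] <- ang[ang > 180] - 360
  ang
}

#' Construct a rigid transform
#'
#' A proper rigid transform: a 3x3 rotation (orthonormal, det +1) plus a
#' translation in centimetres. Maps local coordinates `p` to parent
#' coordinates `R %*% p + t`.
#'
#' @param R 3x3 rotation matrix (default identity).
#' @param t length-3 translation (cm, default zero).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  .check_finite(t, "translation")
  if (length(t) != 3L) stop("translation must have length 3", call. = FALSE)
  if (!.is_rotation(R))
    stop("rotation part is not orthonormal with determinant +1", call. = FALSE)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform (cm):\n")
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(c("x", "y", "z"), c("R.x", "R.y", "R.z", "t"))
  print(round(m, 6))
  invisible(x)
}

#' Six-DOF pose
#'
#' One skeletal element's pose relative to its parent frame: three
#' translations (cm) followed by three rotations (degrees).
#'
#' @param tx,ty,tz translations along the parent frame axes (cm).
#' @param rx,ry,rz Euler rotations (degrees), intrinsic x-then-y-then-z.
#' @return Named numeric vector of length 6.
#' @export
pose6dof <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  .check_finite(c(tx, ty, tz, rx, ry, rz), "pose")
  c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
}

#' Rigid transform of a six-DOF pose
#'
#' @param pose a pose as returned by [pose6dof()] (or any numeric vector
#'   of length 6 ordered tx, ty, tz, rx, ry, rz).
#' @return A [rigid_transform()].
#' @export
pose_transform <- function(pose) {
  pose <- as.numeric(pose)
  if (length(pose) != 6L) stop("pose must have 6 elements", call. = FALSE)
  rigid_transform(euler_matrix(pose[4], pose[5], pose[6]), pose[1:3])
}

#' Compose two rigid transforms
#'
#' `compose(parent, child)` maps child-local coordinates into the parent's
#' parent frame, i.e. applies `child` first. Composition is associative.
#'
#' @param parent,child objects of class `rigid_transform`.
#' @return The composed `rigid_transform`.
#' @export
compose <- function(parent, child) {
  stopifnot(inherits(parent, "rigid_transform"), inherits(child, "rigid_transform"))
  structure(list(R = parent$R %*% child$R,
                 t = as.numeric(parent$R %*% child$t + parent$t)),
            class = "rigid_transform")
}

#' Invert a rigid transform
#'
#' @param x a `rigid_transform`.
#' @return The inverse transform: `compose(x, invert(x))` is the identity.
#' @export
invert <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  Rt <- t(x$R)
  structure(list(R = Rt, t = as.numeric(-Rt %*% x$t)), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param x a `rigid_transform`.
#' @param pts a length-3 vector or an n x 3 matrix of points (cm).
#' @return Transformed points, same shape as the input.
#' @export
transform_points <- function(x, pts) {
  stopifnot(inherits(x, "rigid_transform"))
  if (is.null(dim(pts))) return(as.numeric(x$R %*% pts + x$t))
  t(x$R %*% t(pts) + x$t)
}

#' Unwrap an angle trace
#'
#' Removes artificial +-360 degree jumps from a sampled angle trace so that
#' amplitudes can be read off continuous curves.
#'
#' @param x numeric vector of angles (degrees) sampled along time.
#' @return Unwrapped trace, first element unchanged.
#' @export
unwrap_deg <- function(x) {
  .check_finite(x, "angles")
  if (length(x) < 2L) return(x)
  d <- diff(x)
  adj <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  x + c(0, adj)
}
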