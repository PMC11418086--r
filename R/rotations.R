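#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, in degrees. Mostly useful
#' for building deterministic fixtures and for specifying viewing geometries by
#' hand.
#'
#' @param deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), -sin(th),
           0, sin(th), cos(th)), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th),
           0, 1, 0,
           -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0,
           sin(th), cos(th), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Test whether a matrix is a rotation
#'
#' Checks orthogonality (`m %*% t(m) = I`) and `det(m) = +1` to within `tol`.
#'
#' @param m A 3x3 numeric matrix.
#' @param tol Numerical tolerance.
#' @return Logical scalar.
#' @export
is_rotation <- function(m, tol = 1e-12) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) && all(is.finite(m)) &&
    max(abs(m %*% t(m) - diag(3))) <= tol && abs(det(m) - 1) <= tol
}

quat_to_rotation <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Draw rotations from the uniform distribution on SO(3)
#'
#' Samples unit quaternions (four i.i.d. standard normals, normalised), which
#' induces the Haar (uniform) distribution on the rotation group. This avoids
#' the polar bias of naive Euler-angle sampling.
#'
#' @param n Number of rotations to draw (positive integer).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of `n` 3x3 rotation matrices.
#' @examples
#' rots <- random_rotations(5, seed = 1)
#' all(vapply(rots, is_rotation, logical(1), tol = 1e-9))
#' @export
random_rotations <- function(n, seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  q <- matrix(stats::rnorm(4L * n), ncol = 4L)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) quat_to_rotation(q[i, ]))
}

#' Project a matrix to the nearest rotation
#'
#' Polar projection via the SVD, with the determinant forced to +1 (the final
#' singular direction is flipped if needed). This is the standard projection
#' onto SO(3) in Frobenius norm.
#'
#' @param m A 3x3 numeric matrix.
#' @return The nearest 3x3 rotation matrix.
#' @export
nearest_rotation <- function(m) {
  s <- svd(m)
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, sign(d))) %*% t(s$v)
}
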