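# Rigid-transform algebra. Transforms act on coordinates as
# x -> R x + t; composition follows function application order.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation, Angstrom.
#' @return A [RigidTransform-class].
#' @examples
#' t <- rigidTransform(diag(3), c(1, 2, 3))
#' applyTransform(t, matrix(0, 1, 3))
#' @export
rigidTransform <- function(rotation, translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = unname(as.matrix(rotation)),
      translation = unname(as.numeric(translation)))
}

#' Identity transform
#' @return The identity [RigidTransform-class].
#' @export
identityTransform <- function() rigidTransform(diag(3), c(0, 0, 0))

#' Rotation about an axis
#'
#' @param axis numeric length-3 rotation axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotationAboutAxis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Uniformly random rotation matrix
#'
#' Draws from the Haar measure on SO(3) via a random unit quaternion.
#' Uses R's global RNG stream.
#' @return 3x3 rotation matrix.
#' @export
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Nearest proper rotation (Frobenius) via SVD; rescues numerical drift
# accumulated along deep composition chains.
.nearestRotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

.renormalize <- function(t) {
  R <- t@rotation
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    t@rotation <- .nearestRotation(R)
  t
}

#' Apply a rigid transform to coordinates
#'
#' @param t a [RigidTransform-class].
#' @param coords n x 3 numeric matrix.
#' @return n x 3 matrix of transformed coordinates.
#' @export
applyTransform <- function(t, coords) {
  stopifnot(is(t, "RigidTransform"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be n x 3")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  sweep(coords %*% t(t@rotation), 2, t@translation, "+")
}

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` is the transform that applies `b` first, then
#' `a` (i.e. `a(b(x))`). The result is re-orthonormalized if composition
#' drift exceeds 1e-6.
#'
#' @param a,b [RigidTransform-class] objects (outer, inner).
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  .renormalize(rigidTransform(a@rotation %*% b@rotation,
                              as.vector(a@rotation %*% b@translation) +
                                a@translation))
}

#' Invert a rigid transform
#'
#' @param t a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(t) {
  Rt <- t(t@rotation)
  .renormalize(rigidTransform(Rt, -as.vector(Rt %*% t@translation)))
}
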