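# Rigid-body geometry shared by the pharmacophore matcher, the pose model
# and the trajectory analysis.

#' Optimal rigid superposition of two point sets (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `reference`.
#' The returned rotation is proper (determinant +1); reflections are never
#' produced.
#'
#' @param reference n x 3 matrix of target coordinates (Angstrom).
#' @param mobile n x 3 matrix to be superposed; same row order as
#'   `reference`.
#' @return list with `R` (3 x 3 rotation), `t` (length-3 translation such
#'   that `mobile %*% t(R) + t` approximates `reference`) and `rmsd`
#'   (Angstrom, over the fitted points).
#' @examples
#' p <- matrix(rnorm(15), 5, 3)
#' fit <- kabsch(p, p + 2)  # pure translation: rmsd ~ 0
#' @export
kabsch <- function(reference, mobile) {
  stopifnot(is.matrix(reference), is.matrix(mobile),
            ncol(reference) == 3L, ncol(mobile) == 3L,
            nrow(reference) == nrow(mobile))
  if (nrow(reference) < 3L)
    stop("superposition requires at least 3 points")
  cr <- colMeans(reference)
  cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  sv <- svd(crossprod(P, Q))
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- cr - as.vector(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, tvec, "+")
  list(R = R, t = tvec,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

# Apply a rigid transform returned by kabsch() to an n x 3 matrix.
applyTransform <- function(coords, trans) {
  sweep(coords %*% t(trans$R), 2, trans$t, "+")
}

# TRUE when the centered points span fewer than 2 dimensions (collinear or
# coincident), in which case the rotation is not determined.
isCollinear <- function(coords, tol = 1e-8) {
  centered <- sweep(coords, 2, colMeans(coords))
  sv <- svd(centered, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

# Rotation matrix about a unit axis by angle theta (Rodrigues).
rotationAbout <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Minimal rotation mapping unit vector a onto unit vector b.
rotationBetween <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * a) * a
    return(rotationAbout(axis, pi))
  }
  rotationAbout(v / s, atan2(s, cth))
}

# Place a rigid body so that two of its atoms land at prescribed distances
# r1 and r2 from the origin.  Atom i1 goes to r1 * u (u a unit vector);
# atom i2 goes to a point at distance r2 from the origin on the circle of
# radius |x_i2 - x_i1| around the new i1 position, selected by `phi`;
# the remaining degree of freedom (spin about the i1->i2 axis) is `spin`.
# Feasible iff |r1 - d12| <= r2 <= r1 + d12.
placeTwoAtoms <- function(coords, i1, i2, r1, r2,
                          u = c(1, 0, 0), phi = 0, spin = 0) {
  d12 <- sqrt(sum((coords[i2, ] - coords[i1, ])^2))
  if (r2 < abs(r1 - d12) - 1e-9 || r2 > r1 + d12 + 1e-9)
    stop(sprintf(
      "infeasible placement: with |a1-a2| = %.3f A, r2 must lie in [%.3f, %.3f]",
      d12, abs(r1 - d12), r1 + d12))
  u <- u / sqrt(sum(u^2))
  t1 <- r1 * u
  # target for i2: solve on the sphere intersection circle
  cosA <- (r1^2 + d12^2 - r2^2) / (2 * r1 * d12)
  cosA <- max(-1, min(1, cosA))
  sinA <- sqrt(1 - cosA^2)
  # basis perpendicular to u
  perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- perp - sum(perp * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  dir12 <- -cosA * u + sinA * (cos(phi) * e1 + sin(phi) * e2)
  t2 <- t1 + d12 * dir12
  # rigid transform: first align the i1->i2 direction, then spin, then shift
  v0 <- coords[i2, ] - coords[i1, ]
  R1 <- rotationBetween(v0, t2 - t1)
  R <- rotationAbout(t2 - t1, spin) %*% R1
  shifted <- sweep(coords, 2, coords[i1, ])
  out <- sweep(shifted %*% t(R), 2, t1, "+")
  dimnames(out) <- dimnames(coords)
  out
}

rowDistances <- function(coords, point) {
  sqrt(rowSums(sweep(coords, 2, point)^2))
}
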