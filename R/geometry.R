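# Low-level vector geometry. Coordinates are plain numeric 3-vectors or
# n x 3 matrices throughout; all angles in degrees.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) v / .vnorm(v)

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle at b formed by a-b-c.
.angle3 <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Signed dihedral a-b-c-d in (-180, 180].
.dihedral4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .unit(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Natural-extension-reference-frame placement: position atom D given the
# three parent positions and internal coordinates bond |C-D|, angle B-C-D
# and torsion A-B-C-D (degrees).
.nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Squared cross-distances between row-sets of two n x 3 matrices.
.cross_dist2 <- function(A, B) {
  an <- rowSums(A * A); bn <- rowSums(B * B)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Optimal least-squares superposition (Kabsch, SVD with reflection guard).
# Returns the rotation that maps centred B onto centred A plus the RMSD.
.kabsch <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  list(R = R, center_a = ca, center_b = cb, rmsd = rmsd)
}

# Deterministic near-uniform points on the unit sphere (golden-section
# spiral); the basis of seed-free Shrake-Rupley sampling.
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
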