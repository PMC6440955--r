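# Small 3D helpers shared by the generator and the geometry analyses.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two vectors, degrees
vec_angle <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

# rotation matrix about a (unit) axis, angle in degrees (Rodrigues)
rotation_matrix <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Natural-extension placement: position atom d given a-b-c with bond
# |c-d|, angle b-c-d and dihedral a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Kabsch: rotation + translation mapping mobile onto target (n x 3 each).
# Returns list(R, t) with fitted = mobile %*% R + t (row vectors).
kabsch_fit <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(R = R, t = ct - as.numeric(cm %*% R))
}

apply_fit <- function(coords, fit) {
  sweep(coords %*% fit$R, 2, fit$t, "+")
}

# rotation angle (deg) and axis of a rotation matrix
rotation_angle_axis <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  angle <- acos(pmin(pmax(ca, -1), 1)) * 180 / pi
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(ax) < 1e-12) {
    # angle ~ 0 or 180; pick dominant eigenvector of (R + I)
    ev <- eigen(R)
    i <- which.min(abs(Re(ev$values) - 1))
    ax <- Re(ev$vectors[, i])
  }
  list(angle = angle, axis = unit(ax))
}

# signed angle of b relative to a about axis n (all 3-vectors), degrees
signed_angle_about <- function(a, b, n) {
  n <- unit(n)
  a <- unit(a - sum(a * n) * n)
  b <- unit(b - sum(b * n) * n)
  ang <- atan2(sum(cross3(a, b) * n), sum(a * b)) * 180 / pi
  ang
}
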