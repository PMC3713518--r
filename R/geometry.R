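# Internal 3D geometry helpers. Coordinates are plain numeric 3-vectors or
# n x 3 matrices, units Angstrom, angles in degrees unless noted.

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize zero-length vector", call. = FALSE)
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Angle a-b-c at vertex b, degrees in [0, 180].
.angle3 <- function(a, b, c) {
  u <- .unit(a - b)
  v <- .unit(c - b)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Signed dihedral a-b-c-d, degrees in (-180, 180].
.dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  .rad2deg(atan2(y, x))
}

# NeRF atom placement: position D bonded to C with |CD| = bond,
# angle(B,C,D) = ang and dihedral(A,B,C,D) = dih.
.placeAtom <- function(a, b, c, bond, ang, dih) {
  th <- .deg2rad(ang)
  ch <- .deg2rad(dih)
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ch), bond * sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix for a right-handed rotation of `deg` degrees about `axis`.
.rotAxis <- function(axis, deg) {
  u <- .unit(axis)
  th <- .deg2rad(deg)
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Rotation matrix from ZYX Euler angles (degrees).
.rotEuler <- function(rx, ry, rz) {
  .rotAxis(c(0, 0, 1), rz) %*% .rotAxis(c(0, 1, 0), ry) %*% .rotAxis(c(1, 0, 0), rx)
}

# Apply rotation R then translation t to an n x 3 coordinate matrix.
.xform <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, t, "+")
}

# Kabsch: optimal rotation (and translation) mapping Y onto X.
.kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(y0, x0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cx - as.vector(R %*% cy))
}

# Heavy-atom RMSD between two conformations, optionally after optimal
# superposition. x, y: n x 3 matrices with matched rows.
.rmsdXYZ <- function(x, y, fit = TRUE) {
  if (fit) {
    k <- .kabsch(x, y)
    y <- sweep(y %*% t(k$R), 2, k$t, "+")
  }
  sqrt(mean(rowSums((x - y)^2)))
}

# Least-squares plane through points (n x 3). Returns origin (centroid) and
# unit normal (smallest principal direction).
.lsPlane <- function(xyz) {
  if (nrow(xyz) < 3) stop("need at least 3 points to fit a plane", call. = FALSE)
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  s <- svd(x0, nu = 0)
  if (s$d[2] < 1e-9) stop("degenerate (collinear) selection: plane undefined", call. = FALSE)
  list(origin = ctr, normal = as.vector(s$v[, 3]),
       inplane = list(as.vector(s$v[, 1]), as.vector(s$v[, 2])),
       rms = s$d[3] / sqrt(nrow(xyz)))
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
.fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# FNV-1a 32-bit hash of a character string, as 8-digit hex. Used to stamp
# artifacts with a config fingerprint without external digest dependencies.
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (h may exceed the bitwXor integer range)
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by 16777619 done in two 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
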