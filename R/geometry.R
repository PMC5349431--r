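# Small 3D geometry helpers (plain numeric 3-vectors).

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle p1-p2-p3 in degrees.
.angle_deg <- function(p1, p2, p3) {
  u <- .unit(p1 - p2); v <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Dihedral p1-p2-p3-p4 in degrees (IUPAC sign convention).
.dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place atom X bonded to A with |X-A| = r, angle(X, A, B) = theta and
# dihedral(X, A, B, C) = phi (degrees).  C may be NULL, in which case an
# arbitrary but deterministic reference perpendicular is used.
.place_internal <- function(A, B, C, r, theta_deg, phi_deg) {
  ab <- .unit(B - A)
  ref <- if (is.null(C)) {
    w <- if (abs(ab[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w
  } else .unit(C - B)
  n <- .vcross(ab, ref)
  if (sqrt(sum(n^2)) < 1e-8) {
    w <- if (abs(ab[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- .vcross(ab, w)
  }
  n <- .unit(n)
  m <- .vcross(n, ab)
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  A + r * (cos(th) * ab + sin(th) * (cos(ph) * m + sin(ph) * n))
}
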