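# 3D vector geometry used by the dihedral classifier, the pseudo-C-beta
# construction and the fixture builders; all angles in degrees

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two vectors, [0, 180] degrees; NA for degenerate input
vangle <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na < 1e-9 || nb < 1e-9) return(NA_real_)
  cosang <- sum(a * b) / (na * nb)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# signed dihedral p1-p2-p3-p4 in degrees, IUPAC convention (trans = 180)
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- vcross(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Natural-extension-reference-frame placement: position atom D given the
# three preceding atoms A-B-C, the bond length C-D, the bond angle B-C-D
# and the torsion A-B-C-D (degrees)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- -torsion * pi / 180
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(c + m %*% d2)
}

rot_z <- function(theta) {
  th <- theta * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(theta) {
  th <- theta * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
}

# rotation taking unit vector `from` onto unit vector `to` (Rodrigues)
rot_between <- function(from, to) {
  f <- vunit(from); t <- vunit(to)
  v <- vcross(f, t)
  s <- vnorm(v)
  cth <- sum(f * t)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular axis
    perp <- if (abs(f[1]) < 0.9) vunit(vcross(f, c(1, 0, 0))) else vunit(vcross(f, c(0, 1, 0)))
    v <- perp
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  v <- v / s
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + sin(acos(max(-1, min(1, cth)))) * K +
    (1 - cth) * (K %*% K)
}
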