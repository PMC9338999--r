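## Internal-coordinate geometry: atom placement from bond length / bond angle /
## torsion (NeRF construction) and the reverse measurements.

vnorm <- function(v) sqrt(sum(v * v))
vunit <- function(v) v / vnorm(v)
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Given three reference positions `a`, `b`, `c`, returns the position `d`
#' such that the bond length |c-d| is `r` Angstrom, the bond angle b-c-d is
#' `theta` degrees and the proper dihedral a-b-c-d is `phi` degrees
#' (standard NeRF construction).
#'
#' @param a,b,c numeric 3-vectors, reference atom coordinates.
#' @param r bond length (Angstrom).
#' @param theta bond angle b-c-d (degrees).
#' @param phi dihedral a-b-c-d (degrees).
#' @return numeric 3-vector.
#' @export
place_atom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- vunit(c - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10) stop("collinear reference atoms in place_atom")
  n <- vunit(n)
  m <- vcross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), -r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Measure a proper dihedral angle
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return dihedral a-b-c-d in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

bond_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}
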