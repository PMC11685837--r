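# Small 3D geometry kernel: torsion-based atom placement (NeRF), bond/dihedral
# measurement, and random rigid transforms for invariance testing.

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame (NeRF) placement: the new atom `d` is
#' positioned at `bond` Angstrom from `c`, with angle `b-c-d` and proper
#' torsion `a-b-c-d` as requested (degrees).
#'
#' @param p1,p2,p3 numeric length-3 coordinates of the three reference atoms
#'   (`p3` is the bonded parent of the new atom).
#' @param bond bond length p3-d in Angstrom.
#' @param angle bond angle p2-p3-d in degrees.
#' @param torsion dihedral p1-p2-p3-d in degrees.
#' @return numeric length-3 coordinates of the placed atom.
#' @keywords internal
place_atom <- function(p1, p2, p3, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(p3 - p2)
  n <- unitv(cross3(p2 - p1, bc))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  as.numeric(p3 + cbind(bc, m, n) %*% d_local)
}

#' Measure a bond angle (degrees) at vertex b
#' @keywords internal
bond_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
}

#' Measure a proper dihedral a-b-c-d (degrees)
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3) via QR decomposition of a Gaussian matrix with the
#' determinant sign fixed.
#'
#' @param seed optional integer seed.
#' @return 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_d)
    d <- diag(qr.R(qr_d))
    q <- q %*% diag(sign(d))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Apply a rigid-body transform to a structure
#'
#' @param structure a [protein_structure()].
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 offset in Angstrom.
#' @return the transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is_protein_structure(structure))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}
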