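# Small geometric and indexing helpers shared across modules.

# Reshape a length-3A xyz vector (x1,y1,z1,x2,...) into an A x 3 matrix.
xyz2mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Inverse of xyz2mat.
mat2xyz <- function(m) as.numeric(t(m))

# xyz column indices (into a frames x 3A matrix) for a set of atom indices.
atom2xyz_inds <- function(atoms) {
  as.integer(t(outer(atoms - 1L, 1:3, function(a, k) 3L * a + k)))
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Angle a-b-c in degrees.
angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Dihedral a-b-c-d in degrees, in (-180, 180].
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    n1[2] * unitv(b2)[3] - n1[3] * unitv(b2)[2],
    n1[3] * unitv(b2)[1] - n1[1] * unitv(b2)[3],
    n1[1] * unitv(b2)[2] - n1[2] * unitv(b2)[1]
  )
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place atom D given positions of A, B, C and the internal coordinates
# |C-D|, angle B-C-D (deg) and dihedral A-B-C-D (deg).  Standard NeRF
# construction used to build ideal backbones.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(tor),
    bond * sin(ang) * sin(tor)
  )
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d2 + c)
}

# Cross product (kept local; avoids pulling in a package for one primitive).
pracma_cross <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

# Arithmetic mean of per-frame pairwise distance matrices is never needed;
# but several modules need a per-frame atom-atom distance matrix.
frame_dist <- function(coords) as.matrix(stats::dist(coords))

`%||%` <- function(a, b) if (is.null(a)) b else a
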