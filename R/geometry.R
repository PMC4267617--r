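# Vector geometry and periodic-boundary primitives.
# Lengths in angstroms, angles in degrees unless noted otherwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop("coordinates must be length-3 vectors or n x 3 matrices")
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  if (ncol(x) != 3L) stop("coordinate matrix must have 3 columns")
  x
}

#' Minimum-image displacement for an orthorhombic box
#'
#' Folds a displacement (or matrix of displacements) into the central image
#' of an orthorhombic periodic box, so that each component lies in
#' `[-box/2, box/2)`.
#'
#' @param d numeric length-3 vector or n x 3 matrix of raw displacements (A).
#' @param box numeric length-3 vector of box edge lengths (A).
#' @return object of the same shape as `d`.
#' @export
min_image_disp <- function(d, box) {
  stopifnot(length(box) == 3L, all(box > 0))
  vec <- is.null(dim(d))
  d <- as_coord_matrix(d)
  if (nrow(d) == 0L) return(d)
  b <- matrix(box, nrow(d), 3L, byrow = TRUE)
  out <- d - b * round(d / b)
  if (vec && nrow(out) == 1L) drop(out) else out
}

#' Minimum-image distance in an orthorhombic periodic box
#'
#' Euclidean distance between `p` and the nearest periodic image of `q`.
#' Both arguments may be length-3 vectors or n x 3 matrices (recycled
#' row-wise against each other).
#'
#' @param p,q points (A), length-3 vectors or n x 3 matrices.
#' @param box numeric length-3 vector of box edge lengths (A); all > 0.
#' @return numeric vector of distances (A).
#' @examples
#' min_image_distance(c(0, 0, 0), c(81, 0, 0), c(82, 82, 82)) # 1
#' @export
min_image_distance <- function(p, q, box) {
  p <- as_coord_matrix(p)
  q <- as_coord_matrix(q)
  if (nrow(p) != nrow(q)) {
    if (nrow(p) == 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
    else if (nrow(q) == 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
    else stop("p and q must have compatible numbers of rows")
  }
  d <- min_image_disp(p - q, box)
  d <- as_coord_matrix(d)
  sqrt(rowSums(d * d))
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; result in degrees in `(-180, 180]`.  Errors when
#' three consecutive points are (numerically) collinear, in which case the
#' torsion is undefined.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (A).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("dihedral undefined: three consecutive points are collinear")
  }
  b2u <- unitv(b2)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D bonded to C given the chain A-B-C, bond length r (A),
# bond angle theta = angle(B, C, D) and dihedral phi = dihedral(A, B, C, D),
# both in degrees (standard internal-coordinate / NeRF construction).
place_atom <- function(a, b, c, r, theta, phi) {
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + bc * d_local[1] + m * d_local[2] + n * d_local[3]
}

rot_z <- function(theta) {
  t <- deg2rad(theta)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(theta) {
  t <- deg2rad(theta)
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}

# Rigid transform (no reflection) mapping the rows of src onto dst in the
# least-squares sense; returns a function acting on n x 3 matrices.
rigid_fit <- function(src, dst) {
  src <- as_coord_matrix(src)
  dst <- as_coord_matrix(dst)
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- t(sweep(src, 2, cs)) %*% sweep(dst, 2, cd)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  function(x) {
    x <- as_coord_matrix(x)
    sweep(sweep(x, 2, cs) %*% R, 2, cd, "+")
  }
}
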