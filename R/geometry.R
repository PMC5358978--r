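## Geometric primitives: torsion angles, rigid-body superposition.

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(a) sqrt(sum(a * a))

#' Torsion (dihedral) angle of four points
#'
#' Standard atan2 formulation; the result is in degrees in (-180, 180],
#' measured about the p2-p3 axis with the IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, b2 / .vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `R %*% x + t` over paired atoms of `mobile` onto `reference`. The
#' rotation is constrained to determinant +1 (no reflection) via the SVD
#' sign correction.
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows,
#'   n >= 3, non-degenerate (a collinear reference is an error).
#' @return object of class `nes_superposition`: list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (Angstrom, over the fitted atoms) and
#'   `n_atoms`.
#' @seealso [apply_transform()]
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate matrices must have 3 columns")
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("mobile and reference must pair row-wise")
  if (n < 3L) stop("superposition needs at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  sv_ref <- svd(B)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    stop("reference coordinates are collinear; superposition is degenerate")
  M <- crossprod(A, B)                     # 3x3
  sv <- svd(M)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  fitted <- t(R %*% t(mobile)) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = t_vec,
                 rmsd = rmsd, n_atoms = n),
            class = "nes_superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param coords n x 3 matrix (or length-3 vector).
#' @param transform `nes_superposition` from [superpose()].
#' @return transformed coordinates, same shape as input.
#' @export
apply_transform <- function(coords, transform) {
  stopifnot(inherits(transform, "nes_superposition"))
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, 1, 3) else as.matrix(coords)
  out <- t(transform$rotation %*% t(m)) +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' RMSD between paired coordinate sets (no fitting)
#'
#' @param a,b n x 3 matrices with paired rows.
#' @return root-mean-square deviation in Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' @export
print.nes_superposition <- function(x, ...) {
  cat(sprintf("Rigid-body superposition over %d atoms, rmsd %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

# Random rigid transform used by invariance tests and jitter utilities.
random_rigid_transform <- function() {
  ax <- stats::rnorm(3); ax <- ax / .vnorm(ax)
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  structure(list(rotation = R, translation = stats::rnorm(3, sd = 10),
                 rmsd = NA_real_, n_atoms = NA_integer_),
            class = "nes_superposition")
}
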