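# Rigid-body geometry primitives shared by the detection and alignment stages.
# All coordinates are n x 3 matrices in Angstrom.

#' Rigid transform constructor
#'
#' A rigid (proper) transform `x' = R x + t` with `R` a 3x3 rotation matrix
#' (orthonormal, det +1) and `t` a translation 3-vector in Angstrom.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric 3-vector.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation matrix is improper (det -1): reflections are not allowed")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n"); print(round(x$R, 6))
  cat("translation:", paste(round(x$t, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param tr A `rigid_transform`.
#' @param xyz n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates, same shape as input.
#' @export
transform_coords <- function(tr, xyz) {
  vec <- is.null(dim(xyz))
  if (vec) xyz <- matrix(xyz, nrow = 1)
  out <- xyz %*% t(tr$R) + matrix(tr$t, nrow(xyz), 3, byrow = TRUE)
  if (vec) out[1, ] else out
}

#' Invert a rigid transform
#' @param tr A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), as.numeric(-t(tr$R) %*% tr$t))
}

#' Compose rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first,
#' then `a`.
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Least-squares rigid superposition of corresponded point sets
#'
#' Finds the proper rotation + translation minimizing the sum of squared
#' distances between `moving` and `fixed` under the given (row-by-row)
#' correspondence, via the SVD-based closed form. With a fully constrained
#' correspondence this is the single step to which constrained
#' iterative-closest-points collapses.
#'
#' @param moving,fixed n x 3 matrices of corresponded points (row i of
#'   `moving` corresponds to row i of `fixed`).
#' @return list with `transform` (a `rigid_transform` mapping `moving` onto
#'   `fixed`) and `rmsd` (Angstrom, over the same correspondence).
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(ncol(moving) == 3L, ncol(fixed) == 3L,
            nrow(moving) == nrow(fixed))
  n <- nrow(moving)
  if (n < 3L) stop("superposition needs at least 3 point pairs")
  pm <- colMeans(moving); qm <- colMeans(fixed)
  P <- sweep(moving, 2, pm); Q <- sweep(fixed, 2, qm)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) point set: superposition is ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- qm - as.numeric(R %*% pm)
  tr <- rigid_transform(R, tvec)
  resid <- P %*% t(R) - Q
  list(transform = tr, rmsd = sqrt(mean(rowSums(resid^2))))
}

#' RMSD of two corresponded coordinate sets (no fitting)
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

# All-pairs Euclidean distances between two coordinate sets; returns an
# n x m matrix. Used by the minimum-distance criteria throughout.
cross_distances <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) +
    matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE) -
    2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Minimum pairwise distance between two atom sets.
min_cross_distance <- function(a, b) min(cross_distances(a, b))

#' Principal axis of a point cloud
#'
#' Least-squares line through the centroid along the direction of maximal
#' variance (first principal component).
#'
#' @param xyz n x 3 matrix.
#' @return list with `point` (centroid) and `direction` (unit 3-vector).
#' @export
principal_axis <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3L) stop("principal axis needs at least 3 points")
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  if (ev$values[1] < 1e-8) stop("degenerate point cloud: no principal axis")
  list(point = ctr, direction = ev$vectors[, 1])
}

# Distance from point(s) to the infinite line (point, direction).
point_line_distance <- function(p, axis) {
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1)
  v <- sweep(p, 2, axis$point)
  proj <- as.numeric(v %*% axis$direction)
  perp <- v - outer(proj, axis$direction)
  d <- sqrt(rowSums(perp^2))
  if (vec) d[1] else d
}

#' Deterministic random proper rotation
#'
#' Draws a uniformly distributed rotation matrix (QR of a Gaussian matrix,
#' sign-fixed, reflected into det +1 if needed).
#'
#' @param seed optional integer seed; when given the draw is reproducible
#'   and the RNG state of the caller is untouched.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  }
  if (is.null(seed)) return(draw())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draw()
}
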