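## Low-level rigid-body geometry shared across the pipeline.

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric length-3 axis (need not be unit length).
#' @param theta rotation angle in radians, right-handed about `axis`.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

rot_z <- function(theta_deg) rotation_matrix(c(0, 0, 1), theta_deg * pi / 180)

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` using the
#' SVD-based Kabsch algorithm, with the reflection guard so the returned
#' rotation is always proper (determinant +1).
#'
#' @param mobile N x 3 coordinate matrix to move.
#' @param reference N x 3 coordinate matrix (same row order).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `coords` (the transformed mobile coordinates).
#'   Transformed coordinates are `mobile %*% rotation` shifted so centroids
#'   coincide: `coords = (mobile - cm_mob) %*% R + cm_ref`.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' b <- a %*% rot_z(90)
#' superpose(b, a)$rmsd  # ~0
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("superpose: coordinate sets differ in size (",
         nrow(mobile), " vs ", nrow(reference), " rows)")
  if (nrow(mobile) < 3L)
    stop("superpose: need at least 3 points")
  cm_m <- colMeans(mobile); cm_r <- colMeans(reference)
  A <- sweep(mobile, 2, cm_m); B <- sweep(reference, 2, cm_r)
  s <- svd(crossprod(A, B))          # A^T B = U D V^T ; R = U diag(1,1,d) V^T
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) stop("superpose: degenerate (collinear?) coordinates")
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  moved <- A %*% R
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R,
       translation = as.numeric(cm_r - cm_m %*% R),
       rmsd = rmsd,
       coords = sweep(moved, 2, cm_r, "+"))
}

#' Root-mean-square deviation between two coordinate sets (no fitting)
#' @keywords internal
rmsd_raw <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Signed angle between two XY-plane vectors, right-handed about +z
#' @return degrees in (-180, 180]
#' @keywords internal
signed_xy_angle <- function(v_from, v_to) {
  a <- atan2(v_to[2], v_to[1]) - atan2(v_from[2], v_from[1])
  a <- a * 180 / pi
  a <- ((a + 180) %% 360) - 180
  if (a == -180) a <- 180
  a
}

#' Circular mean of angles in degrees
#' @keywords internal
circular_mean_deg <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' Helical axis of a run of C-alpha atoms
#'
#' Estimates the axis direction of an (approximately) alpha-helical stretch
#' from the bisector construction: for three consecutive C-alphas the angle
#' bisector points radially toward the helix axis, so cross products of
#' successive bisectors are parallel to the axis. On an ideal helix this is
#' exact for any length; it is therefore preferred over the principal axis
#' of the coordinates, which is biased by the helical winding for short
#' segments. Falls back to the principal axis when fewer than 6 points are
#' supplied.
#'
#' @param coords N x 3 matrix of consecutive C-alpha coordinates, N >= 4.
#' @return unit length-3 axis vector oriented with positive z component.
#' @export
helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4L) stop("helix_axis: need at least 4 points")
  if (n >= 6L) {
    # bisectors b_i at interior points
    v1 <- coords[1:(n - 2), , drop = FALSE] - coords[2:(n - 1), , drop = FALSE]
    v2 <- coords[3:n, , drop = FALSE] - coords[2:(n - 1), , drop = FALSE]
    b <- v1 / sqrt(rowSums(v1^2)) + v2 / sqrt(rowSums(v2^2))
    m <- nrow(b)
    cr <- matrix(0, m - 1, 3)
    for (i in seq_len(m - 1)) {
      cr[i, ] <- c(b[i, 2] * b[i + 1, 3] - b[i, 3] * b[i + 1, 2],
                   b[i, 3] * b[i + 1, 1] - b[i, 1] * b[i + 1, 3],
                   b[i, 1] * b[i + 1, 2] - b[i, 2] * b[i + 1, 1])
    }
    # orient consistently before averaging
    ref <- cr[1, ]
    flip <- (cr %*% ref) < 0
    cr[flip, ] <- -cr[flip, ]
    ax <- colSums(cr)
  } else {
    cc <- scale(coords, scale = FALSE)
    ax <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  }
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-12) stop("helix_axis: degenerate geometry, axis undefined")
  ax <- ax / nrm
  if (ax[3] < 0) ax <- -ax
  ax
}

#' Orthonormal rigid-body basis (3 translations + 3 rotations) at a geometry
#'
#' @param coords N x 3 coordinates; rotations are taken about the centroid.
#' @return 3N x 6 matrix with orthonormal columns spanning the rigid-body
#'   subspace.
#' @keywords internal
rigid_body_basis <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  cc <- sweep(coords, 2, colMeans(coords))
  B <- matrix(0, 3 * n, 6)
  idx <- function(k) seq(k, 3 * n, by = 3)
  for (k in 1:3) B[idx(k), k] <- 1
  # infinitesimal rotations about x, y, z
  B[, 4] <- as.vector(t(cbind(0, -cc[, 3], cc[, 2])))
  B[, 5] <- as.vector(t(cbind(cc[, 3], 0, -cc[, 1])))
  B[, 6] <- as.vector(t(cbind(-cc[, 2], cc[, 1], 0)))
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

## flat 3N vector <-> N x 3 matrix (x1,y1,z1,x2,...) ordering
vec2mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
mat2vec <- function(m) as.vector(t(m))
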