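## PCA of superposed coordinate ensembles, projections of structures and
## trajectory frames onto principal components, and relative free-energy
## landscapes over the projection plane.

#' Principal component analysis of a superposed coordinate ensemble
#'
#' Diagonalizes the covariance matrix (about the ensemble mean, uniform
#' C-alpha weights) of an ensemble of superposed coordinate rows. The
#' covariance is never formed explicitly; modes come from the SVD of the
#' centred coordinate matrix. Mode signs are fixed so that the projection
#' of the second ensemble member is non-negative on every mode.
#'
#' @param x `ensemble` (from [build_core()]), state-ensemble list, or a
#'   plain members x 3N coordinate matrix of already-superposed members.
#' @param provenance provenance tag stored with the modes
#'   ("ensemble-PCA", "ED", "ENM").
#' @return object of class `modeset`: `modes` (3N x K, orthonormal columns,
#'   sorted by decreasing eigenvalue), `eigenvalues` (Angstrom^2, variance
#'   per mode), `variance_fraction`, `mean` (3N), `n_res`, `provenance`.
#' @export
fit_pca <- function(x, provenance = "ensemble-PCA") {
  xyz <- if (is.matrix(x)) x else x$xyz
  if (is.null(xyz) || nrow(xyz) < 2) stop("fit_pca: need >= 2 ensemble members")
  m <- nrow(xyz)
  mu <- colMeans(xyz)
  Xc <- sweep(xyz, 2, mu)
  s <- svd(Xc, nu = 0)
  lambda <- s$d^2 / (m - 1)
  k_max <- min(m - 1, ncol(xyz))
  keep <- seq_len(k_max)
  lambda <- lambda[keep]
  modes <- s$v[, keep, drop = FALSE]
  # drop numerically-zero directions beyond rank
  nz <- lambda > max(lambda[1], 0) * 1e-12
  lambda[!nz] <- 0
  # sign convention: second member projects >= 0
  pr2 <- as.numeric((xyz[2, ] - mu) %*% modes)
  flip <- pr2 < 0
  modes[, flip] <- -modes[, flip]
  structure(list(modes = modes, eigenvalues = lambda,
                 variance_fraction = if (sum(lambda) > 0)
                   lambda / sum(lambda) else lambda,
                 mean = mu, n_res = ncol(xyz) / 3,
                 provenance = provenance),
            class = "modeset")
}

#' @export
print.modeset <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("modeset (", x$provenance, "): ", ncol(x$modes), " modes over ",
      x$n_res, " residues\n", sep = "")
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]), collapse = " "),
      if (length(x$eigenvalues) > k) "..." else "", "\n")
  invisible(x)
}

## resolve a reference to a flat 3N vector
ref_vec <- function(reference) {
  if (inherits(reference, "structure3d") || inherits(reference, "ca_set"))
    return(mat2vec(as_ca(reference)$coords))
  if (is.matrix(reference) && ncol(reference) == 3) return(mat2vec(reference))
  as.numeric(reference)
}

#' Project structures onto principal components
#'
#' The projection of structure i on mode k is the dot product of the
#' difference vector (structure minus reference) with the unit mode, i.e.
#' the length of the difference vector times the cosine of the angle it
#' makes with the mode. The reference structure projects to the origin.
#'
#' @param x coordinates to project: `ensemble`, `ca_set`, `structure3d`,
#'   N x 3 matrix, or a members x 3N matrix.
#' @param modeset `modeset` from [fit_pca()].
#' @param reference reference coordinates (N x 3 matrix, 3N vector, or a
#'   structure); projections are taken relative to it.
#' @param fit superpose each row onto the reference before projecting
#'   (default TRUE; set FALSE when coordinates are already in the reference
#'   frame).
#' @param n_modes how many components to report (default all).
#' @return data.frame of class `pc_projection`: one row per input
#'   structure/frame with columns `pc1`, `pc2`, ..., `diff_norm` (length of
#'   the difference vector, Angstrom) and `fit_rmsd`.
#' @export
project <- function(x, modeset, reference, fit = TRUE, n_modes = NULL) {
  stopifnot(inherits(modeset, "modeset"))
  xyz <- if (is.matrix(x) && ncol(x) != 3) x
  else if (is.matrix(x)) matrix(mat2vec(x), nrow = 1)
  else if (inherits(x, "ensemble") || inherits(x, "ca_traj")) x$xyz
  else as_ca(x)$xyz
  rv <- ref_vec(reference)
  if (length(rv) != ncol(xyz)) stop("project: reference dimension mismatch")
  if (ncol(xyz) != nrow(modeset$modes))
    stop("project: coordinates do not match the mode set dimension")
  k <- n_modes %||% ncol(modeset$modes)
  k <- min(k, ncol(modeset$modes))
  refm <- vec2mat(rv)
  out <- matrix(0, nrow(xyz), k)
  dn <- numeric(nrow(xyz)); fr <- rep(NA_real_, nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    v <- xyz[i, ]
    if (fit) {
      sp <- superpose(vec2mat(v), refm)
      v <- mat2vec(sp$coords)
      fr[i] <- sp$rmsd
    }
    d <- v - rv
    out[i, ] <- as.numeric(d %*% modeset$modes[, seq_len(k), drop = FALSE])
    dn[i] <- sqrt(sum(d^2))
  }
  df <- as.data.frame(out)
  names(df) <- paste0("pc", seq_len(k))
  df$diff_norm <- dn
  df$fit_rmsd <- fr
  class(df) <- c("pc_projection", "data.frame")
  df
}

#' Project a trajectory onto principal components
#'
#' Each frame is rigid-body superposed onto the reference (removing global
#' drift) before projecting; the per-frame fit RMSD is kept in the result.
#'
#' @inheritParams project
#' @param trajectory `ca_traj`, multi-frame `structure3d`, or frames x 3N
#'   matrix.
#' @return `pc_projection` data.frame, one row per frame in order, with a
#'   `frame` column.
#' @export
project_trajectory <- function(trajectory, modeset, reference,
                               n_modes = NULL) {
  df <- project(trajectory, modeset, reference, fit = TRUE,
                n_modes = n_modes)
  df$frame <- seq_len(nrow(df))
  df
}

#' Relative free-energy landscape over two projection coordinates
#'
#' Bins samples on the (PC1, PC2) plane and converts the occupancy into a
#' relative free energy dG = -kT log(P / Pmax), so the most populated bin
#' is at 0 and empty bins are masked (NA). Reported both in kT units and in
#' kJ/mol at the stated temperature.
#'
#' @param projections `pc_projection` data.frame (or any data.frame/matrix
#'   whose first two columns, or `pc1`/`pc2` columns, are the coordinates).
#' @param temperature Kelvin (default 300; kT = 2.494 kJ/mol).
#' @param bins number of bins per axis (default 50).
#' @param pad fractional padding of the data range (default 0.05).
#' @return object of class `fel_grid`: `x_mid`, `y_mid`, `x_edges`,
#'   `y_edges`, `counts`, `dg_kt`, `dg_kjmol`, `temperature`.
#' @export
free_energy_landscape <- function(projections, temperature = 300,
                                  bins = 50, pad = 0.05) {
  if (is.data.frame(projections) && all(c("pc1", "pc2") %in% names(projections))) {
    xy <- cbind(projections$pc1, projections$pc2)
  } else {
    xy <- as.matrix(projections)[, 1:2, drop = FALSE]
  }
  if (nrow(xy) < 1) stop("free_energy_landscape: no samples")
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  expand <- function(r) {
    w <- diff(r); if (w == 0) w <- 1
    r + c(-1, 1) * pad * w
  }
  rng_x <- expand(rng_x); rng_y <- expand(rng_y)
  xe <- seq(rng_x[1], rng_x[2], length.out = bins + 1)
  ye <- seq(rng_y[1], rng_y[2], length.out = bins + 1)
  ix <- findInterval(xy[, 1], xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(xy[, 2], ye, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (i in seq_len(nrow(xy)))
    counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  p <- counts / sum(counts)
  dg <- -log(p / max(p))
  dg[counts == 0L] <- NA_real_
  kT <- 0.0083144621 * temperature   # kJ/mol
  structure(list(x_mid = (xe[-1] + xe[-length(xe)]) / 2,
                 y_mid = (ye[-1] + ye[-length(ye)]) / 2,
                 x_edges = xe, y_edges = ye, counts = counts,
                 dg_kt = dg, dg_kjmol = dg * kT,
                 temperature = temperature),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat("free-energy landscape:", length(x$x_mid), "x", length(x$y_mid),
      "bins,", sum(x$counts), "samples, T =", x$temperature, "K\n")
  cat("  occupied bins:", sum(!is.na(x$dg_kt)),
      "; max dG =", round(max(x$dg_kt, na.rm = TRUE), 2), "kT\n")
  invisible(x)
}

#' Image plot of a free-energy landscape
#' @param x `fel_grid`.
#' @param unit "kt" or "kjmol".
#' @param ... passed to [graphics::image()].
#' @export
plot.fel_grid <- function(x, unit = c("kt", "kjmol"), ...) {
  unit <- match.arg(unit)
  z <- if (unit == "kt") x$dg_kt else x$dg_kjmol
  graphics::image(x$x_mid, x$y_mid, z, xlab = "PC1 (A)", ylab = "PC2 (A)",
                  col = grDevices::hcl.colors(40, "viridis", rev = TRUE), ...)
  invisible(x)
}

#' Pearson correlation of projections with descriptor columns
#'
#' Convenience report relating PC projections to heuristic channel
#' descriptors over the same set of structures.
#'
#' @param projections `pc_projection` rows (one per structure).
#' @param descriptors data.frame of descriptor values (same row order).
#' @param n_modes how many components to correlate (default 2).
#' @return matrix of correlations, modes x descriptors.
#' @export
correlate_descriptors <- function(projections, descriptors, n_modes = 2) {
  pcs <- as.matrix(projections[, paste0("pc", seq_len(n_modes)), drop = FALSE])
  dd <- as.matrix(descriptors)
  stats::cor(pcs, dd)
}
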