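## Elastic-network normal modes on C-alpha beads. Two force fields are
## provided: a plain cutoff ANM (uniform springs within a distance cutoff)
## and a sequence-distance calibrated variant in which close sequence
## neighbours get stiff springs decaying as the inverse squared sequence
## separation and spatial pairs get springs decaying with the sixth power
## of distance. The network potential is harmonic in the pair distances,
## E = 1/2 sum_ij K_ij (R_ij - R0_ij)^2, so K_ij is the literal spring
## constant and the Hessian super-blocks at the minimum are
## H_ij = -K_ij (r^ x r^).

#' Build an elastic network on C-alpha coordinates
#'
#' @param x coordinates: `structure3d`, `ca_set`, or N x 3 matrix. Chain
#'   identity (for the sequential-spring rule) is taken from the labels
#'   when present, else all beads are treated as one chain.
#' @param force_field "edenm" (sequence-calibrated, the default) or
#'   "cutoff" (uniform springs).
#' @param cutoff distance cutoff for the uniform force field, Angstrom.
#' @param k_uniform uniform spring constant, kcal/mol/A^2.
#' @param c_seq sequential spring scale: pairs with sequence separation
#'   s <= 3 in the same chain get K = c_seq / s^2 (kcal/mol/A^2).
#' @param c_cart spatial spring distance scale, Angstrom: other pairs
#'   within `spatial_cap` get K = (c_cart / R0)^6 kcal/mol/A^2, i.e. unit
#'   stiffness at R0 = c_cart decaying with the sixth power of distance.
#' @param spatial_cap distance cap for spatial springs, Angstrom.
#' @return object of class `elastic_network`: `coords` (N x 3), `pairs`
#'   (data.frame i/j/k/r0), `force_field`, `labels`.
#' @export
build_network <- function(x, force_field = c("edenm", "cutoff"),
                          cutoff = 10, k_uniform = 1,
                          c_seq = 60, c_cart = 6, spatial_cap = 12) {
  force_field <- match.arg(force_field)
  ca <- as_ca(x)
  coords <- ca$coords
  n <- nrow(coords)
  if (n < 3) stop("build_network: need >= 3 nodes")
  # collinearity check
  cc <- scale(coords, scale = FALSE)
  ev <- eigen(crossprod(cc), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-8 * max(ev[1], 1))
    stop("build_network: nodes are collinear; network would be degenerate")
  D <- as.matrix(stats::dist(coords))
  chain <- ca$labels$chain %||% rep("A", n)
  resno <- ca$labels$resno %||% seq_len(n)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  r0 <- D[ut]
  if (force_field == "cutoff") {
    keep <- r0 <= cutoff
    k <- rep(k_uniform, sum(keep))
    pairs <- data.frame(i = i[keep], j = j[keep], k = k, r0 = r0[keep])
  } else {
    same_chain <- chain[i] == chain[j]
    sep <- abs(resno[i] - resno[j])
    seq_pair <- same_chain & sep >= 1 & sep <= 3
    spat_pair <- !seq_pair & r0 <= spatial_cap
    k <- numeric(length(r0))
    k[seq_pair] <- c_seq / sep[seq_pair]^2
    k[spat_pair] <- (c_cart / r0[spat_pair])^6
    keep <- seq_pair | spat_pair
    pairs <- data.frame(i = i[keep], j = j[keep], k = k[keep], r0 = r0[keep])
  }
  # connectivity: single rigid cluster required
  g <- igraph::graph_from_edgelist(as.matrix(pairs[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- sort(comp$csize, decreasing = TRUE)
    stop("build_network: network is disconnected (", comp$no,
         " components of sizes ", paste(sizes, collapse = ", "), ")")
  }
  structure(list(coords = coords, pairs = pairs, force_field = force_field,
                 labels = ca$labels),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("elastic_network (", x$force_field, "): ", nrow(x$coords), " nodes, ",
      nrow(x$pairs), " springs\n", sep = "")
  cat("  spring constants: ", signif(min(x$pairs$k), 3), " .. ",
      signif(max(x$pairs$k), 3), " kcal/mol/A^2\n", sep = "")
  invisible(x)
}

#' Harmonic network energy at arbitrary coordinates
#'
#' E = 1/2 sum K_ij (R_ij - R0_ij)^2 over the network pair list. Used by
#' the finite-difference consistency checks of the Hessian.
#'
#' @param network `elastic_network`.
#' @param coords N x 3 coordinates (default: the network's own coordinates,
#'   giving zero).
#' @return energy, kcal/mol.
#' @export
network_energy <- function(network, coords = network$coords) {
  p <- network$pairs
  d <- sqrt(rowSums((coords[p$i, , drop = FALSE] -
                     coords[p$j, , drop = FALSE])^2))
  0.5 * sum(p$k * (d - p$r0)^2)
}

#' Hessian of the elastic-network energy
#'
#' Standard anisotropic-network super-element structure: the off-diagonal
#' 3x3 block for a connected pair is -K_ij times the outer product of the
#' unit inter-node vector; diagonal blocks make every row block sum to zero
#' (translation invariance).
#'
#' @param network `elastic_network`.
#' @return 3N x 3N symmetric matrix (kcal/mol/A^2).
#' @export
hessian <- function(network) {
  coords <- network$coords
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  p <- network$pairs
  for (e in seq_len(nrow(p))) {
    i <- p$i[e]; j <- p$j[e]
    u <- coords[j, ] - coords[i, ]
    u <- u / sqrt(sum(u^2))
    blk <- p$k[e] * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  (H + t(H)) / 2
}

#' Normal modes of an elastic network
#'
#' Diagonalizes the Hessian, removes the six rigid-body zero modes (a
#' connected, non-linear 3D network has exactly six) and returns the
#' remaining modes softest-first.
#'
#' @param x `elastic_network` or a precomputed symmetric Hessian matrix.
#' @param zero_tol relative tolerance for zero eigenvalues (fraction of the
#'   largest eigenvalue).
#' @param n_zero_expected expected rigid-body zero modes: 6 for any
#'   non-linear 3D network (the default); pass 5 for strictly collinear
#'   systems such as a two-bead dimer, whose rotation about the bond axis
#'   is degenerate.
#' @return object of class `normal_mode_set`: `eigenvalues` (ascending,
#'   kcal/mol/A^2), `modes` (3N x K orthonormal columns, softest first),
#'   `n_zero`, `all_eigenvalues`.
#' @export
normal_modes <- function(x, zero_tol = 1e-9, n_zero_expected = 6) {
  H <- if (inherits(x, "elastic_network")) hessian(x) else as.matrix(x)
  if (max(abs(H - t(H))) > 1e-9) stop("normal_modes: Hessian not symmetric")
  e <- eigen(H, symmetric = TRUE)
  vals <- rev(e$values)                       # ascending
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  if (min(vals) < -1e-8 * max(abs(vals)))
    stop("normal_modes: significantly negative eigenvalue; not a minimum")
  nz_tol <- zero_tol * max(vals)
  n_zero <- sum(abs(vals) < nz_tol)
  if (n_zero != n_zero_expected)
    stop("normal_modes: expected exactly ", n_zero_expected,
         " zero modes, found ", n_zero,
         " (disconnected or degenerate network?)")
  keep <- (n_zero + 1):length(vals)
  structure(list(eigenvalues = vals[keep],
                 modes = vecs[, keep, drop = FALSE],
                 n_zero = n_zero, all_eigenvalues = vals),
            class = "normal_mode_set")
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat("normal_mode_set:", ncol(x$modes), "modes (6 zero modes removed)\n")
  cat("  softest eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 3), collapse = " "), "\n")
  invisible(x)
}

#' Convert normal modes to the shared `modeset` container
#'
#' ENM modes become interchangeable with PCA/ED modes for the overlap
#' metrics; pseudo-eigenvalues are the inverse stiffness 1/lambda (softest
#' mode first and largest, mirroring the variance ordering of PCA modes).
#'
#' @param nms `normal_mode_set`.
#' @param reference reference coordinates stored as the mode-set mean.
#' @return `modeset` with provenance "ENM".
#' @export
as_modeset <- function(nms, reference = NULL) {
  stopifnot(inherits(nms, "normal_mode_set"))
  inv <- 1 / nms$eigenvalues
  structure(list(modes = nms$modes, eigenvalues = inv,
                 variance_fraction = inv / sum(inv),
                 mean = if (is.null(reference)) NULL else ref_vec(reference),
                 n_res = nrow(nms$modes) / 3,
                 provenance = "ENM"),
            class = "modeset")
}

#' Residue thermal fluctuations from normal modes
#'
#' Mean-square fluctuation of residue i is kT times the trace of the i-th
#' 3x3 diagonal block of the Hessian pseudo-inverse (zero modes excluded);
#' pairwise correlations are the block traces normalized to [-1, 1].
#'
#' @param nms `normal_mode_set`.
#' @param temperature Kelvin.
#' @return list: `msf` (per-residue mean-square fluctuation, A^2),
#'   `correlation` (N x N normalized cross-correlation matrix),
#'   `temperature`.
#' @export
fluctuations <- function(nms, temperature = 300) {
  stopifnot(inherits(nms, "normal_mode_set"))
  kT <- 0.0019872041 * temperature   # kcal/mol
  V <- nms$modes
  w <- 1 / nms$eigenvalues
  n <- nrow(V) / 3
  # C = kT * V diag(w) V^T, needed only as per-residue 3x3 block traces
  Vw <- sweep(V, 2, sqrt(w), "*")
  # trace of block (i,j) = sum over xyz of row-block products
  msf <- numeric(n)
  blocktr <- matrix(0, n, n)
  for (a in 1:3) {
    rows <- seq(a, 3 * n, by = 3)
    blocktr <- blocktr + tcrossprod(Vw[rows, , drop = FALSE])
  }
  blocktr <- kT * blocktr
  msf <- diag(blocktr)
  corr <- blocktr / sqrt(outer(msf, msf))
  list(msf = msf, correlation = corr, temperature = temperature)
}
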