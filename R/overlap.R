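## Similarity between mode spaces (ENM / ED / ensemble-PCA) and
## experimental transition vectors.

#' Normalized transition vector between two conformations
#'
#' The second structure is optimally superposed onto the first, then the
#' 3N-dimensional coordinate difference is normalized to unit length. The
#' pre-normalization magnitude equals the post-fit RMSD times sqrt(N).
#' Rigid-body components (numerically residual after the fit) are
#' projected out by default so that comparisons against ENM modes, which
#' exclude the six zero modes, are not inflated.
#'
#' @param structureA,structureB structures or N x 3 coordinate matrices
#'   mapped to the same residue core (same row order).
#' @param remove_rigid project the 6 rigid-body directions of A out of the
#'   difference before normalizing (default TRUE).
#' @return object of class `transition_vector`: `dr` (unit 3N vector),
#'   `magnitude` (Angstrom, before normalization), `rmsd` (post-fit).
#' @export
transition_vector <- function(structureA, structureB, remove_rigid = TRUE) {
  a <- as_ca(structureA)$coords
  b <- as_ca(structureB)$coords
  if (!all(dim(a) == dim(b)))
    stop("transition_vector: structures do not share a residue core")
  fit <- superpose(b, a)
  d <- mat2vec(fit$coords) - mat2vec(a)
  mag <- sqrt(sum(d^2))
  if (mag < 1e-9)
    stop("transition_vector: structures are identical; direction undefined")
  if (remove_rigid) {
    B <- rigid_body_basis(a)
    d <- d - B %*% crossprod(B, d)
  }
  structure(list(dr = as.numeric(d / sqrt(sum(d^2))), magnitude = mag,
                 rmsd = fit$rmsd),
            class = "transition_vector")
}

#' @export
print.transition_vector <- function(x, ...) {
  cat("transition_vector: |R2 - R1| =", round(x$magnitude, 3),
      "A (RMSD", round(x$rmsd, 3), "A) over",
      length(x$dr) / 3, "residues\n")
  invisible(x)
}

## coerce to a unit numeric vector
unit_vec <- function(v) {
  if (inherits(v, "transition_vector")) v <- v$dr
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("zero vector has no direction")
  v / n
}

#' Overlap (absolute angle cosine) between a transition vector and a mode
#'
#' @param dr `transition_vector` or numeric 3N vector.
#' @param mode numeric 3N vector (a mode); normalized internally.
#' @return overlap in [0, 1]; 1 means parallel directions.
#' @export
mode_overlap <- function(dr, mode) {
  a <- unit_vec(dr); b <- unit_vec(mode)
  if (length(a) != length(b)) stop("mode_overlap: dimension mismatch")
  abs(sum(a * b))
}

#' Cumulative overlap of the first M modes with a transition vector
#'
#' Root sum of squared per-mode overlaps over the first M modes:
#' delta(M) = sqrt(sum_k alpha_k^2), non-decreasing in M and bounded by 1
#' for orthonormal modes.
#'
#' @param dr `transition_vector` or numeric 3N vector.
#' @param modeset `modeset`, `normal_mode_set`, or 3N x K mode matrix with
#'   modes in columns (most important first).
#' @param M number of modes to accumulate (default 10).
#' @param per_mode also return the per-mode overlaps.
#' @return cumulative overlap (numeric), or a list with `delta` and
#'   `alpha` when `per_mode = TRUE`.
#' @export
cumulative_overlap <- function(dr, modeset, M = 10, per_mode = FALSE) {
  V <- if (inherits(modeset, "modeset") || inherits(modeset, "normal_mode_set"))
    modeset$modes else as.matrix(modeset)
  if (M < 1 || M > ncol(V))
    stop("cumulative_overlap: M must be between 1 and ", ncol(V))
  a <- unit_vec(dr)
  if (length(a) != nrow(V)) stop("cumulative_overlap: dimension mismatch")
  Vm <- V[, seq_len(M), drop = FALSE]
  cn <- sqrt(colSums(Vm^2))
  alpha <- abs(as.numeric(a %*% Vm)) / cn
  delta <- sqrt(sum(alpha^2))
  if (per_mode) list(delta = delta, alpha = alpha) else delta
}
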