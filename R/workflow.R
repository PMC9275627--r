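## High-level driver for analysing an experimental structural ensemble:
## common core, PCA with variance fractions, projections onto PC1-2,
## per-structure pore radii, and mode-transition overlaps between chosen
## state representatives. This is the deterministic end of the pipeline:
## given a directory of curated PDB files it reproduces ensemble-level
## numbers (PC variance fractions, mean RMSD to the reference, gate
## radii, ENM overlap between states) with no randomness.

#' Ensemble analysis report for a set of PDB structures
#'
#' Builds the common C-alpha core across all structures, superposes them
#' onto the reference, runs PCA, projects every member onto the leading
#' components, and (optionally) computes pore profiles and ENM
#' mode-transition overlaps between named state representatives.
#'
#' @param paths character vector of PDB file paths (>= 2), or an
#'   `ensemble` already built with [build_core()].
#' @param reference id (file base name) or index of the reference
#'   structure; default the first.
#' @param n_modes how many PC projections to report (default 5).
#' @param pore_for ids for which a full-structure pore profile and minimum
#'   radius are computed (default none; can be slow for large proteins).
#' @param overlap_pairs optional 2-column matrix/data.frame of id pairs;
#'   for each pair the ED-ENM 10-mode cumulative overlap of the first
#'   member's modes with the transition toward the second is computed.
#' @param enm_modes number of soft modes used in the overlaps (default 10).
#' @return list of class `ensemble_report`: `ensemble`, `pca` (modeset),
#'   `variance_fraction`, `projections` (data.frame id/pc1/pc2/...),
#'   `mean_rmsd_to_reference`, `pore` (per-id min radius, or NULL),
#'   `overlaps` (per-pair delta, or NULL).
#' @export
ensemble_report <- function(paths, reference = 1, n_modes = 5,
                            pore_for = character(0), overlap_pairs = NULL,
                            enm_modes = 10) {
  if (inherits(paths, "ensemble")) {
    ens <- paths
  } else {
    ids <- sub("\\.[^.]*$", "", basename(paths))
    structs <- lapply(paths, read_structure)
    ref_idx <- if (is.character(reference)) match(reference, ids)
    else as.integer(reference)
    if (is.na(ref_idx)) stop("ensemble_report: reference not found")
    ens <- build_core(structs, reference = ref_idx, ids = ids)
  }
  ms <- fit_pca(ens)
  k <- min(n_modes, ncol(ms$modes))
  pj <- project(ens, ms, ens$ref_coords, fit = FALSE, n_modes = k)
  pj <- cbind(id = ens$ids, pj)
  pore <- NULL
  if (length(pore_for)) {
    pore <- vapply(pore_for, function(id) {
      i <- match(id, ens$ids)
      if (is.na(i)) return(NA_real_)
      co <- vec2mat(ens$xyz[i, ])
      suppressWarnings(pore_profile(co)$min_radius)
    }, numeric(1))
  }
  overlaps <- NULL
  if (!is.null(overlap_pairs)) {
    op <- as.matrix(overlap_pairs)
    overlaps <- data.frame(from = op[, 1], to = op[, 2],
                           delta = NA_real_, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(op))) {
      i <- match(op[r, 1], ens$ids); j <- match(op[r, 2], ens$ids)
      if (is.na(i) || is.na(j)) next
      a <- vec2mat(ens$xyz[i, ]); b <- vec2mat(ens$xyz[j, ])
      lab <- ens$core
      ca_a <- structure(list(coords = a, labels = lab,
                             xyz = ens$xyz[i, , drop = FALSE],
                             skipped = NULL), class = "ca_set")
      nm <- normal_modes(build_network(ca_a))
      tv <- transition_vector(a, b)
      overlaps$delta[r] <- cumulative_overlap(tv, as_modeset(nm),
                                              M = enm_modes)
    }
  }
  structure(list(ensemble = ens, pca = ms,
                 variance_fraction = ms$variance_fraction,
                 projections = pj,
                 mean_rmsd_to_reference =
                   mean(ens$fit_rmsd[-ens$reference]),
                 pore = pore, overlaps = overlaps),
            class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat("ensemble_report:", nrow(x$ensemble$xyz), "structures,",
      nrow(x$ensemble$core), "core residues\n")
  vf <- x$variance_fraction
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%%, PC1-2 %.1f%% of variance\n",
              100 * vf[1], 100 * vf[2], 100 * sum(vf[1:2])))
  cat(sprintf("  mean RMSD to reference: %.2f A\n",
              x$mean_rmsd_to_reference))
  if (!is.null(x$pore)) {
    cat("  min pore radii (A):\n")
    for (id in names(x$pore))
      cat(sprintf("    %s: %.2f\n", id, x$pore[[id]]))
  }
  if (!is.null(x$overlaps)) {
    cat("  ENM 10-mode overlaps with transitions:\n")
    for (r in seq_len(nrow(x$overlaps)))
      cat(sprintf("    %s -> %s: %.2f\n", x$overlaps$from[r],
                  x$overlaps$to[r], x$overlaps$delta[r]))
  }
  invisible(x)
}
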