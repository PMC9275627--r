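## Frame-wise trajectory analysis: RMSD series, GROMOS-style conformational
## clustering (largest-neighbourhood-first), essential dynamics, C-alpha
## helicity, and polar-contact persistence.

## coerce trajectory-like inputs to a frames x 3N matrix (+labels)
as_traj <- function(x) {
  if (inherits(x, "ca_traj")) return(x)
  if (inherits(x, "structure3d")) {
    ca <- extract_calpha(x)
    return(structure(list(xyz = ca$xyz, labels = ca$labels),
                     class = "ca_traj"))
  }
  if (inherits(x, "ca_set"))
    return(structure(list(xyz = x$xyz, labels = x$labels), class = "ca_traj"))
  if (is.matrix(x)) {
    if (ncol(x) == 3)          # a single N x 3 structure, not frames x 3N
      return(structure(list(xyz = matrix(mat2vec(x), nrow = 1),
                            labels = NULL), class = "ca_traj"))
    return(structure(list(xyz = x, labels = NULL), class = "ca_traj"))
  }
  stop("expected a trajectory (ca_traj, multi-frame structure3d, or matrix)")
}

sel_cols <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(ncol(traj$xyz)))
  if (is.null(traj$labels)) stop("selection requires residue labels")
  rows <- which(traj$labels$resno %in% selection)
  if (!length(rows)) stop("selection matches no residues")
  as.vector(rbind(3 * rows - 2, 3 * rows - 1, 3 * rows))
}

#' Per-frame RMSD to a reference structure
#'
#' Each frame is rigid-body superposed onto the reference over the
#' selection before the RMSD is taken.
#'
#' @param trajectory `ca_traj`, multi-frame `structure3d`, or frames x 3N
#'   matrix.
#' @param reference reference coordinates (N x 3, 3N vector, or structure).
#' @param selection optional residue numbers to restrict the comparison.
#' @param breaks histogram breaks (passed to [graphics::hist()]).
#' @return list of class `rmsd_series`: `rmsd` (Angstrom, per frame),
#'   `histogram`.
#' @export
rmsd_series <- function(trajectory, reference, selection = NULL,
                        breaks = "Sturges") {
  traj <- as_traj(trajectory)
  cols <- sel_cols(traj, selection)
  rv <- ref_vec(reference)
  if (length(rv) == ncol(traj$xyz)) rv <- rv[cols]
  if (length(rv) != length(cols))
    stop("rmsd_series: reference does not match the selection")
  refm <- vec2mat(rv)
  r <- vapply(seq_len(nrow(traj$xyz)), function(f)
    superpose(vec2mat(traj$xyz[f, cols]), refm)$rmsd, numeric(1))
  structure(list(rmsd = r,
                 histogram = graphics::hist(r, breaks = breaks, plot = FALSE)),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat("rmsd_series:", length(x$rmsd), "frames; mean",
      round(mean(x$rmsd), 3), "A, max", round(max(x$rmsd), 3), "A\n")
  invisible(x)
}

## pairwise RMSD matrix with per-pair superposition
pairwise_rmsd <- function(xyz) {
  n <- nrow(xyz)
  D <- matrix(0, n, n)
  mats <- lapply(seq_len(n), function(i) vec2mat(xyz[i, ]))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- superpose(mats[[j]], mats[[i]])$rmsd
  }
  D
}

#' GROMOS-style conformational clustering
#'
#' Iterative largest-neighbourhood clustering on the pairwise-fitted RMSD
#' matrix: the frame with the most neighbours within `cutoff` becomes the
#' representative of cluster 1 together with those neighbours; all are
#' removed and the procedure repeats. Ties in neighbour count are broken
#' toward the lowest frame index. Cluster sizes are non-increasing by
#' construction.
#'
#' @param trajectory frames to cluster.
#' @param cutoff RMSD cutoff, Angstrom (default 2.0, i.e. 0.20 nm).
#' @param selection optional residue filter.
#' @return list of class `cluster_result`: `assignment` (cluster id per
#'   frame), `clusters` (data.frame id/size/representative/fraction),
#'   `cutoff`.
#' @export
gromos_cluster <- function(trajectory, cutoff = 2.0, selection = NULL) {
  traj <- as_traj(trajectory)
  cols <- sel_cols(traj, selection)
  xyz <- traj$xyz[, cols, drop = FALSE]
  n <- nrow(xyz)
  if (n < 1) stop("gromos_cluster: need at least 1 frame")
  D <- pairwise_rmsd(xyz)
  active <- rep(TRUE, n)
  assignment <- integer(n)
  reps <- integer(0); sizes <- integer(0)
  cl <- 0L
  while (any(active)) {
    cl <- cl + 1L
    idx <- which(active)
    nb <- vapply(idx, function(i) sum(D[i, idx] <= cutoff), integer(1))
    center <- idx[which.max(nb)]          # which.max: first max = lowest index
    members <- idx[D[center, idx] <= cutoff]
    assignment[members] <- cl
    active[members] <- FALSE
    reps <- c(reps, center); sizes <- c(sizes, length(members))
  }
  structure(list(assignment = assignment,
                 clusters = data.frame(id = seq_len(cl), size = sizes,
                                       representative = reps,
                                       fraction = sizes / n),
                 cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", nrow(x$clusters), "clusters at cutoff",
      x$cutoff, "A\n")
  print(utils::head(x$clusters, 10))
  invisible(x)
}

#' Essential dynamics of a trajectory
#'
#' PCA of the trajectory coordinates after rigid-body superposition of
#' every frame onto a reference (default: the first frame), tagged with
#' provenance "ED" so the modes are interchangeable with ENM modes in the
#' overlap metrics.
#'
#' @param trajectory frames to analyse.
#' @param reference superposition reference (default first frame).
#' @param selection optional residue filter.
#' @return `modeset` with provenance "ED".
#' @export
essential_dynamics <- function(trajectory, reference = NULL,
                               selection = NULL) {
  traj <- as_traj(trajectory)
  cols <- sel_cols(traj, selection)
  xyz <- traj$xyz[, cols, drop = FALSE]
  if (nrow(xyz) < 2) stop("essential_dynamics: need >= 2 frames")
  rv <- if (is.null(reference)) xyz[1, ] else {
    r <- ref_vec(reference)
    if (length(r) == ncol(traj$xyz)) r[cols] else r
  }
  refm <- vec2mat(rv)
  fitted <- t(vapply(seq_len(nrow(xyz)), function(f)
    mat2vec(superpose(vec2mat(xyz[f, ]), refm)$coords),
    numeric(ncol(xyz))))
  fit_pca(fitted, provenance = "ED")
}

ca_pseudo_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  # sign: right-handed alpha geometry gives ~ +50 degrees
  -atan2(sum(m1 * n2) / b2n, sum(n1 * n2)) * 180 / pi
}

#' C-alpha helicity of a residue range
#'
#' A 4-residue window i..i+3 counts as helical when the C-alpha i to i+3
#' distance lies in [4.5, 5.5] Angstrom and the C-alpha pseudo-dihedral is
#' in [35, 65] degrees (both satisfied by ideal alpha geometry, neither by
#' extended chain). Helicity is the fraction of helical windows in the
#' range, per frame.
#'
#' @param trajectory frames (or a single structure).
#' @param residue_range residue numbers forming the stretch (>= 5
#'   residues), evaluated per chain.
#' @param chain optional single chain to restrict to.
#' @return numeric vector, helicity in [0, 1] per frame.
#' @export
helicity <- function(trajectory, residue_range, chain = NULL) {
  traj <- as_traj(trajectory)
  if (is.null(traj$labels)) {
    labels <- data.frame(chain = "A", resno = seq_len(ncol(traj$xyz) / 3))
  } else labels <- traj$labels
  if (length(residue_range) < 5) stop("helicity: range too short (< 5 residues)")
  chains <- if (is.null(chain)) unique(labels$chain) else chain
  vapply(seq_len(nrow(traj$xyz)), function(f) {
    co <- vec2mat(traj$xyz[f, ])
    hel <- 0L; tot <- 0L
    for (ch in chains) {
      rows <- which(labels$chain == ch & labels$resno %in% residue_range)
      rows <- rows[order(labels$resno[rows])]
      if (length(rows) < 4) next
      rn <- labels$resno[rows]
      for (k in seq_len(length(rows) - 3)) {
        if (rn[k + 3] - rn[k] != 3) next      # require consecutive residues
        tot <- tot + 1L
        d13 <- sqrt(sum((co[rows[k + 3], ] - co[rows[k], ])^2))
        if (d13 < 4.5 || d13 > 5.5) next
        dih <- ca_pseudo_dihedral(co[rows[k], ], co[rows[k + 1], ],
                                  co[rows[k + 2], ], co[rows[k + 3], ])
        if (dih >= 35 && dih <= 65) hel <- hel + 1L
      }
    }
    if (tot == 0) return(NA_real_)
    hel / tot
  }, numeric(1))
}

#' Polar contacts and their persistence over a trajectory
#'
#' With full-atom coordinates, salt bridges are charged-group centroid
#' pairs within `sb_cutoff` (Asp/Glu carboxylates versus Lys/Arg/His
#' amines) and hydrogen bonds are donor-acceptor heavy-atom pairs within
#' `hb_cutoff` (no angle criterion without hydrogens). With C-alpha-only
#' input the method falls back to C-alpha proxy contacts within
#' `ca_cutoff`. Persistence is the fraction of frames in which the
#' contact's distance criterion holds; candidate pairs are those satisfied
#' in at least one frame.
#'
#' @param x `structure3d` (single- or multi-frame).
#' @param sb_cutoff salt-bridge centroid cutoff, Angstrom.
#' @param hb_cutoff hydrogen-bond heavy-atom cutoff, Angstrom.
#' @param ca_cutoff C-alpha proxy contact cutoff, Angstrom.
#' @param min_seq_sep minimum sequence separation within a chain.
#' @return data.frame of class `contact_table`: per contact `chain_i`,
#'   `res_i`, `chain_j`, `res_j`, `type` ("salt_bridge", "hbond" or
#'   "ca_proxy"), `persistence`, `min_distance`; attribute `mode` records
#'   whether full-atom or C-alpha criteria were used.
#' @export
polar_contacts <- function(x, sb_cutoff = 4.0, hb_cutoff = 3.5,
                           ca_cutoff = 8.0, min_seq_sep = 3) {
  stopifnot(inherits(x, "structure3d"))
  prot <- !(x$atom$is_water %||% FALSE) & !(x$atom$is_ion %||% FALSE)
  a <- x$atom[prot, , drop = FALSE]
  arow <- which(prot)                 # original row -> xyz column mapping
  nf <- nrow(x$xyz)
  polar_names <- c("OD1", "OD2", "OE1", "OE2", "NZ", "NH1", "NH2", "NE",
                   "ND1", "NE2", "OG", "OG1", "OH", "ND2", "N", "O")
  full_atom <- any(a$elety %in% polar_names)
  coords_f <- function(f, rows) {
    orows <- arow[rows]
    vec2mat(x$xyz[f, as.vector(rbind(3 * orows - 2, 3 * orows - 1,
                                     3 * orows))])
  }
  mk_table <- function(pairs, type, cutoff) {
    if (!nrow(pairs)) return(NULL)
    pers <- numeric(nrow(pairs)); mind <- rep(Inf, nrow(pairs))
    for (f in seq_len(nf)) {
      for (p in seq_len(nrow(pairs))) {
        ci <- colMeans(coords_f(f, pairs$rows_i[[p]]))
        cj <- colMeans(coords_f(f, pairs$rows_j[[p]]))
        d <- sqrt(sum((ci - cj)^2))
        mind[p] <- min(mind[p], d)
        if (d <= cutoff) pers[p] <- pers[p] + 1
      }
    }
    keep <- pers > 0
    if (!any(keep)) return(NULL)
    data.frame(chain_i = pairs$chain_i[keep], res_i = pairs$res_i[keep],
               chain_j = pairs$chain_j[keep], res_j = pairs$res_j[keep],
               type = type, persistence = pers[keep] / nf,
               min_distance = mind[keep], stringsAsFactors = FALSE)
  }
  res_key <- paste(a$chain, a$resno, sep = "|")
  out <- NULL
  if (full_atom) {
    acidic <- c(ASP = "OD1|OD2", GLU = "OE1|OE2")
    basic <- c(LYS = "NZ", ARG = "NH1|NH2|NE", HIS = "ND1|NE2")
    neg_keys <- unique(res_key[a$resid %in% names(acidic)])
    pos_keys <- unique(res_key[a$resid %in% names(basic)])
    pairs <- list()
    for (nk in neg_keys) for (pk in pos_keys) {
      ri <- which(res_key == nk & grepl(acidic[[a$resid[res_key == nk][1]]], a$elety))
      rj <- which(res_key == pk & grepl(basic[[a$resid[res_key == pk][1]]], a$elety))
      if (!length(ri) || !length(rj)) next
      pairs[[length(pairs) + 1L]] <- list(
        chain_i = a$chain[ri[1]], res_i = a$resno[ri[1]],
        chain_j = a$chain[rj[1]], res_j = a$resno[rj[1]],
        rows_i = ri, rows_j = rj)
    }
    if (length(pairs)) {
      pdf <- data.frame(chain_i = vapply(pairs, `[[`, "", "chain_i"),
                        res_i = vapply(pairs, `[[`, 0, "res_i"),
                        chain_j = vapply(pairs, `[[`, "", "chain_j"),
                        res_j = vapply(pairs, `[[`, 0, "res_j"))
      pdf$rows_i <- lapply(pairs, `[[`, "rows_i")
      pdf$rows_j <- lapply(pairs, `[[`, "rows_j")
      out <- mk_table(pdf, "salt_bridge", sb_cutoff)
    }
    # hydrogen bonds: donor/acceptor heavy atoms (side-chain + backbone N/O)
    don_acc <- which(a$elety %in% polar_names)
    if (length(don_acc) >= 2) {
      co <- as.matrix(a[don_acc, c("x", "y", "z")])
      D <- as.matrix(stats::dist(co))
      ut <- which(upper.tri(D) & D <= hb_cutoff + 2, arr.ind = TRUE)
      hb <- list()
      for (r in seq_len(nrow(ut))) {
        i <- don_acc[ut[r, 1]]; j <- don_acc[ut[r, 2]]
        if (a$chain[i] == a$chain[j] &&
            abs(a$resno[i] - a$resno[j]) < min_seq_sep) next
        hb[[length(hb) + 1L]] <- list(chain_i = a$chain[i], res_i = a$resno[i],
                                      chain_j = a$chain[j], res_j = a$resno[j],
                                      rows_i = i, rows_j = j)
      }
      if (length(hb)) {
        hdf <- data.frame(chain_i = vapply(hb, `[[`, "", "chain_i"),
                          res_i = vapply(hb, `[[`, 0, "res_i"),
                          chain_j = vapply(hb, `[[`, "", "chain_j"),
                          res_j = vapply(hb, `[[`, 0, "res_j"))
        hdf$rows_i <- lapply(hb, `[[`, "rows_i")
        hdf$rows_j <- lapply(hb, `[[`, "rows_j")
        out <- rbind(out, mk_table(hdf, "hbond", hb_cutoff))
      }
    }
    mode <- "full_atom"
  } else {
    ca_rows <- which(a$elety == "CA")
    co <- as.matrix(a[ca_rows, c("x", "y", "z")])
    D <- as.matrix(stats::dist(co))
    ut <- which(upper.tri(D) & D <= ca_cutoff + 3, arr.ind = TRUE)
    pr <- list()
    for (r in seq_len(nrow(ut))) {
      i <- ca_rows[ut[r, 1]]; j <- ca_rows[ut[r, 2]]
      if (a$chain[i] == a$chain[j] &&
          abs(a$resno[i] - a$resno[j]) < min_seq_sep) next
      pr[[length(pr) + 1L]] <- list(chain_i = a$chain[i], res_i = a$resno[i],
                                    chain_j = a$chain[j], res_j = a$resno[j],
                                    rows_i = i, rows_j = j)
    }
    out <- NULL
    if (length(pr)) {
      pdf <- data.frame(chain_i = vapply(pr, `[[`, "", "chain_i"),
                        res_i = vapply(pr, `[[`, 0, "res_i"),
                        chain_j = vapply(pr, `[[`, "", "chain_j"),
                        res_j = vapply(pr, `[[`, 0, "res_j"))
      pdf$rows_i <- lapply(pr, `[[`, "rows_i")
      pdf$rows_j <- lapply(pr, `[[`, "rows_j")
      out <- mk_table(pdf, "ca_proxy", ca_cutoff)
    }
    mode <- "ca_proxy"
  }
  if (is.null(out))
    out <- data.frame(chain_i = character(0), res_i = integer(0),
                      chain_j = character(0), res_j = integer(0),
                      type = character(0), persistence = numeric(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("contact_table", "data.frame")
  out
}
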