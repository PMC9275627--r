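## Heuristic channel descriptors: quaternary twist, ECD blooming, TM2
## tilt/twist, pore-radius profile and gate radii, hydration, and ion
## permeation. All descriptors assume the pore/symmetry axis is along +z
## (see orient_pore_axis) and are invariant to global rotation about z and
## to global translation.

#' Orient a structure so the pore axis lies along +z
#'
#' Rotates the coordinates so that the principal inertia axis of the TMD
#' C-alphas (the symmetry axis of the helix bundle: the covariance
#' eigenvector whose eigenvalue is most separated from the other two) maps
#' to +z, and centers the TMD at the origin.
#'
#' @param x `structure3d`.
#' @param channel_def `channel_def` (TMD residue range).
#' @return reoriented `structure3d`.
#' @export
orient_pore_axis <- function(x, channel_def) {
  ca <- extract_calpha(x)
  tmd <- ca$coords[ca$labels$resno %in% channel_def$tmd, , drop = FALSE]
  ctr <- colMeans(tmd)
  cc <- sweep(tmd, 2, ctr)
  e <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  # pick the eigenvalue most distinct from the other two (C5 bundle: the
  # two in-plane eigenvalues are nearly equal)
  v <- e$values
  sep <- vapply(1:3, function(k) min(abs(v[k] - v[-k])), numeric(1))
  ax <- e$vectors[, which.max(sep)]
  # orient toward the ECD side
  ecd <- ca$coords[ca$labels$resno %in% channel_def$ecd, , drop = FALSE]
  if (nrow(ecd) && sum((colMeans(ecd) - ctr) * ax) < 0) ax <- -ax
  z <- c(0, 0, 1)
  cr <- c(ax[2] * z[3] - ax[3] * z[2], ax[3] * z[1] - ax[1] * z[3],
          ax[1] * z[2] - ax[2] * z[1])
  R <- if (sqrt(sum(cr^2)) < 1e-12) diag(3) else
    rotation_matrix(cr, acos(min(max(sum(ax * z), -1), 1)))
  out <- x
  for (f in seq_len(nrow(x$xyz))) {
    m <- sweep(vec2mat(x$xyz[f, ]), 2, ctr) %*% t(R)
    out$xyz[f, ] <- mat2vec(m)
  }
  out$atom$x <- out$xyz[1, seq(1, ncol(out$xyz), 3)]
  out$atom$y <- out$xyz[1, seq(2, ncol(out$xyz), 3)]
  out$atom$z <- out$xyz[1, seq(3, ncol(out$xyz), 3)]
  out
}

## per-chain C-alpha coordinates for a resno range
chain_coords <- function(ca, chain, resnos) {
  sel <- ca$labels$chain == chain & ca$labels$resno %in% resnos
  ca$coords[sel, , drop = FALSE]
}

#' Quaternary twist of a pentamer
#'
#' Per subunit, the signed XY-plane angle (right-handed about +z) between
#' the vector from the overall center of mass to the TMD center of mass
#' and the vector to the ECD center of mass; the reported value is the
#' circular mean over the five subunits. Positive values mean the ECD is
#' rotated counter-clockwise (viewed from the extracellular side) relative
#' to the TMD.
#'
#' @param x `structure3d` (oriented pore axis along +z).
#' @param channel_def `channel_def`.
#' @return twist in degrees, with per-subunit values in attribute
#'   `per_subunit`.
#' @export
quaternary_twist <- function(x, channel_def) {
  ca <- as_ca(x)
  chains <- unique(ca$labels$chain)
  if (length(chains) != 5) stop("quaternary_twist: expected 5 chains")
  cm_all <- colMeans(ca$coords)
  per <- vapply(chains, function(ch) {
    ecd <- chain_coords(ca, ch, channel_def$ecd)
    tmd <- chain_coords(ca, ch, channel_def$tmd)
    if (!nrow(ecd) || !nrow(tmd))
      stop("quaternary_twist: chain ", ch, " missing domain residues")
    signed_xy_angle(colMeans(tmd) - cm_all, colMeans(ecd) - cm_all)
  }, numeric(1))
  out <- circular_mean_deg(per)
  attr(out, "per_subunit") <- per
  out
}

#' ECD blooming radius
#'
#' Default ("pairwise"): half the maximum pairwise C-alpha distance among
#' the extracellular tip residues of the five subunits — for five tips on
#' a circle of radius R this is R sin(72 deg). Alternative ("axis"): the
#' maximum in-plane distance of a tip residue from the pore axis (taken
#' through the XY centroid of all C-alphas).
#'
#' @param x `structure3d`.
#' @param channel_def `channel_def` (`tip_residues`).
#' @param method "pairwise" (default) or "axis".
#' @return blooming radius, Angstrom.
#' @export
blooming <- function(x, channel_def, method = c("pairwise", "axis")) {
  method <- match.arg(method)
  ca <- as_ca(x)
  tips <- ca$coords[ca$labels$resno %in% channel_def$tip_residues, ,
                    drop = FALSE]
  if (nrow(tips) < 2) stop("blooming: fewer than 2 tip residues")
  if (method == "pairwise") {
    max(stats::dist(tips)) / 2
  } else {
    ctr <- colMeans(ca$coords)[1:2]
    max(sqrt((tips[, 1] - ctr[1])^2 + (tips[, 2] - ctr[2])^2))
  }
}

#' TM2 tilt and twist angles
#'
#' Per subunit, a local right-handed frame is built with Z the pore axis
#' (+z), X the in-plane unit vector from the protein center of mass to the
#' TM2 helix center of mass (the radial direction), and Y = Z x X (the
#' tangential direction). The TM2 helical axis (bisector cross-product
#' estimator, oriented +z-ward; see [helix_axis()]) is expressed in this
#' frame; tilt is the signed angle between its XZ-plane projection and Z
#' (positive = leaning outward), twist the signed angle between its
#' YZ-plane projection and Z.
#'
#' @param x `structure3d` (oriented pore axis along +z).
#' @param channel_def `channel_def`.
#' @param reference optional reference structure; when supplied, the radial
#'   (X) direction of each subunit frame is taken from the reference
#'   geometry after superposing it onto `x`, which stabilizes the frame for
#'   strongly deformed structures.
#' @return data.frame with per-subunit `chain`, `tilt`, `twist` (degrees)
#'   and attributes `mean_tilt`, `mean_twist` (circular means).
#' @export
tm2_angles <- function(x, channel_def, reference = NULL) {
  ca <- as_ca(x)
  frame_ca <- ca
  if (!is.null(reference)) {
    rc <- as_ca(reference)
    fit <- superpose(rc$coords, ca$coords)
    frame_ca <- rc; frame_ca$coords <- fit$coords
  }
  chains <- unique(ca$labels$chain)
  cm_prot <- colMeans(frame_ca$coords)
  res <- lapply(chains, function(ch) {
    tm2 <- chain_coords(ca, ch, channel_def$tm2)
    if (nrow(tm2) < 6) stop("tm2_angles: TM2 of chain ", ch, " too short")
    ax <- helix_axis(tm2)
    cm_h <- colMeans(chain_coords(frame_ca, ch, channel_def$tm2))
    X <- c(cm_h[1] - cm_prot[1], cm_h[2] - cm_prot[2], 0)
    nx <- sqrt(sum(X^2))
    if (nx < 1e-9) stop("tm2_angles: degenerate radial direction for chain ", ch)
    X <- X / nx
    Z <- c(0, 0, 1)
    Y <- c(Z[2] * X[3] - Z[3] * X[2], Z[3] * X[1] - Z[1] * X[3],
           Z[1] * X[2] - Z[2] * X[1])
    al <- c(sum(ax * X), sum(ax * Y), sum(ax * Z))
    data.frame(chain = ch,
               tilt = atan2(al[1], al[3]) * 180 / pi,
               twist = atan2(al[2], al[3]) * 180 / pi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "mean_tilt") <- circular_mean_deg(out$tilt)
  attr(out, "mean_twist") <- circular_mean_deg(out$twist)
  out
}

## largest clearance at one z slice: max over candidate circle centres of
## min over slab atoms of (in-plane distance - atom radius). The candidate
## domain is a fixed box of half-width `search_half` about the pore-axis
## guess `start` (the search must be bounded: outside the helix ring the
## clearance grows without limit), scanned coarsely and then refined on
## two finer grids clamped to the same box.
slice_radius <- function(xy, start, atom_radius, search_half = 4) {
  eval_grid <- function(gx, gy) {
    mind <- NULL
    for (a in seq_len(nrow(xy))) {
      d <- sqrt((gx - xy[a, 1])^2 + (gy - xy[a, 2])^2)
      mind <- if (is.null(mind)) d else pmin(mind, d)
    }
    k <- which.max(mind)
    c(gx[k], gy[k], mind[k] - atom_radius)
  }
  # coarse pass over the full bounded box (the clearance landscape is
  # multimodal; a fine global grid avoids local basins)
  g <- seq(-search_half, search_half, by = 0.1)
  gx <- start[1] + rep(g, times = length(g))
  gy <- start[2] + rep(g, each = length(g))
  best <- eval_grid(gx, gy)
  # two refinement passes about the winner, clamped to the box
  for (step in c(0.02, 0.004)) {
    g <- seq(-6 * step, 6 * step, by = step)
    gx <- best[1] + rep(g, times = length(g))
    gy <- best[2] + rep(g, each = length(g))
    keep <- abs(gx - start[1]) <= search_half &
      abs(gy - start[2]) <= search_half
    if (!any(keep)) break
    cand <- eval_grid(gx[keep], gy[keep])
    if (cand[3] > best[3]) best <- cand
  }
  best
}

#' Pore-radius profile along the channel axis
#'
#' Deterministic inscribed-circle profile: the z range of the selected
#' atoms is sliced every `step` Angstrom; within each slab (half-width =
#' `step`) the radius is the largest clearance `min(in-plane distance to
#' atom) - atom_radius` over candidate circle centres, found by a coarse
#' grid around the previous slice's centre followed by two grid-refinement
#' passes. Slices with no atoms in the slab, or fully blocked (negative
#' clearance), are masked.
#'
#' @param x `structure3d` (pore axis along +z) or N x 3 coordinate matrix.
#' @param selection optional residue numbers to restrict the atom set
#'   (e.g. the TM2 range for an M2-only profile).
#' @param step z step, Angstrom (default 0.5; slab half-width = step).
#' @param atom_radius effective C-alpha radius, Angstrom (default 1.9,
#'   united-atom scale).
#' @param zlim optional explicit z range.
#' @return object of class `pore_profile`: data.frame `profile`
#'   (z, radius, cx, cy), `min_radius`, `step`, `atom_radius`.
#' @export
pore_profile <- function(x, selection = NULL, step = 0.5, atom_radius = 1.9,
                         zlim = NULL) {
  if (step <= 0) stop("pore_profile: step must be > 0")
  ca <- as_ca(x)
  coords <- ca$coords
  if (!is.null(selection)) {
    if (is.null(ca$labels)) stop("pore_profile: selection needs residue labels")
    coords <- coords[ca$labels$resno %in% selection, , drop = FALSE]
  }
  if (!nrow(coords)) stop("pore_profile: empty atom selection")
  if (is.null(zlim)) zlim <- range(coords[, 3])
  zs <- seq(zlim[1], zlim[2], by = step)
  ctr0 <- colMeans(coords)[1:2]
  out <- data.frame(z = zs, radius = NA_real_, cx = NA_real_, cy = NA_real_)
  any_empty <- FALSE
  for (i in seq_along(zs)) {
    slab <- abs(coords[, 3] - zs[i]) <= step
    if (!any(slab)) { any_empty <- TRUE; next }
    b <- slice_radius(coords[slab, 1:2, drop = FALSE], ctr0, atom_radius)
    if (b[3] >= 0) {
      out$radius[i] <- b[3]; out$cx[i] <- b[1]; out$cy[i] <- b[2]
    }
  }
  if (any_empty) warning("pore_profile: some z slices had no atoms; masked")
  structure(list(profile = out,
                 min_radius = if (all(is.na(out$radius))) NA_real_
                 else min(out$radius, na.rm = TRUE),
                 step = step, atom_radius = atom_radius),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("pore_profile:", nrow(x$profile), "slices, step", x$step, "A\n")
  cat("  min radius:", round(x$min_radius, 3), "A\n")
  invisible(x)
}

#' @export
plot.pore_profile <- function(x, ...) {
  graphics::plot(x$profile$z, x$profile$radius, type = "l",
                 xlab = "z (A)", ylab = "pore radius (A)", ...)
  invisible(x)
}

#' Mean pore radius around a gate position
#'
#' Averages the profile radius over a symmetric z window centred on the
#' gate residues' center-of-mass z (default +/- 2.5 Angstrom).
#'
#' @param profile `pore_profile`.
#' @param gate_z z of the gate residue center of mass, Angstrom.
#' @param window half-window, Angstrom.
#' @return mean radius over the window, Angstrom.
#' @export
radius_at_gate <- function(profile, gate_z, window = 2.5) {
  stopifnot(inherits(profile, "pore_profile"))
  z <- profile$profile$z
  if (gate_z - window < min(z) - profile$step / 2 ||
      gate_z + window > max(z) + profile$step / 2)
    stop("radius_at_gate: window extends outside the profile range")
  sel <- z >= gate_z - window & z <= gate_z + window
  r <- profile$profile$radius[sel]
  if (all(is.na(r))) stop("radius_at_gate: window fully masked")
  mean(r, na.rm = TRUE)
}

#' Count water oxygens inside the pore cylinder
#'
#' @param waters n x 3 matrix of water-oxygen coordinates (or a
#'   `structure3d`, whose water records are used).
#' @param cylinder list(radius, zlim, center = c(x, y)).
#' @return integer count.
#' @export
hydration_count <- function(waters, cylinder) {
  if (inherits(waters, "structure3d")) {
    a <- waters$atom
    sel <- a$is_water & a$elety %in% c("O", "OW", "OH2")
    if (!any(sel)) sel <- a$is_water
    waters <- as.matrix(a[sel, c("x", "y", "z")])
  }
  if (is.null(dim(waters)) || nrow(waters) == 0) {
    warning("hydration_count: no waters in frame")
    return(0L)
  }
  ctr <- cylinder$center %||% c(0, 0)
  inplane <- sqrt((waters[, 1] - ctr[1])^2 + (waters[, 2] - ctr[2])^2)
  sum(inplane <= cylinder$radius &
        waters[, 3] >= cylinder$zlim[1] & waters[, 3] <= cylinder$zlim[2])
}

#' Per-frame hydration of a solvated trajectory
#' @param solvated `solvated_traj` from [make_solvated_frames()].
#' @param cylinder optional cylinder override.
#' @return integer vector, one count per frame.
#' @export
hydration_series <- function(solvated, cylinder = NULL) {
  stopifnot(inherits(solvated, "solvated_traj"))
  cyl <- cylinder %||% solvated$cylinder
  rep(hydration_count(solvated$waters, cyl), solvated$n_frames)
}

#' Ion z-traces, permeation events and pore occupancy
#'
#' A permeation event is an ion that enters the pore cylinder through one
#' z boundary and exits through the opposite boundary without leaving the
#' cylinder laterally in between. Entries or exits through the cylinder
#' wall reset the ion's transit.
#'
#' @param solvated `solvated_traj`, or an array frames x n_ions x 3 of ion
#'   coordinates (then `species` and `cylinder` must be given).
#' @param cylinder list(radius, zlim, center); default from the object.
#' @param species optional species filter.
#' @param hist_breaks number of z-histogram bins (default 30).
#' @return list: `traces` (frames x n_ions z matrix), `events` (data.frame
#'   ion/species/frame/direction), `n_events`, `z_histogram` (per species).
#' @export
ion_tracking <- function(solvated, cylinder = NULL, species = NULL,
                         hist_breaks = 30) {
  if (inherits(solvated, "solvated_traj")) {
    ions <- solvated$ions; sp <- solvated$species
    cyl <- cylinder %||% solvated$cylinder
  } else {
    ions <- solvated; sp <- attr(solvated, "species")
    cyl <- cylinder
    if (is.null(cyl)) stop("ion_tracking: cylinder required")
  }
  n_ions <- dim(ions)[2]
  keep <- if (is.null(species)) seq_len(n_ions) else which(sp %in% species)
  ctr <- cyl$center %||% c(0, 0)
  zmin <- cyl$zlim[1]; zmax <- cyl$zlim[2]
  events <- list()
  traces <- if (n_ions) matrix(ions[, , 3], ncol = n_ions) else
    matrix(numeric(0), nrow = dim(ions)[1])
  for (i in keep) {
    x <- ions[, i, 1]; y <- ions[, i, 2]; z <- ions[, i, 3]
    lat_in <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2) <= cyl$radius
    z_in <- z >= zmin & z <= zmax
    inside <- lat_in & z_in
    entered_from <- NA_character_
    for (f in seq_along(inside)[-1]) {
      if (!inside[f - 1] && inside[f]) {
        # entry: classify by where the ion came from
        entered_from <- if (!z_in[f - 1] && z[f - 1] > zmax) "top"
        else if (!z_in[f - 1] && z[f - 1] < zmin) "bottom"
        else NA_character_           # lateral entry: cannot permeate
      } else if (inside[f - 1] && !inside[f]) {
        exit_via <- if (!z_in[f] && z[f] > zmax) "top"
        else if (!z_in[f] && z[f] < zmin) "bottom"
        else "lateral"
        if (!is.na(entered_from) && exit_via != "lateral" &&
            exit_via != entered_from) {
          events[[length(events) + 1L]] <-
            data.frame(ion = i, species = sp[i] %||% NA_character_,
                       frame = f,
                       direction = paste0(entered_from, "->", exit_via),
                       stringsAsFactors = FALSE)
        }
        entered_from <- NA_character_
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(ion = integer(0), species = character(0), frame = integer(0),
               direction = character(0), stringsAsFactors = FALSE)
  # z occupancy histogram per species (frames where the ion is in the pore)
  zh <- list()
  for (s in unique(sp[keep])) {
    zs <- c()
    for (i in keep[sp[keep] == s]) {
      x <- ions[, i, 1]; y <- ions[, i, 2]; z <- ions[, i, 3]
      insd <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2) <= cyl$radius &
        z >= zmin & z <= zmax
      zs <- c(zs, z[insd])
    }
    zh[[s]] <- if (length(zs))
      graphics::hist(zs, breaks = seq(zmin, zmax, length.out = hist_breaks + 1),
                     plot = FALSE) else NULL
  }
  list(traces = traces, events = ev, n_events = nrow(ev), z_histogram = zh)
}

#' Full descriptor record for one structure
#'
#' @param x `structure3d` (pore axis along +z).
#' @param channel_def `channel_def`.
#' @param pore_selection residue numbers for the pore profile (default: all).
#' @return one-row data.frame: `quaternary_twist`, `bloom`, `tm2_tilt`,
#'   `tm2_twist`, `min_pore_radius`, `radius_at_9prime`.
#' @export
descriptor_record <- function(x, channel_def, pore_selection = NULL) {
  ca <- as_ca(x)
  qt <- quaternary_twist(x, channel_def)
  bl <- blooming(x, channel_def)
  ang <- tm2_angles(x, channel_def)
  pp <- pore_profile(x, selection = pore_selection)
  z9 <- mean(ca$coords[ca$labels$resno == channel_def$res_9prime, 3])
  r9 <- tryCatch(radius_at_gate(pp, z9), error = function(e) NA_real_)
  data.frame(quaternary_twist = as.numeric(qt),
             bloom = bl,
             tm2_tilt = attr(ang, "mean_tilt"),
             tm2_twist = attr(ang, "mean_twist"),
             min_pore_radius = pp$min_radius,
             radius_at_9prime = r9)
}
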