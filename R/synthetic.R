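## Synthetic C5-symmetric toy pentamers with known ground truth.
##
## The generator builds a minimal pLGIC-like fold: per subunit an ECD
## modelled as one long ideal alpha-helix leaning outward to an
## "extracellular tip", and a TMD of four ideal transmembrane helices
## (TM1-TM4) with TM2 lining the central pore. Deformations that mimic the
## gating motions of real channels (quaternary twist, ECD blooming, TM2
## tilt/twist) are applied with known magnitudes so that descriptor and
## mode-recovery code can be validated against construction parameters.

#' Parameters for the toy pentamer generator
#'
#' @param n_res_ecd residues per subunit extracellular domain.
#' @param n_res_per_helix residues per transmembrane helix.
#' @param helix_rise helical rise, Angstrom per residue (ideal alpha: 1.5).
#' @param helix_turn helical turn, degrees per residue (ideal alpha: 100).
#' @param helix_radius C-alpha helix radius, Angstrom (ideal alpha: 2.3).
#' @param ecd_radius distance of the ECD tip beads from the symmetry axis, Angstrom.
#' @param tm2_axis_radius distance of each TM2 helical axis from the pore axis, Angstrom.
#' @param quaternary_twist rotation of the ECD about z relative to the TMD, degrees.
#' @param bloom radial ECD expansion, Angstrom.
#' @param tm2_tilt TM2 axis lean in its radial plane, degrees (outward positive).
#' @param tm2_twist TM2 axis lean in its tangential plane, degrees.
#' @param noise_sigma isotropic Gaussian noise per C-alpha coordinate, Angstrom.
#' @param seed integer RNG seed used when noise is drawn.
#' @return object of class `pentamer_params`.
#' @export
pentamer_params <- function(n_res_ecd = 28, n_res_per_helix = 18,
                            helix_rise = 1.5, helix_turn = 100,
                            helix_radius = 2.3,
                            ecd_radius = 25, tm2_axis_radius = 8,
                            quaternary_twist = 0, bloom = 0,
                            tm2_tilt = 0, tm2_twist = 0,
                            noise_sigma = 0, seed = 1L) {
  p <- list(n_res_ecd = as.integer(n_res_ecd),
            n_res_per_helix = as.integer(n_res_per_helix),
            helix_rise = helix_rise, helix_turn = helix_turn,
            helix_radius = helix_radius,
            ecd_radius = ecd_radius, tm2_axis_radius = tm2_axis_radius,
            quaternary_twist = quaternary_twist, bloom = bloom,
            tm2_tilt = tm2_tilt, tm2_twist = tm2_twist,
            noise_sigma = noise_sigma, seed = as.integer(seed))
  if (p$n_res_ecd < 1 || p$n_res_per_helix < 1)
    stop("pentamer_params: residue counts must be >= 1")
  if (p$helix_rise <= 0) stop("pentamer_params: helix_rise must be > 0")
  if (p$ecd_radius <= 0 || p$tm2_axis_radius <= 0 || p$helix_radius <= 0)
    stop("pentamer_params: radii must be > 0")
  if (p$noise_sigma < 0) stop("pentamer_params: noise_sigma must be >= 0")
  class(p) <- "pentamer_params"
  p
}

## one ideal helix: n beads wound about a straight axis.
## origin: first axis point; dir: unit axis; u,v: unit vectors completing a
## right-handed frame with dir. "down" traverses the same bead positions in
## reverse residue order (keeps right-handed helical geometry).
ideal_helix <- function(n, origin, dir, rise, turn_deg, radius, phase0 = 0,
                        direction = c("up", "down")) {
  direction <- match.arg(direction)
  dir <- dir / sqrt(sum(dir^2))
  # frame perpendicular to dir
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * dir) * dir; u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  j <- 0:(n - 1)
  ph <- (phase0 + j * turn_deg) * pi / 180
  pts <- outer(j * rise, dir) + outer(radius * cos(ph), u) +
    outer(radius * sin(ph), v)
  pts <- sweep(pts, 2, origin, "+")
  if (direction == "down") pts <- pts[n:1, , drop = FALSE]
  pts
}

## Build one undeformed subunit in the local frame (radial = +x). Returns a
## list of per-segment N x 3 blocks in residue order, plus segment ranges.
build_subunit <- function(p) {
  n_h <- p$n_res_per_helix
  tm_top <- (n_h - 1) * p$helix_rise          # TMD spans z in [0, tm_top]
  # ECD: one helix leaning outward; residue 1 at the extracellular tip.
  n_e <- p$n_res_ecd
  L <- max((n_e - 1) * p$helix_rise, 1e-6)
  base_r <- 13                                  # ECD base radius, Angstrom
  z0 <- tm_top + 6.5                            # ECD base height
  s <- (p$ecd_radius - base_r) / L
  s <- max(min(s, 0.95), -0.95)
  dir <- c(s, 0, sqrt(1 - s^2))                 # leans outward, runs up
  ecd_up <- ideal_helix(n_e, c(base_r, 0, z0), dir, p$helix_rise,
                        p$helix_turn, p$helix_radius)
  ecd <- ecd_up[n_e:1, , drop = FALSE]          # residue 1 on top (tip)
  hx <- function(r, ang_deg, direction, phase0 = 0) {
    a <- ang_deg * pi / 180
    ideal_helix(n_h, c(r * cos(a), r * sin(a), 0), c(0, 0, 1),
                p$helix_rise, p$helix_turn, p$helix_radius,
                phase0 = phase0, direction = direction)
  }
  tm1 <- hx(15.5, -22, "down", 0)
  tm2 <- hx(p$tm2_axis_radius, 0, "up", 180)    # pore-facing
  tm3 <- hx(15.5, 22, "down", 90)
  tm4 <- hx(22, 0, "up", 45)
  # align the ECD and TMD centre-of-mass azimuths exactly to the subunit
  # direction (+x), so a zero programmed quaternary twist measures as zero
  derot <- function(blocks, phi) {
    R <- rot_z(-phi * 180 / pi)
    lapply(blocks, function(b) b %*% t(R))
  }
  cm_e <- colMeans(ecd)
  ecd <- derot(list(ecd), atan2(cm_e[2], cm_e[1]))[[1]]
  tmd <- rbind(tm1, tm2, tm3, tm4)
  cm_t <- colMeans(tmd)
  tmb <- derot(list(tm1 = tm1, tm2 = tm2, tm3 = tm3, tm4 = tm4),
               atan2(cm_t[2], cm_t[1]))
  list(ecd = ecd, tm1 = tmb$tm1, tm2 = tmb$tm2, tm3 = tmb$tm3, tm4 = tmb$tm4)
}

## segment residue ranges within one chain (1-based)
segment_ranges <- function(p) {
  n_e <- p$n_res_ecd; n_h <- p$n_res_per_helix
  ecd <- 1:n_e
  tm1 <- (n_e + 1):(n_e + n_h)
  tm2 <- (n_e + n_h + 1):(n_e + 2 * n_h)
  tm3 <- (n_e + 2 * n_h + 1):(n_e + 3 * n_h)
  tm4 <- (n_e + 3 * n_h + 1):(n_e + 4 * n_h)
  list(ecd = ecd, tm1 = tm1, tm2 = tm2, tm3 = tm3, tm4 = tm4,
       tmd = c(tm1, tm2, tm3, tm4))
}

#' Channel definition for toy pentamers
#'
#' Residue ranges (per subunit, shared across the 5 chains) for the domains
#' and gates the channel descriptors need. TM2 primed positions are indexed
#' from the intracellular end with -2' at the first TM2 residue, so the 9'
#' activation gate sits 11 residues above the TM2 start.
#' @param params `pentamer_params`.
#' @return list of class `channel_def` with elements `ecd`, `tmd`,
#'   `tm1`..`tm4`, `tip_residues`, `res_9prime`, `res_minus2prime`.
#' @export
toy_channel_def <- function(params) {
  sr <- segment_ranges(params)
  cd <- list(ecd = sr$ecd, tmd = sr$tmd, tm1 = sr$tm1, tm2 = sr$tm2,
             tm3 = sr$tm3, tm4 = sr$tm4,
             tip_residues = 1L,
             res_minus2prime = sr$tm2[1],
             res_9prime = sr$tm2[1] + 11L)
  class(cd) <- "channel_def"
  cd
}

#' Build a C5-symmetric toy pentamer with known ground truth
#'
#' Constructs the five chains (A-E, counter-clockwise viewed from +z, the
#' pore/symmetry axis) by 72-degree rotations of one subunit, applies the
#' programmed quaternary twist / bloom / TM2 tilt / TM2 twist deformations,
#' then adds isotropic Gaussian noise. Ground-truth descriptor values are
#' recorded from the noise-free deformed coordinates.
#'
#' @param params `pentamer_params`.
#' @return list with `structure` (class `structure3d`, C-alpha only),
#'   `ground_truth` (list: `true_quaternary_twist`, `true_bloom`,
#'   `true_tm2_tilt`, `true_tm2_twist`, `true_min_pore_radius`,
#'   `tip_radius`), `channel_def` and `params`.
#' @export
make_toy_pentamer <- function(params = pentamer_params()) {
  p <- params
  if (!inherits(p, "pentamer_params")) p <- do.call(pentamer_params, as.list(p))
  seg <- build_subunit(p)
  sr <- segment_ranges(p)
  n_chain <- length(unlist(sr[c("ecd", "tm1", "tm2", "tm3", "tm4")])) / 2 # unused guard
  # deform TM2 in the local frame: axis target a ~ (tan tilt, tan twist, 1)
  if (p$tm2_tilt != 0 || p$tm2_twist != 0) {
    a <- c(tan(p$tm2_tilt * pi / 180), tan(p$tm2_twist * pi / 180), 1)
    a <- a / sqrt(sum(a^2))
    z <- c(0, 0, 1)
    ax <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
            z[1] * a[2] - z[2] * a[1])
    if (sqrt(sum(ax^2)) > 1e-12) {
      R <- rotation_matrix(ax, acos(min(max(sum(z * a), -1), 1)))
      ctr <- colMeans(seg$tm2)
      seg$tm2 <- sweep(sweep(seg$tm2, 2, ctr) %*% t(R), 2, ctr, "+")
    }
  }
  # ECD deformations in the local frame: bloom = radial push from the pore
  # axis; quaternary twist applied after chain placement (global z rotation).
  if (p$bloom != 0) {
    xy <- seg$ecd[, 1:2, drop = FALSE]
    r <- sqrt(rowSums(xy^2)); r[r < 1e-9] <- 1e-9
    seg$ecd[, 1:2] <- xy * (1 + p$bloom / r)
  }
  sub <- rbind(seg$ecd, seg$tm1, seg$tm2, seg$tm3, seg$tm4)
  n_res <- nrow(sub)
  chains <- LETTERS[1:5]
  coords <- matrix(0, 5 * n_res, 3)
  for (k in 0:4) {
    Rk <- rot_z(72 * k)
    coords[k * n_res + seq_len(n_res), ] <- sub %*% t(Rk)
  }
  atom <- data.frame(type = "ATOM",
                     eleno = seq_len(5 * n_res),
                     elety = "CA",
                     resid = "ALA",
                     chain = rep(chains, each = n_res),
                     resno = rep(seq_len(n_res), 5),
                     insert = "",
                     o = 1, b = 0,
                     stringsAsFactors = FALSE)
  # quaternary twist: rotate all ECD beads about the global z axis
  if (p$quaternary_twist != 0) {
    is_ecd <- atom$resno %in% sr$ecd
    coords[is_ecd, ] <- coords[is_ecd, , drop = FALSE] %*% t(rot_z(p$quaternary_twist))
  }
  cd <- toy_channel_def(p)
  gt <- list(
    true_quaternary_twist = p$quaternary_twist,
    true_bloom = p$bloom,
    true_tm2_tilt = rep(p$tm2_tilt, 5),
    true_tm2_twist = rep(p$tm2_twist, 5),
    tip_radius = {
      tip <- coords[atom$resno %in% cd$tip_residues, , drop = FALSE]
      mean(sqrt(rowSums(tip[, 1:2, drop = FALSE]^2)))
    },
    true_min_pore_radius = axis_min_pore_radius(coords, atom, cd),
    planted_mutation_hotspots = integer(0),
    permeation_event_count = 0L)
  if (p$noise_sigma > 0) {
    set.seed(p$seed)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, p$noise_sigma),
                              ncol = 3)
  }
  atom$x <- coords[, 1]; atom$y <- coords[, 2]; atom$z <- coords[, 3]
  st <- new_structure3d(atom, source = "make_toy_pentamer")
  list(structure = st, ground_truth = gt, channel_def = cd, params = p)
}

## on-axis minimum pore radius of the noise-free construction, using the
## same z step / slab conventions as pore_profile(); by C5 symmetry the
## widest inscribed circle of the ideal geometry is centred on the axis.
axis_min_pore_radius <- function(coords, atom, cd, step = 0.5,
                                 atom_radius = 1.9) {
  sel <- atom$resno %in% cd$tmd
  xyz <- coords[sel, , drop = FALSE]
  zr <- range(coords[atom$resno %in% cd$tm2, 3])
  zs <- seq(zr[1], zr[2], by = step)
  rho <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  rmin <- Inf
  for (z0 in zs) {
    in_slab <- abs(xyz[, 3] - z0) <= step
    if (!any(in_slab)) next
    rmin <- min(rmin, min(rho[in_slab]) - atom_radius)
  }
  max(rmin, 0)
}

#' Ensemble of toy-pentamer states with planted deformations
#'
#' Generates `n_per_state` noisy replicas of each programmed state. A state
#' is the base parameter set plus a named deformation delta (any of
#' `quaternary_twist`, `bloom`, `tm2_tilt`, `tm2_twist`).
#'
#' @param base `pentamer_params` for the undeformed state.
#' @param state_deltas list of named numeric vectors, one per state
#'   (>= 2 states).
#' @param n_per_state replicas per state (>= 1).
#' @param noise_sigma Gaussian noise added to every replica, Angstrom.
#' @param seed RNG seed.
#' @return list with `xyz` (members x 3N coordinate matrix), `state`
#'   (factor per member), `labels` (chain/resno per atom), `states`
#'   (per-state ground truth), `channel_def`.
#' @export
make_state_ensemble <- function(base = pentamer_params(), state_deltas,
                                n_per_state = 1, noise_sigma = 0, seed = 1) {
  if (length(state_deltas) < 2) stop("make_state_ensemble: need >= 2 states")
  if (n_per_state < 1) stop("make_state_ensemble: n_per_state must be >= 1")
  set.seed(seed)
  states <- vector("list", length(state_deltas))
  rows <- list(); lab <- NULL; st_id <- character(0)
  for (s in seq_along(state_deltas)) {
    d <- state_deltas[[s]]
    ps <- as.list(base)
    for (nm in names(d)) {
      if (!nm %in% c("quaternary_twist", "bloom", "tm2_tilt", "tm2_twist"))
        stop("make_state_ensemble: unknown deformation '", nm, "'")
      ps[[nm]] <- ps[[nm]] + d[[nm]]
    }
    ps$noise_sigma <- 0
    tp <- make_toy_pentamer(do.call(pentamer_params, ps))
    states[[s]] <- tp$ground_truth
    ca <- extract_calpha(tp$structure)
    if (is.null(lab)) lab <- ca$labels
    base_vec <- mat2vec(ca$coords)
    for (r in seq_len(n_per_state)) {
      v <- base_vec
      if (noise_sigma > 0) v <- v + stats::rnorm(length(v), 0, noise_sigma)
      rows[[length(rows) + 1L]] <- v
      st_id <- c(st_id, names(state_deltas)[s] %||% paste0("state", s))
    }
  }
  xyz <- do.call(rbind, rows)
  list(xyz = xyz, state = factor(st_id, levels = unique(st_id)),
       labels = lab, states = states,
       channel_def = toy_channel_def(if (inherits(base, "pentamer_params"))
         base else do.call(pentamer_params, as.list(base))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear-interpolation transition trajectory between two states
#'
#' Frame k (k = 0..n-1) is `A + k/(n-1) * (B - A)` plus isotropic Gaussian
#' noise; frame 0 is A and the last frame is B (up to noise).
#'
#' @param stateA,stateB structures (`structure3d`) or C-alpha coordinate
#'   matrices with identical residue maps.
#' @param n_frames number of frames (>= 2).
#' @param noise_sigma per-coordinate Gaussian noise, Angstrom.
#' @param seed RNG seed.
#' @return object of class `ca_traj`: list with `xyz` (frames x 3N) and
#'   `labels`.
#' @export
make_transition_trajectory <- function(stateA, stateB, n_frames = 11,
                                       noise_sigma = 0, seed = 1) {
  ca_a <- as_ca(stateA); ca_b <- as_ca(stateB)
  if (!is.null(ca_a$labels) && !is.null(ca_b$labels)) {
    if (!identical(ca_a$labels[c("chain", "resno")],
                   ca_b$labels[c("chain", "resno")]))
      stop("make_transition_trajectory: residue maps of A and B differ")
  } else if (nrow(ca_a$coords) != nrow(ca_b$coords)) {
    stop("make_transition_trajectory: residue maps of A and B differ")
  }
  if (n_frames < 2) stop("make_transition_trajectory: need >= 2 frames")
  va <- mat2vec(ca_a$coords); vb <- mat2vec(ca_b$coords)
  set.seed(seed)
  tfrac <- seq(0, 1, length.out = n_frames)
  xyz <- t(vapply(tfrac, function(f) {
    v <- (1 - f) * va + f * vb
    if (noise_sigma > 0) v <- v + stats::rnorm(length(v), 0, noise_sigma)
    v
  }, numeric(length(va))))
  structure(list(xyz = xyz, labels = ca_a$labels), class = "ca_traj")
}

#' Mutation and conservation tables with planted 3D hotspots
#'
#' Emulates a somatic-mutation export (`position,allele,count`) and a
#' conservation table (`position,score`, integer grades 1-9) for one
#' subunit sequence, with elevated counts planted at chosen hotspot
#' residues and Poisson background elsewhere. Hotspot positions get the
#' top conservation grade so that conservation weighting retains them.
#'
#' @param structure toy pentamer `structure3d` (positions refer to per-chain
#'   residue numbers).
#' @param hotspot_residues integer residue positions carrying planted signal.
#' @param hotspot_counts counts added at each hotspot (recycled).
#' @param background_rate Poisson mean of the per-position background count.
#' @param conservation optional integer vector (1-9) per position; default:
#'   uniform random grades with hotspots set to 9.
#' @param seed RNG seed.
#' @param dir optional directory; when given, `mutations.csv` and
#'   `conservation.tsv` are written there.
#' @return list with `mutations` (data.frame position/allele/count),
#'   `conservation` (position/score), `ground_truth`
#'   (`planted_mutation_hotspots`) and `files` (paths or NULL).
#' @export
make_mutation_scan <- function(structure, hotspot_residues, hotspot_counts = 5,
                               background_rate = 0.1, conservation = NULL,
                               seed = 1, dir = NULL) {
  ca <- as_ca(structure)
  pos_all <- sort(unique(ca$labels$resno))
  if (!all(hotspot_residues %in% pos_all))
    stop("make_mutation_scan: hotspot residues not present in structure")
  hotspot_counts <- rep_len(hotspot_counts, length(hotspot_residues))
  if (any(hotspot_counts < 0) || background_rate < 0)
    stop("make_mutation_scan: counts and rates must be >= 0")
  set.seed(seed)
  n <- length(pos_all)
  counts <- stats::rpois(n, background_rate)
  names(counts) <- pos_all
  counts[as.character(hotspot_residues)] <-
    counts[as.character(hotspot_residues)] + hotspot_counts
  if (is.null(conservation)) {
    conservation <- sample(1:9, n, replace = TRUE)
    names(conservation) <- pos_all
    conservation[as.character(hotspot_residues)] <- 9L
  } else {
    conservation <- rep_len(as.integer(conservation), n)
    names(conservation) <- pos_all
  }
  aa <- c("A", "V", "L", "S", "T", "R", "K", "D", "E", "G", "P", "M", "W")
  rows <- list()
  for (i in seq_len(n)) {
    if (counts[i] == 0) next
    n_alleles <- if (counts[i] >= 3) sample(1:2, 1) else 1L
    split <- if (n_alleles == 2) {
      a <- sample(seq_len(counts[i] - 1), 1); c(a, counts[i] - a)
    } else counts[i]
    subs <- paste0(sample(aa, n_alleles), pos_all[i],
                   sample(aa, n_alleles))
    rows[[length(rows) + 1L]] <-
      data.frame(position = pos_all[i], allele = subs, count = split,
                 stringsAsFactors = FALSE)
  }
  mut <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), allele = character(0),
               count = integer(0))
  rownames(mut) <- NULL
  cons <- data.frame(position = pos_all, score = as.integer(conservation))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fm <- file.path(dir, "mutations.csv")
    fc <- file.path(dir, "conservation.tsv")
    utils::write.csv(mut, fm, row.names = FALSE, quote = FALSE)
    utils::write.table(cons, fc, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(mutations = fm, conservation = fc)
  }
  list(mutations = mut, conservation = cons,
       ground_truth = list(planted_mutation_hotspots = sort(hotspot_residues)),
       files = files)
}

#' Ion path constructors for solvated toy trajectories
#'
#' `ion_path_cross` programs one full permeation: the ion enters through one
#' z boundary and exits through the opposite one while staying on the pore
#' axis. `ion_path_retreat` programs an entry followed by a retreat through
#' the same boundary (no permeation). `ion_path_custom` takes an explicit
#' z(t) (and optional xy(t)) with the number of genuine crossings declared
#' by the caller.
#'
#' @param species ion species label ("K", "CL", "NA").
#' @param from which boundary the ion enters through ("top" or "bottom").
#' @param t0,t1 fractions of the trajectory (0-1) over which the motion runs.
#' @param depth for retreats: how far into the pore (fraction of pore
#'   height) the ion reaches before turning back.
#' @param z numeric vector of z positions (recycled/interpolated to the
#'   frame count).
#' @param xy length-2 lateral position, or an n x 2 matrix.
#' @param crossings number of full crossings the custom path performs.
#' @return list of class `ion_path`.
#' @name ion_paths
#' @export
ion_path_cross <- function(species = "K", from = c("top", "bottom"),
                           t0 = 0.1, t1 = 0.9) {
  from <- match.arg(from)
  structure(list(kind = "cross", species = species, from = from,
                 t0 = t0, t1 = t1, crossings = 1L), class = "ion_path")
}

#' @rdname ion_paths
#' @export
ion_path_retreat <- function(species = "K", from = c("top", "bottom"),
                             t0 = 0.1, t1 = 0.9, depth = 0.5) {
  from <- match.arg(from)
  structure(list(kind = "retreat", species = species, from = from,
                 t0 = t0, t1 = t1, depth = depth, crossings = 0L),
            class = "ion_path")
}

#' @rdname ion_paths
#' @export
ion_path_custom <- function(species = "K", z, xy = c(0, 0), crossings = 0L) {
  structure(list(kind = "custom", species = species, z = z, xy = xy,
                 crossings = as.integer(crossings)), class = "ion_path")
}

#' Solvated toy trajectory with programmed permeation events
#'
#' Places `n_waters` water oxygens at fixed positions inside the pore
#' cylinder and moves ions along programmed z paths. The ground-truth
#' permeation count is the number of programmed full crossings.
#'
#' @param pore_structure toy pentamer (list from [make_toy_pentamer()]) or
#'   `structure3d`; used to define the pore cylinder.
#' @param n_waters number of water oxygens placed inside the cylinder.
#' @param ion_paths list of `ion_path` objects.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param cylinder list(radius, zlim, center); default radius 8 Angstrom,
#'   z bounds = TM2 z extent +/- 2 Angstrom.
#' @return list of class `solvated_traj`: `waters` (n_waters x 3, static),
#'   `ions` (array frames x n_ions x 3), `species`, `cylinder`, `n_frames`,
#'   `ground_truth` (`permeation_event_count`).
#' @export
make_solvated_frames <- function(pore_structure, n_waters = 50,
                                 ion_paths = list(), n_frames = 100,
                                 seed = 1, cylinder = NULL) {
  st <- if (is.list(pore_structure) && !is.null(pore_structure$structure))
    pore_structure else list(structure = pore_structure, channel_def = NULL)
  if (is.null(cylinder)) {
    if (is.null(st$channel_def))
      stop("make_solvated_frames: supply a cylinder or a toy pentamer with channel_def")
    ca <- as_ca(st$structure)
    z2 <- ca$coords[ca$labels$resno %in% st$channel_def$tm2, 3]
    cylinder <- list(radius = 8, zlim = range(z2) + c(-2, 2), center = c(0, 0))
  }
  set.seed(seed)
  # static waters strictly inside the cylinder
  r <- cylinder$radius * 0.9 * sqrt(stats::runif(n_waters))
  th <- stats::runif(n_waters, 0, 2 * pi)
  zw <- stats::runif(n_waters, cylinder$zlim[1] + 0.5, cylinder$zlim[2] - 0.5)
  waters <- cbind(cylinder$center[1] + r * cos(th),
                  cylinder$center[2] + r * sin(th), zw)
  n_ions <- length(ion_paths)
  ions <- array(0, dim = c(n_frames, max(n_ions, 0), 3))
  species <- character(n_ions)
  zmin <- cylinder$zlim[1]; zmax <- cylinder$zlim[2]
  h <- zmax - zmin
  tt <- seq(0, 1, length.out = n_frames)
  for (i in seq_along(ion_paths)) {
    p <- ion_paths[[i]]
    species[i] <- p$species
    if (p$kind == "custom") {
      z <- if (length(p$z) == n_frames) p$z else
        stats::approx(seq(0, 1, length.out = length(p$z)), p$z, tt)$y
      xy <- if (is.matrix(p$xy)) p$xy else
        matrix(rep(p$xy, each = n_frames), n_frames, 2)
    } else {
      margin <- 3
      z_in <- if (p$from == "top") zmax + margin else zmin - margin
      z_out <- if (p$kind == "cross") {
        if (p$from == "top") zmin - margin else zmax + margin
      } else {
        if (p$from == "top") zmax - p$depth * h else zmin + p$depth * h
      }
      prog <- pmin(pmax((tt - p$t0) / max(p$t1 - p$t0, 1e-9), 0), 1)
      if (p$kind == "cross") {
        z <- z_in + prog * (z_out - z_in)
      } else {                     # in and back out the same side
        updown <- 1 - abs(2 * prog - 1)
        z <- z_in + updown * (z_out - z_in)
      }
      xy <- matrix(rep(cylinder$center, each = n_frames), n_frames, 2)
    }
    ions[, i, 1] <- xy[, 1]; ions[, i, 2] <- xy[, 2]; ions[, i, 3] <- z
  }
  structure(list(waters = waters, ions = ions, species = species,
                 cylinder = cylinder, n_frames = n_frames,
                 ground_truth = list(permeation_event_count =
                   sum(vapply(ion_paths, function(p) p$crossings, integer(1))))),
            class = "solvated_traj")
}
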