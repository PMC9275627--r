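## Structure and trajectory containers, PDB input/output, common-core
## construction across ensembles. PDB parsing/writing is delegated to bio3d;
## this layer adds altLoc resolution, multi-MODEL handling and the ordered
## C-alpha contracts the rest of the pipeline depends on.

#' @keywords internal
new_structure3d <- function(atom, xyz = NULL, source = NA_character_) {
  if (is.null(xyz)) xyz <- matrix(mat2vec(as.matrix(atom[, c("x", "y", "z")])),
                                  nrow = 1)
  stopifnot(ncol(xyz) == 3 * nrow(atom))
  structure(list(atom = atom, xyz = xyz, source = source),
            class = "structure3d")
}

water_resids <- c("HOH", "WAT", "TIP3", "SOL", "TIP")
ion_resids <- c("K", "CL", "NA", "POT", "CLA", "SOD", "MG", "CA2", "ZN")

#' Read a structure (or multi-model trajectory) from a PDB file
#'
#' All ATOM and HETATM records are retained; water and ion records are
#' flagged by residue name. Alternate locations are resolved by keeping the
#' highest-occupancy record per atom (ties broken alphabetically by altLoc,
#' so 'A' wins). Multi-MODEL files become multi-frame structures.
#'
#' @param path path to a PDB file.
#' @return object of class `structure3d`: `atom` (data.frame with chain,
#'   resno, insert, resid, elety, occupancy `o`, B-factor `b`, `is_water`,
#'   `is_ion`, and frame-1 x/y/z), `xyz` (frames x 3*natoms matrix),
#'   `source`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("read_structure: empty file: ", path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("read_structure: no ATOM/HETATM records in ", path)
  bad <- which(is_atom & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad))
    stop("read_structure: malformed ATOM/HETATM record at line ", bad[1],
         " of ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  # altLoc resolution: highest occupancy, ties -> first altLoc alphabetically
  alt <- atom$alt; alt[is.na(alt)] <- ""
  occ <- atom$o; occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$resid, atom$elety,
               sep = "|")
  keep <- rep(TRUE, nrow(atom))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    idx <- which(key == k)
    ord <- order(-occ[idx], alt[idx], idx)
    keep[idx[-ord[1]]] <- FALSE
  }
  if (!all(keep)) {
    atom <- atom[keep, , drop = FALSE]
    cols <- as.vector(rbind(3 * (which(keep)) - 2, 3 * which(keep) - 1,
                            3 * which(keep)))
    xyz <- xyz[, cols, drop = FALSE]
  }
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- ""
  atom$is_water <- atom$resid %in% water_resids
  atom$is_ion <- atom$resid %in% ion_resids
  atom$x <- xyz[1, seq(1, ncol(xyz), 3)]
  atom$y <- xyz[1, seq(2, ncol(xyz), 3)]
  atom$z <- xyz[1, seq(3, ncol(xyz), 3)]
  rownames(atom) <- NULL
  new_structure3d(atom, xyz, source = path)
}

#' Write a structure (one MODEL per frame) to a PDB file
#'
#' @param x `structure3d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  a <- x$atom
  nf <- nrow(x$xyz)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tmp, xyz = x$xyz[f, ],
                     type = if (!is.null(a$type)) a$type else "ATOM",
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$elety,
                     o = if (!is.null(a$o)) a$o else 1,
                     b = if (!is.null(a$b)) a$b else 0)
    ln <- readLines(tmp, warn = FALSE)
    writeLines(grep("^(ATOM  |HETATM|TER)", ln, value = TRUE), con)
    unlink(tmp)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atom), "atoms,", nrow(x$xyz), "frame(s)\n")
  cat("  chains:", paste(unique(x$atom$chain), collapse = " "), "\n")
  if (any(x$atom$is_water %||% FALSE))
    cat("  waters:", sum(x$atom$is_water), " ions:", sum(x$atom$is_ion), "\n")
  invisible(x)
}

#' Extract the ordered C-alpha set of a structure
#'
#' One row per residue, ordered by chain then residue number (insertion
#' codes sort after the plain residue). Residues lacking a CA atom are
#' skipped with a warning and listed in the `skipped` element.
#'
#' @param x `structure3d`.
#' @param chains optional chain filter (character vector).
#' @return list of class `ca_set`: `coords` (N x 3, frame 1), `labels`
#'   (data.frame chain/resno/insert), `xyz` (frames x 3N), `skipped`.
#' @export
extract_calpha <- function(x, chains = NULL) {
  stopifnot(inherits(x, "structure3d"))
  a <- x$atom
  prot <- !(a$is_water %||% FALSE) & !(a$is_ion %||% FALSE)
  if (!is.null(chains)) prot <- prot & a$chain %in% chains
  if (!any(prot & a$elety == "CA"))
    stop("extract_calpha: structure has no CA atoms",
         if (!is.null(chains)) paste0(" in chains ",
                                      paste(chains, collapse = ",")))
  res_key <- paste(a$chain, a$resno, a$insert, sep = "|")
  prot_keys <- unique(res_key[prot])
  is_ca <- prot & a$elety == "CA"
  ca_idx <- which(is_ca)
  # residues (among protein records) without a CA
  missing <- setdiff(prot_keys, res_key[ca_idx])
  skipped <- NULL
  if (length(missing)) {
    parts <- do.call(rbind, strsplit(missing, "|", fixed = TRUE))
    skipped <- data.frame(chain = parts[, 1],
                          resno = as.integer(parts[, 2]),
                          insert = if (ncol(parts) >= 3) parts[, 3] else "",
                          stringsAsFactors = FALSE)
    for (m in missing) warning("extract_calpha: residue ", m,
                               " has no CA atom; skipped", call. = FALSE)
  }
  ord <- ca_idx[order(a$chain[ca_idx], a$resno[ca_idx], a$insert[ca_idx])]
  labels <- data.frame(chain = a$chain[ord], resno = a$resno[ord],
                       insert = a$insert[ord], stringsAsFactors = FALSE)
  cols <- as.vector(rbind(3 * ord - 2, 3 * ord - 1, 3 * ord))
  xyz <- x$xyz[, cols, drop = FALSE]
  structure(list(coords = vec2mat(xyz[1, ]), labels = labels, xyz = xyz,
                 skipped = skipped), class = "ca_set")
}

## Accept structure3d, ca_set, ca_traj, or bare N x 3 matrix.
as_ca <- function(x) {
  if (inherits(x, "structure3d")) return(extract_calpha(x))
  if (inherits(x, "ca_set")) return(x)
  if (inherits(x, "ca_traj"))
    return(structure(list(coords = vec2mat(x$xyz[1, ]), labels = x$labels,
                          xyz = x$xyz, skipped = NULL), class = "ca_set"))
  if (is.matrix(x) && ncol(x) == 3)
    return(structure(list(coords = x,
                          labels = data.frame(chain = "A",
                                              resno = seq_len(nrow(x)),
                                              insert = "",
                                              stringsAsFactors = FALSE),
                          xyz = matrix(mat2vec(x), nrow = 1),
                          skipped = NULL), class = "ca_set"))
  stop("expected a structure3d, ca_set/ca_traj, or an N x 3 matrix")
}

#' Build the common residue core of an ensemble and superpose members
#'
#' The core is the ordered intersection of (chain, residue number,
#' insertion code) keys that carry a CA atom in every member; order follows
#' the reference member. Every member is then rigid-body superposed onto
#' the reference over the core.
#'
#' @param structures list of `structure3d` (or `ca_set`) objects, length >= 2.
#' @param reference index of the reference member (default 1; it defines
#'   core order and the superposition target).
#' @param ids optional member labels.
#' @return list of class `ensemble`: `core` (data.frame chain/resno/insert),
#'   `xyz` (members x 3N, superposed), `ids`, `reference` (index),
#'   `ref_coords` (N x 3), `fit_rmsd` per member.
#' @export
build_core <- function(structures, reference = 1, ids = NULL) {
  if (length(structures) < 2) stop("build_core: need >= 2 structures")
  cas <- lapply(structures, as_ca)
  keys <- lapply(cas, function(ca)
    paste(ca$labels$chain, ca$labels$resno, ca$labels$insert, sep = "|"))
  core_keys <- keys[[reference]]
  for (k in keys) core_keys <- core_keys[core_keys %in% k]
  if (length(core_keys) == 0) stop("build_core: empty residue intersection")
  ref_ca <- cas[[reference]]
  ref_rows <- match(core_keys, keys[[reference]])
  ref_coords <- ref_ca$coords[ref_rows, , drop = FALSE]
  m <- length(cas)
  xyz <- matrix(0, m, 3 * length(core_keys))
  fit_rmsd <- numeric(m)
  for (i in seq_len(m)) {
    rows <- match(core_keys, keys[[i]])
    co <- cas[[i]]$coords[rows, , drop = FALSE]
    fit <- superpose(co, ref_coords)
    xyz[i, ] <- mat2vec(fit$coords)
    fit_rmsd[i] <- fit$rmsd
  }
  core <- ref_ca$labels[ref_rows, , drop = FALSE]
  rownames(core) <- NULL
  structure(list(core = core, xyz = xyz,
                 ids = ids %||% names(structures) %||%
                   paste0("member", seq_len(m)),
                 reference = reference, ref_coords = ref_coords,
                 fit_rmsd = fit_rmsd),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", nrow(x$xyz), "members,", nrow(x$core),
      "core residues; reference =", x$ids[x$reference], "\n")
  cat("  fit RMSD to reference: mean",
      round(mean(x$fit_rmsd), 3), "A, max", round(max(x$fit_rmsd), 3), "A\n")
  invisible(x)
}

#' Read an ensemble manifest (JSON list of PDB paths + reference id)
#'
#' The manifest is a JSON object `{"files": [...], "reference": "<id>"}`;
#' relative paths are resolved against the manifest directory. Member ids
#' are file base names without extension.
#'
#' @param path manifest path.
#' @return `ensemble` (see [build_core()]).
#' @export
read_ensemble_manifest <- function(path) {
  man <- jsonlite::fromJSON(path)
  files <- man$files
  rel <- !grepl("^(/|[A-Za-z]:)", files)
  files[rel] <- file.path(dirname(path), files[rel])
  ids <- sub("\\.[^.]*$", "", basename(files))
  structs <- lapply(files, read_structure)
  ref <- if (!is.null(man$reference)) match(man$reference, ids) else 1L
  if (is.na(ref)) stop("read_ensemble_manifest: reference id not in file list")
  build_core(structs, reference = ref, ids = ids)
}
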