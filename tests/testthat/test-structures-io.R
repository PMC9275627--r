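## PDB round-trips, altLoc resolution, C-alpha extraction, common-core
## construction.

make_pdb_text <- function(lines) {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                      alt = " ", occ = 1.0) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", name), alt, resid, chain, resno, x, y, z,
          occ, 0)
}

test_that("minimal and multi-model PDB files read correctly", {
  f <- make_pdb_text(c(atom_line(1, "CA", "ALA", "A", 1, 1, 2, 3), "END"))
  st <- read_structure(f)
  expect_equal(nrow(st$atom), 1)
  expect_equal(st$atom$x, 1)

  f3 <- make_pdb_text(c(
    "MODEL        1", atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "ENDMDL",
    "MODEL        2", atom_line(1, "CA", "ALA", "A", 1, 1, 0, 0), "ENDMDL",
    "MODEL        3", atom_line(1, "CA", "ALA", "A", 1, 2, 0, 0), "ENDMDL",
    "END"))
  st3 <- read_structure(f3)
  expect_equal(nrow(st3$xyz), 3)
  expect_equal(st3$xyz[, 1], c(0, 1, 2))
})

test_that("read errors carry context: empty files and malformed records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(read_structure(f), "empty")
  fbad <- make_pdb_text(c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                          "ATOM      2  CA  ALA A   2        garbage",
                          "END"))
  expect_error(read_structure(fbad), "line 2")
  expect_error(read_structure(tempfile()), "no such file")
})

test_that("altLoc records keep the highest occupancy, ties to A", {
  # hand-counted fixture: residue 1 has A(0.4)/B(0.6) -> keep B;
  # residue 2 has A(0.5)/B(0.5) -> keep A; residue 3 single -> 3 atoms total
  f <- make_pdb_text(c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, alt = "A", occ = 0.4),
    atom_line(2, "CA", "ALA", "A", 1, 9, 0, 0, alt = "B", occ = 0.6),
    atom_line(3, "CA", "ALA", "A", 2, 0, 5, 0, alt = "A", occ = 0.5),
    atom_line(4, "CA", "ALA", "A", 2, 9, 5, 0, alt = "B", occ = 0.5),
    atom_line(5, "CA", "ALA", "A", 3, 0, 0, 7),
    "END"))
  st <- read_structure(f)
  expect_equal(nrow(st$atom), 3)
  expect_equal(st$atom$x, c(9, 0, 0))   # B kept for res 1, A for res 2
})

test_that("water and ion records are flagged", {
  f <- make_pdb_text(c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    sub("^ATOM  ", "HETATM", atom_line(2, "O", "HOH", "W", 100, 1, 1, 1)),
    sub("^ATOM  ", "HETATM", atom_line(3, "K", "K", "I", 200, 2, 2, 2)),
    "END"))
  st <- read_structure(f)
  expect_equal(sum(st$atom$is_water), 1)
  expect_equal(sum(st$atom$is_ion), 1)
})

test_that("structures round-trip through PDB write/read", {
  tp <- default_pentamer()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tp$structure, f)
  st <- read_structure(f)
  ca0 <- extract_calpha(tp$structure)
  ca1 <- extract_calpha(st)
  expect_equal(ca1$coords, ca0$coords, tolerance = 1e-3)  # PDB has 3 decimals
  expect_identical(ca1$labels$chain, ca0$labels$chain)
  # trajectory round-trip: MODEL per frame
  tr <- make_transition_trajectory(ca0$coords, ca0$coords + 1, n_frames = 3)
  st_tr <- tp$structure; st_tr$xyz <- tr$xyz
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st_tr, f2)
  rt <- read_structure(f2)
  expect_equal(nrow(rt$xyz), 3)
})

test_that("extract_calpha orders by chain/residue and reports missing CAs", {
  tp <- default_pentamer()
  ca <- extract_calpha(tp$structure)
  expect_equal(nrow(ca$coords), 500)
  expect_false(is.unsorted(ca$labels$resno[ca$labels$chain == "A"]))
  caA <- extract_calpha(tp$structure, chains = "A")
  expect_equal(nrow(caA$coords), 100)
  # delete two CAs: 498 rows and 2 warnings
  st <- tp$structure
  drop <- which(st$atom$chain == "B" & st$atom$resno %in% c(10, 20))
  st$atom <- st$atom[-drop, ]
  keep <- setdiff(seq_len(500), drop)
  st$xyz <- st$xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep)),
                   drop = FALSE]
  ws <- capture_warnings(ca2 <- extract_calpha(st))
  expect_equal(nrow(ca2$coords), 498)
  expect_length(ws, 0)   # removed residues entirely: no CA-less residues left
  # now a residue present but without CA: replace elety instead
  st2 <- tp$structure
  st2$atom$elety[st2$atom$chain == "C" & st2$atom$resno %in% c(5, 6)] <- "CB"
  ws2 <- capture_warnings(ca3 <- extract_calpha(st2))
  expect_equal(nrow(ca3$coords), 498)
  expect_length(ws2, 2)
  expect_equal(nrow(ca3$skipped), 2)
})

test_that("build_core intersects residue keys and superposes members", {
  tp <- default_pentamer()
  # identical structures: core is the full residue set, fit RMSD 0
  ens <- build_core(list(tp$structure, tp$structure))
  expect_equal(nrow(ens$core), 500)
  expect_lt(max(ens$fit_rmsd), 1e-9)
  # one member missing residues 10-20 of chain A: core drops exactly those
  st <- tp$structure
  drop <- which(st$atom$chain == "A" & st$atom$resno %in% 10:20)
  keep <- setdiff(seq_len(500), drop)
  st$atom <- st$atom[-drop, ]
  st$xyz <- st$xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep)),
                   drop = FALSE]
  ens2 <- build_core(list(tp$structure, st))
  expect_equal(nrow(ens2$core), 489)
  expect_false(any(ens2$core$chain == "A" & ens2$core$resno %in% 10:20))
  expect_error(build_core(list(tp$structure)), ">= 2")
})

test_that("staggered-gap cores equal the brute-force set intersection", {
  tp <- make_toy_pentamer(pentamer_params(seed = 5))
  gaps <- list(c(1:5), c(30:40), c(77), c(90:99), integer(0))
  structs <- list(); key_sets <- list()
  for (i in 1:5) {
    st <- tp$structure
    drop <- which(st$atom$chain == "A" & st$atom$resno %in% gaps[[i]])
    if (length(drop)) {
      keep <- setdiff(seq_len(500), drop)
      st$atom <- st$atom[-drop, ]
      st$xyz <- st$xyz[, as.vector(rbind(3 * keep - 2, 3 * keep - 1,
                                         3 * keep)), drop = FALSE]
    }
    structs[[i]] <- st
    key_sets[[i]] <- paste(st$atom$chain, st$atom$resno)
  }
  expected <- Reduce(intersect, key_sets)
  ens <- build_core(structs)
  expect_equal(nrow(ens$core), length(expected))
})

test_that("core alignment is idempotent", {
  tpA <- default_pentamer()
  tpB <- make_toy_pentamer(pentamer_params(quaternary_twist = 10, seed = 2))
  # displace B rigidly so superposition has work to do
  stB <- tpB$structure
  R <- random_rotation(9)
  m <- matrix(stB$xyz[1, ], ncol = 3, byrow = TRUE)
  stB$xyz[1, ] <- as.vector(t(sweep(m %*% t(R), 2, c(5, 5, 5), "+")))
  ens1 <- build_core(list(tpA$structure, stB))
  # re-align the aligned coordinates: nothing should move
  m2 <- matrix(ens1$xyz[2, ], ncol = 3, byrow = TRUE)
  fit <- superpose(m2, ens1$ref_coords)
  expect_lt(max(abs(fit$coords - m2)), 1e-9)
})

test_that("ensemble manifests resolve paths and the reference id", {
  tp <- default_pentamer()
  tp2 <- make_toy_pentamer(pentamer_params(quaternary_twist = 5))
  d <- withr::local_tempdir()
  write_structure(tp$structure, file.path(d, "closed.pdb"))
  write_structure(tp2$structure, file.path(d, "twisted.pdb"))
  jsonlite::write_json(list(files = c("closed.pdb", "twisted.pdb"),
                            reference = "twisted"),
                       file.path(d, "manifest.json"), auto_unbox = TRUE)
  ens <- read_ensemble_manifest(file.path(d, "manifest.json"))
  expect_equal(ens$reference, 2L)
  expect_equal(nrow(ens$xyz), 2)
})
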