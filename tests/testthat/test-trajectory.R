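test_that("RMSD series match a per-frame superposition oracle", {
  tpA <- default_pentamer()
  tpB <- make_toy_pentamer(pentamer_params(quaternary_twist = 6))
  caA <- extract_calpha(tpA$structure)
  tr <- make_transition_trajectory(tpA$structure, tpB$structure,
                                   n_frames = 12, noise_sigma = 0.1,
                                   seed = 10)
  rs <- rmsd_series(tr, caA$coords)
  oracle <- vapply(seq_len(12), function(f)
    quaternion_rmsd(matrix(tr$xyz[f, ], ncol = 3, byrow = TRUE), caA$coords),
    numeric(1))
  expect_equal(rs$rmsd, oracle, tolerance = 1e-6)
  # trajectory of reference copies: all zeros
  const <- structure(list(xyz = rbind(mat2vec(caA$coords),
                                      mat2vec(caA$coords)),
                          labels = caA$labels), class = "ca_traj")
  expect_lt(max(rmsd_series(const, caA$coords)$rmsd), 1e-9)
  # displacement orthogonal to rigid-body space: RMSD = |v|/sqrt(N)
  B <- pentadyn:::rigid_body_basis(caA$coords)
  set.seed(4)
  v <- rnorm(1500); v <- v - B %*% crossprod(B, v)
  v <- as.numeric(v)
  moved <- mat2vec(caA$coords) + v
  one <- structure(list(xyz = matrix(moved, nrow = 1), labels = caA$labels),
                   class = "ca_traj")
  expect_equal(rmsd_series(one, caA$coords)$rmsd,
               sqrt(sum(v^2) / 500), tolerance = 1e-6)
})

test_that("GROMOS clustering separates tight groups and is exhaustive", {
  set.seed(20)
  base <- matrix(rnorm(60, sd = 5), 20, 3)
  base2 <- matrix(rnorm(60, sd = 5), 20, 3)   # unrelated conformation
  groupA <- t(vapply(1:6, function(i)
    mat2vec(base + matrix(rnorm(60, sd = 0.2), 20, 3)), numeric(60)))
  groupB <- t(vapply(1:4, function(i)
    mat2vec(base2 + matrix(rnorm(60, sd = 0.2), 20, 3)), numeric(60)))
  cl <- gromos_cluster(rbind(groupA, groupB), cutoff = 2)
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$assignment, rep(c(1, 2), c(6, 4)))
  expect_equal(cl$clusters$size, c(6, 4))
  # all identical frames: one cluster
  same <- rbind(groupA[1, ], groupA[1, ], groupA[1, ])
  expect_equal(nrow(gromos_cluster(same, cutoff = 2)$clusters), 1)
})

test_that("GROMOS clustering equals the reference implementation on random frames", {
  set.seed(77)
  n_frames <- 20
  base <- matrix(rnorm(45, sd = 4), 15, 3)
  xyz <- t(vapply(seq_len(n_frames), function(i)
    mat2vec(base + matrix(rnorm(45, sd = 1.2), 15, 3)), numeric(45)))
  for (cutoff in c(1.0, 1.5, 2.0, 3.0)) {
    cl <- gromos_cluster(xyz, cutoff = cutoff)
    D <- pentadyn:::pairwise_rmsd(xyz)
    expect_equal(cl$assignment, gromos_reference(D, cutoff),
                 info = paste("cutoff", cutoff))
  }
})

test_that("cluster partitions are disjoint, exhaustive and size-ordered", {
  set.seed(31)
  xyz <- t(vapply(1:30, function(i)
    mat2vec(matrix(rnorm(30, sd = 3), 10, 3)), numeric(30)))
  counts_prev <- Inf
  for (cutoff in c(1, 2, 4, 8)) {
    cl <- gromos_cluster(xyz, cutoff = cutoff)
    expect_setequal(unlist(lapply(seq_len(nrow(cl$clusters)), function(k)
      which(cl$assignment == k))), seq_len(30))
    expect_true(all(diff(cl$clusters$size) <= 0))
    # raising the cutoff never increases the cluster count
    expect_lte(nrow(cl$clusters), counts_prev)
    counts_prev <- nrow(cl$clusters)
  }
})

test_that("essential dynamics is PCA of fitted frames with ED provenance", {
  tpA <- default_pentamer()
  caA <- extract_calpha(tpA$structure)
  # displacement orthogonal to the rigid-body space: per-frame fitting is
  # then the identity and all the exact single-mode identities hold
  B <- pentadyn:::rigid_body_basis(caA$coords)
  set.seed(41)
  u <- rnorm(1500); u <- u - B %*% crossprod(B, u)
  u <- as.numeric(u / sqrt(sum(u^2)))
  endB <- caA$coords + 3 * matrix(u, ncol = 3, byrow = TRUE)
  tr <- make_transition_trajectory(caA$coords, endB, n_frames = 9)
  tr$labels <- caA$labels
  ed <- essential_dynamics(tr)
  expect_equal(ed$provenance, "ED")
  expect_equal(sum(ed$eigenvalues > 1e-9 * ed$eigenvalues[1]), 1)
  expect_gt(mode_overlap(u, ed$modes[, 1]), 1 - 1e-9)
  # definitional: ED of already-fitted frames equals plain PCA
  ms <- fit_pca(tr$xyz)
  expect_equal(ed$eigenvalues, ms$eigenvalues, tolerance = 1e-10)
  # a twist interpolation carries a global-rotation component that the
  # per-frame fit removes: the dominant internal mode still tracks the
  # (rigid-projected) transition vector
  tpB <- make_toy_pentamer(pentamer_params(quaternary_twist = 10))
  tr2 <- make_transition_trajectory(tpA$structure, tpB$structure,
                                    n_frames = 9)
  ed2 <- essential_dynamics(tr2)
  expect_lt(ed2$eigenvalues[2] / ed2$eigenvalues[1], 1e-3)
  tv <- transition_vector(tpA$structure, tpB$structure)
  expect_gt(mode_overlap(tv, ed2$modes[, 1]), 0.999)
})

test_that("noisy-transition ED modes cover the transition direction", {
  tpA <- default_pentamer()
  tpB <- make_toy_pentamer(pentamer_params(quaternary_twist = 10))
  hits <- 0L
  for (s in 1:20) {
    tr <- make_transition_trajectory(tpA$structure, tpB$structure,
                                     n_frames = 40, noise_sigma = 0.1,
                                     seed = 1000 + s)
    ed <- essential_dynamics(tr)
    tv <- transition_vector(tpA$structure, tpB$structure)
    d_true <- cumulative_overlap(tv, ed, M = 10)
    set.seed(s)
    d_rand <- cumulative_overlap(rnorm(1500), ed, M = 10)
    if (d_true > d_rand) hits <- hits + 1L
    if (s <= 3) expect_gt(d_true, 0.9)
  }
  expect_equal(hits, 20L)
})

test_that("helicity separates ideal helices from extended chains", {
  tp <- default_pentamer()
  expect_equal(helicity(tp$structure, tp$channel_def$tm2), 1)
  ext <- cbind(0, 0, seq(0, by = 3.8, length.out = 20))
  expect_equal(helicity(ext, 1:20), 0)
  # half helix / half extended: fraction 0.5 within one window edge
  j <- 0:9; w <- 100 * pi / 180
  helix <- cbind(2.3 * cos(w * j), 2.3 * sin(w * j), 1.5 * j)
  straight <- cbind(2.3, 0, max(helix[, 3]) + 3.8 * (1:10))
  half <- rbind(helix, straight)
  n_windows <- 20 - 3
  # hand count: windows fully inside the helix part pass (7 of 17)
  expect_equal(helicity(half, 1:20), 7 / n_windows, tolerance = 1e-9)
  expect_error(helicity(half, 1:4), "too short")
})

test_that("contact persistence counts the exact fraction of frames", {
  # two CA beads drifting apart: contact holds in 60 of 100 frames
  n <- 100
  d0 <- 7; d1 <- 9   # crosses the 8 A proxy cutoff at frame 61 exactly
  dists <- seq(d0, d1, length.out = n)
  atom <- data.frame(type = "ATOM", eleno = 1:2, elety = "CA",
                     resid = "ALA", chain = c("A", "B"), resno = c(1, 1),
                     insert = "", o = 1, b = 0,
                     x = c(0, d0), y = 0, z = 0,
                     is_water = FALSE, is_ion = FALSE,
                     stringsAsFactors = FALSE)
  xyz <- t(vapply(dists, function(d) c(0, 0, 0, d, 0, 0), numeric(6)))
  st <- structure(list(atom = atom, xyz = xyz, source = "synthetic"),
                  class = "structure3d")
  ct <- polar_contacts(st)
  expect_equal(attr(ct, "mode"), "ca_proxy")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$persistence, sum(dists <= 8) / n)
})

test_that("salt bridges are detected from charged-group centroids", {
  mk_atom <- function(eleno, elety, resid, chain, resno, x) {
    data.frame(type = "ATOM", eleno = eleno, elety = elety, resid = resid,
               chain = chain, resno = resno, insert = "", o = 1, b = 0,
               x = x, y = 0, z = 0, is_water = FALSE, is_ion = FALSE,
               stringsAsFactors = FALSE)
  }
  for (d in c(3, 5)) {
    atom <- rbind(mk_atom(1, "OD1", "ASP", "A", 1, 0),
                  mk_atom(2, "OD2", "ASP", "A", 1, 0),
                  mk_atom(3, "NZ", "LYS", "B", 2, d))
    xyz <- matrix(mat2vec(as.matrix(atom[, c("x", "y", "z")])), nrow = 1)
    st <- structure(list(atom = atom, xyz = xyz, source = "synthetic"),
                    class = "structure3d")
    ct <- polar_contacts(st)
    sb <- ct[ct$type == "salt_bridge", ]
    if (d == 3) expect_equal(nrow(sb), 1) else expect_equal(nrow(sb), 0)
  }
})
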