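test_that("quaternary twist recovers the programmed rotation", {
  tp0 <- default_pentamer()
  expect_equal(as.numeric(quaternary_twist(tp0$structure, tp0$channel_def)),
               0, tolerance = 1e-6)
  tp10 <- make_toy_pentamer(pentamer_params(quaternary_twist = 10))
  expect_equal(as.numeric(quaternary_twist(tp10$structure, tp10$channel_def)),
               10, tolerance = 0.1)
  # whole-structure rotation about z leaves the twist unchanged
  st <- tp10$structure
  m <- matrix(st$xyz[1, ], ncol = 3, byrow = TRUE) %*%
    t(pentadyn:::rot_z(37)) + 5
  st$xyz[1, ] <- as.vector(t(m))
  st$atom$x <- m[, 1]; st$atom$y <- m[, 2]; st$atom$z <- m[, 3]
  expect_equal(as.numeric(quaternary_twist(st, tp10$channel_def)), 10,
               tolerance = 1e-6)
})

test_that("blooming matches pentagon geometry and tracks radial expansion", {
  tp <- default_pentamer()
  cd <- tp$channel_def
  # five tips on a circle of radius R: half max pairwise = R sin(72 deg)
  R <- tp$ground_truth$tip_radius
  expect_equal(blooming(tp$structure, cd), R * sin(72 * pi / 180),
               tolerance = 1e-6)
  expect_equal(blooming(tp$structure, cd, method = "axis"), R,
               tolerance = 1e-6)
  # +5 A radial expansion: both measures grow by the oracle-predicted amount
  tpb <- make_toy_pentamer(pentamer_params(bloom = 5))
  expect_equal(blooming(tpb$structure, cd, method = "axis") -
                 blooming(tp$structure, cd, method = "axis"), 5,
               tolerance = 1e-6)
  expect_equal(blooming(tpb$structure, cd) - blooming(tp$structure, cd),
               5 * sin(72 * pi / 180), tolerance = 1e-6)
  # rotation invariance
  st <- tpb$structure
  m <- matrix(st$xyz[1, ], ncol = 3, byrow = TRUE) %*% t(pentadyn:::rot_z(77))
  st$atom$x <- m[, 1]; st$atom$y <- m[, 2]; st$atom$z <- m[, 3]
  st$xyz[1, ] <- as.vector(t(m))
  expect_equal(blooming(st, cd), blooming(tpb$structure, cd),
               tolerance = 1e-9)
})

test_that("TM2 tilt and twist recover programmed leans independently", {
  cd <- default_pentamer()$channel_def
  t0 <- tm2_angles(default_pentamer()$structure, cd)
  expect_lt(max(abs(t0$tilt)), 1e-6)
  expect_lt(max(abs(t0$twist)), 1e-6)
  tp_tilt <- make_toy_pentamer(pentamer_params(tm2_tilt = 15))
  a <- tm2_angles(tp_tilt$structure, cd)
  expect_equal(attr(a, "mean_tilt"), 15, tolerance = 0.5)
  expect_equal(attr(a, "mean_twist"), 0, tolerance = 0.5)
  tp_tw <- make_toy_pentamer(pentamer_params(tm2_twist = 8))
  b <- tm2_angles(tp_tw$structure, cd)
  expect_equal(attr(b, "mean_twist"), 8, tolerance = 0.5)
  expect_equal(attr(b, "mean_tilt"), 0, tolerance = 0.5)
  cd_short <- cd
  cd_short$tm2 <- cd_short$tm2[1:4]
  expect_error(tm2_angles(default_pentamer()$structure, cd_short),
               "too short")
})

test_that("ring closed forms: slice radius is axis distance minus atom radius", {
  # single ring of 5 CAs at axis distance 8: radius 8 - 1.9 = 6.1
  th <- 2 * pi * (0:4) / 5
  ring <- cbind(8 * cos(th), 8 * sin(th), 0)
  pp <- pore_profile(ring, step = 0.5, zlim = c(0, 0))
  expect_equal(pp$min_radius, 6.1, tolerance = 0.05)
  # two stacked rings at radii 8 and 5: min radius from the 5 A ring
  ring2 <- rbind(cbind(8 * cos(th), 8 * sin(th), 0),
                 cbind(5 * cos(th), 5 * sin(th), 4))
  # mid-gap slices hold no atoms and are masked with a warning
  expect_warning(pp2 <- pore_profile(ring2, step = 0.5), "no atoms")
  expect_equal(pp2$min_radius, 5 - 1.9, tolerance = 0.05)
  iz <- which.min(abs(pp2$profile$z))
  expect_equal(pp2$profile$radius[iz], 6.1, tolerance = 0.05)
})

test_that("pore profile matches the fine-grid inscribed-circle oracle", {
  tp <- make_toy_pentamer(pentamer_params(tm2_tilt = 8))
  ca <- extract_calpha(tp$structure)
  sel <- ca$labels$resno %in% tp$channel_def$tm2
  coords <- ca$coords[sel, ]
  pp <- suppressWarnings(pore_profile(coords, step = 0.5))
  for (i in seq(1, nrow(pp$profile), by = 4)) {
    z0 <- pp$profile$z[i]
    slab <- coords[abs(coords[, 3] - z0) <= 0.5, , drop = FALSE]
    if (!nrow(slab) || is.na(pp$profile$radius[i])) next
    oracle <- slice_radius_bruteforce(slab[, 1:2, drop = FALSE], half = 4)
    expect_lt(abs(pp$profile$radius[i] - oracle), 0.05)
  }
})

test_that("adding atoms never widens the pore (superset monotonicity)", {
  tp <- default_pentamer()
  ca <- extract_calpha(tp$structure)
  cd <- tp$channel_def
  pp_tm2 <- pore_profile(tp$structure, selection = cd$tm2)
  pp_tmd <- pore_profile(tp$structure, selection = cd$tmd,
                         zlim = range(ca$coords[ca$labels$resno %in% cd$tm2, 3]))
  z_common <- intersect(round(pp_tm2$profile$z, 6),
                        round(pp_tmd$profile$z, 6))
  for (z in z_common) {
    r2 <- pp_tm2$profile$radius[round(pp_tm2$profile$z, 6) == z]
    rd <- pp_tmd$profile$radius[round(pp_tmd$profile$z, 6) == z]
    if (!is.na(r2) && !is.na(rd)) expect_lte(rd, r2 + 1e-9)
  }
})

test_that("gate-window radii average the profile correctly", {
  # constant profile
  flat <- structure(list(profile = data.frame(z = seq(0, 10, 0.5),
                                              radius = 3, cx = 0, cy = 0),
                         min_radius = 3, step = 0.5, atom_radius = 1.9),
                    class = "pore_profile")
  expect_equal(radius_at_gate(flat, gate_z = 5), 3)
  # linear ramp: mean over symmetric window = midpoint value
  ramp <- flat
  ramp$profile$radius <- ramp$profile$z   # r = z
  expect_equal(radius_at_gate(ramp, gate_z = 5), 5, tolerance = 1e-9)
  # step discontinuity at z0: hand-computed average of the window samples
  stepped <- flat
  stepped$profile$radius <- ifelse(stepped$profile$z < 5, 2, 4)
  # window [2.5, 7.5] holds z = 2.5..4.5 (radius 2, 5 samples) and
  # z = 5..7.5 (radius 4, 6 samples): mean = (5*2 + 6*4)/11
  expect_equal(radius_at_gate(stepped, gate_z = 5), (5 * 2 + 6 * 4) / 11,
               tolerance = 1e-9)
  expect_error(radius_at_gate(flat, gate_z = 0.5), "outside")
})

test_that("hydration counts equal the brute-force point-in-cylinder test", {
  cyl <- list(radius = 8, zlim = c(0, 20), center = c(0, 0))
  set.seed(14)
  pts <- cbind(runif(200, -15, 15), runif(200, -15, 15), runif(200, -10, 30))
  inside <- sqrt(pts[, 1]^2 + pts[, 2]^2) <= 8 & pts[, 3] >= 0 & pts[, 3] <= 20
  expect_equal(hydration_count(pts, cyl), sum(inside))
  # constructed counts: 50 in, 20 out
  th <- runif(50, 0, 2 * pi); r <- 7 * sqrt(runif(50))
  w_in <- cbind(r * cos(th), r * sin(th), runif(50, 1, 19))
  w_out <- cbind(runif(20, 9, 15), 0, runif(20, 0, 20))
  expect_equal(hydration_count(rbind(w_in, w_out), cyl), 50)
  expect_warning(n0 <- hydration_count(matrix(numeric(0), 0, 3), cyl),
                 "no waters")
  expect_equal(n0, 0L)
})

test_that("ion permeation events follow the boundary-crossing definition", {
  tp <- default_pentamer()
  # single programmed crossing
  sv1 <- make_solvated_frames(tp, n_waters = 0, n_frames = 60, seed = 1,
                              ion_paths = list(ion_path_cross("K", "top")))
  tr1 <- ion_tracking(sv1)
  expect_equal(tr1$n_events, 1)
  expect_equal(tr1$events$direction, "top->bottom")
  # entry then retreat: no event
  sv0 <- make_solvated_frames(tp, n_waters = 0, n_frames = 60, seed = 1,
                              ion_paths = list(ion_path_retreat("K", "top")))
  expect_equal(ion_tracking(sv0)$n_events, 0)
  # 3-ion scenario equals ground truth
  sv3 <- make_solvated_frames(tp, n_waters = 0, n_frames = 120, seed = 1,
                              ion_paths = list(
                                ion_path_cross("K", "top"),
                                ion_path_cross("CL", "bottom", t0 = 0.2, t1 = 0.8),
                                ion_path_retreat("K", "bottom", depth = 0.7)))
  expect_equal(ion_tracking(sv3)$n_events,
               sv3$ground_truth$permeation_event_count)
  # lateral exit resets the transit: build a custom path entering the top,
  # leaving through the wall, re-entering laterally and exiting the bottom
  cyl <- sv1$cylinder
  zmid <- mean(cyl$zlim)
  n <- 40
  z <- c(seq(cyl$zlim[2] + 3, zmid, length.out = 15),
         rep(zmid, 10),
         seq(zmid, cyl$zlim[1] - 3, length.out = 15))
  xy <- rbind(matrix(0, 15, 2),
              cbind(seq(0, cyl$radius + 3, length.out = 5),
                    numeric(5)),
              cbind(seq(cyl$radius + 3, 0, length.out = 5), numeric(5)),
              matrix(0, 15, 2))
  svl <- make_solvated_frames(tp, n_waters = 0, n_frames = n, seed = 1,
                              ion_paths = list(
                                ion_path_custom("K", z = z, xy = xy,
                                                crossings = 0)))
  expect_equal(ion_tracking(svl)$n_events, 0)
})

test_that("descriptor recovery holds across a programmed deformation grid", {
  # coarse grid here; the acceptance suite runs the full 5x5x5 sweep
  for (tw in c(-10, 0, 10)) for (bl in c(0, 3)) for (ti in c(0, 8)) {
    tp <- make_toy_pentamer(pentamer_params(quaternary_twist = tw,
                                            bloom = bl, tm2_tilt = ti))
    cd <- tp$channel_def
    expect_equal(as.numeric(quaternary_twist(tp$structure, cd)), tw,
                 tolerance = 0.5)
    expect_equal(blooming(tp$structure, cd, method = "axis") -
                   default_bloom_axis(), bl, tolerance = 0.3)
    expect_equal(attr(tm2_angles(tp$structure, cd), "mean_tilt"), ti,
                 tolerance = 0.5)
  }
})

test_that("descriptors degrade gracefully under coordinate noise", {
  tp <- make_toy_pentamer(pentamer_params(quaternary_twist = 10, bloom = 4,
                                          tm2_tilt = 10, noise_sigma = 0.5,
                                          seed = 33))
  cd <- tp$channel_def
  expect_lt(abs(as.numeric(quaternary_twist(tp$structure, cd)) - 10), 1)
  expect_lt(abs((blooming(tp$structure, cd, method = "axis") -
                   default_bloom_axis()) - 4), 1)
  expect_lt(abs(attr(tm2_angles(tp$structure, cd), "mean_tilt") - 10), 2)
})
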