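## Shared fixtures and independent oracles. Expensive fixtures are cached
## per session.

.fix <- new.env(parent = emptyenv())

default_pentamer <- function() {
  if (is.null(.fix$tp)) .fix$tp <- make_toy_pentamer()
  .fix$tp
}

default_modes <- function() {
  if (is.null(.fix$nm)) {
    tp <- default_pentamer()
    .fix$net <- build_network(tp$structure)
    .fix$nm <- normal_modes(.fix$net)
  }
  .fix$nm
}

default_network <- function() {
  default_modes()
  .fix$net
}

## quaternion-method superposition oracle (Horn 1987), independent of the
## SVD route used by superpose()
quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

## O(N^2) double-loop sphere-hit oracle
sphere_hits_bruteforce <- function(coords, counts, radius = 9) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= radius)
        s <- s + counts[j]
    }
    out[i] <- s
  }
  out
}

## fine-grid inscribed-circle oracle for one z slice
slice_radius_bruteforce <- function(xy, atom_radius = 1.9, half = 3,
                                    step = 0.025, center = c(0, 0)) {
  g <- seq(-half, half, by = step)
  best <- -Inf
  gx <- rep(center[1] + g, times = length(g))
  gy <- rep(center[2] + g, each = length(g))
  for (a in seq_len(nrow(xy))) {
    d <- sqrt((gx - xy[a, 1])^2 + (gy - xy[a, 2])^2)
    if (a == 1) mind <- d else mind <- pmin(mind, d)
  }
  max(mind) - atom_radius
}

## reference implementation of largest-neighbourhood (GROMOS) clustering,
## written against the published algorithm description, not the package code
gromos_reference <- function(D, cutoff) {
  n <- nrow(D)
  remaining <- seq_len(n)
  assignment <- integer(n)
  cl <- 0L
  while (length(remaining) > 0) {
    cl <- cl + 1L
    best_i <- NA; best_n <- -1L
    for (i in remaining) {
      ni <- sum(D[i, remaining] <= cutoff)
      if (ni > best_n) { best_n <- ni; best_i <- i }
    }
    members <- remaining[D[best_i, remaining] <= cutoff]
    assignment[members] <- cl
    remaining <- setdiff(remaining, members)
  }
  assignment
}

## finite-difference Hessian of the network energy
fd_hessian <- function(network, h = 1e-5) {
  coords <- network$coords
  n3 <- 3 * nrow(coords)
  H <- matrix(0, n3, n3)
  en <- function(v) network_energy(network, matrix(v, ncol = 3, byrow = TRUE))
  v0 <- as.vector(t(coords))
  for (a in seq_len(n3)) for (b in a:n3) {
    vpp <- v0; vpp[a] <- vpp[a] + h; vpp[b] <- vpp[b] + h
    vpm <- v0; vpm[a] <- vpm[a] + h; vpm[b] <- vpm[b] - h
    vmp <- v0; vmp[a] <- vmp[a] - h; vmp[b] <- vmp[b] + h
    vmm <- v0; vmm[a] <- vmm[a] - h; vmm[b] <- vmm[b] - h
    H[a, b] <- H[b, a] <- (en(vpp) - en(vpm) - en(vmp) + en(vmm)) / (4 * h^2)
  }
  H
}

## random rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## axis-method blooming of the undeformed default pentamer (cached)
default_bloom_axis <- function() {
  if (is.null(.fix$bloom0)) {
    tp <- default_pentamer()
    .fix$bloom0 <- blooming(tp$structure, tp$channel_def, method = "axis")
  }
  .fix$bloom0
}
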