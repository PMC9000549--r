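# Independent brute-force oracles and tiny fixture builders shared by the
# unit and acceptance tests. Oracles deliberately avoid the code paths
# they check (no igraph, no SVD, no hill climbing).

# --- fixtures ---------------------------------------------------------------

# minimal frame holding only water oxygens at given coordinates
water_frame <- function(xyz, extra_atoms = NULL, extra_xyz = NULL) {
  xyz <- as.matrix(xyz)
  at <- atom_table(seq_len(nrow(xyz)), rep("OH2", nrow(xyz)), "TIP3",
                   seq_len(nrow(xyz)), "WAT", element = "O")
  if (!is.null(extra_atoms)) {
    extra_atoms$index <- max(at$index) + seq_len(nrow(extra_atoms))
    at <- rbind(at, extra_atoms)
    xyz <- rbind(xyz, extra_xyz)
  }
  structure(list(atoms = at, xyz = xyz, time = 0), class = "traj_frame")
}

# a small channel whose axis passes through the origin: four single-atom
# "helices" at the corners so the four-helix centroid is (0, 0)
toy_channel_frame <- function(water_xyz, membrane_z = c(-10, 10),
                              radius = 6, margin = 2) {
  corners <- rbind(c(5, 5, 0), c(-5, 5, 0), c(-5, -5, 0), c(5, -5, 0))
  helix_at <- atom_table(1:4, rep("CA", 4), "GLY",
                         c(97L, 133L, 166L, 193L),
                         c("S1", "S2", "S3", "S4"), element = "C")
  wat_at <- atom_table(4L + seq_len(nrow(water_xyz)),
                       rep("OH2", nrow(water_xyz)), "TIP3",
                       seq_len(nrow(water_xyz)), "WAT", element = "O")
  frame <- structure(list(atoms = rbind(helix_at, wat_at),
                          xyz = rbind(corners, as.matrix(water_xyz)),
                          time = 0),
                     class = "traj_frame")
  channel <- channel_definition(membrane_z = membrane_z,
                                water_cylinder_radius = radius,
                                boundary_margin = margin)
  list(frame = frame, channel = channel)
}

# --- oracles ----------------------------------------------------------------

# exhaustive point-in-cylinder membership
oracle_in_cylinder <- function(xyz, axis_xy, radius, z_lo, z_hi, margin) {
  r2 <- (xyz[, 1] - axis_xy[1])^2 + (xyz[, 2] - axis_xy[2])^2
  r2 <= radius^2 & xyz[, 3] >= z_lo - margin & xyz[, 3] <= z_hi + margin
}

# O(n^2) double-loop adjacency under strict cutoff
oracle_adjacency <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff)
      out <- rbind(out, c(i, j))
  }
  out
}

# union-find connected-components spanning test (no igraph)
oracle_spans <- function(xyz, cutoff, z_lo, z_hi) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  bottom <- unique(roots[xyz[, 3] <= z_lo])
  top <- unique(roots[xyz[, 3] >= z_hi])
  length(intersect(bottom, top)) > 0
}

# exhaustive fine-grid maximization of the clearance radius over a disc
# of radius `search` about the axis (contains the pore basin optimum for
# wall-enclosed instances)
oracle_pore_radius <- function(apos, avdw, axis_xy, z0, search = 1.6,
                               res = 0.005) {
  g <- seq(-search, search, by = res)
  cand <- expand.grid(x = g, y = g)
  cand <- cand[cand$x^2 + cand$y^2 <= search^2, ]
  cx <- cand$x + axis_xy[1]; cy <- cand$y + axis_xy[2]
  dz2 <- (apos[, 3] - z0)^2
  best <- -Inf
  for (i in seq_along(cx)) {
    v <- min(sqrt((apos[, 1] - cx[i])^2 + (apos[, 2] - cy[i])^2 + dz2) - avdw)
    if (v > best) best <- v
  }
  best
}

# rotation-sampling superposition oracle: best RMSD over many random
# rotations, refined by Nelder-Mead on the rotation vector (axis*angle);
# independent of the Kabsch/SVD path
oracle_superpose_rmsd <- function(mobile, reference, n_samples = 4000,
                                  seed = 42) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R0 <- sweep(reference, 2, colMeans(reference))
  rotvec_to_mat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) {
    R <- rotvec_to_mat(v)
    sqrt(mean(rowSums((M %*% t(R) - R0)^2)))
  }
  set.seed(seed)
  best_v <- c(0, 0, 0); best <- obj(best_v)
  for (i in seq_len(n_samples)) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    v <- ax * stats::runif(1, 0, pi)
    f <- obj(v)
    if (f < best) { best <- f; best_v <- v }
  }
  for (scale in c(0.2, 0.02)) {
    o <- stats::optim(best_v, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14,
                                     parscale = rep(scale, 3)))
    if (o$value < best) { best <- o$value; best_v <- o$par }
  }
  best
}

# jittered-ring pore wall instance: an enclosing wall with planted
# irregularity, seeded; returns atom positions, radii and the slice z
random_wall_instance <- function(seed, n_rings = 5, atoms_per_ring = 7) {
  set.seed(seed)
  zs <- seq(-2, 2, length.out = n_rings)
  pos <- NULL
  for (z in zs) {
    base_r <- stats::runif(1, 2.6, 3.6)
    th <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring +
      stats::runif(1, 0, 2 * pi)
    r <- base_r + stats::rnorm(atoms_per_ring, sd = 0.15)
    pos <- rbind(pos, cbind(r * cos(th), r * sin(th),
                            z + stats::rnorm(atoms_per_ring, sd = 0.1)))
  }
  list(pos = pos, vdw = rep(1.52, nrow(pos)), z0 = 0)
}
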