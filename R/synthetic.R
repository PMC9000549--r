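# Synthetic trajectory generator. Builds a four-helix transmembrane
# scaffold around a z-aligned pore, plants a membrane-spanning water chain
# in a controlled fraction of frames, schedules rigid helix z-shifts,
# donor-acceptor contact formation, and gate-residue drift, and records
# every planted fact in a manifest that downstream analyses must recover.
#
# The scaffold is deliberately idealized: every arc atom is a carbon bead
# named "CA" (so alpha-carbon selections see equal atom counts per helix),
# gate residues carry explicit sidechain heavy atoms and hydrogens with
# ideal bond lengths so distance/angle criteria are exactly computable,
# and water chains run along the pore axis so continuity depends only on
# the planted spacing.

#' Specification for a synthetic trajectory
#'
#' @param n_frames number of frames.
#' @param seed RNG seed for wire-frame sampling and gap placement.
#' @param scaffold list: `radius` (atom-center distance from axis, A),
#'   `length` (z extent, A), `atoms_per_ring` (per helix per ring),
#'   `ring_spacing` (A).
#' @param helix_schedules named list (helix label -> per-frame z offset
#'   vector, A) or NULL.
#' @param wire_fraction fraction of frames with a continuous water wire;
#'   `wire_fraction * n_frames` must be an integer.
#' @param wire_spacing O-O spacing of the planted chain, A (< 3.4).
#' @param gap_size the single super-cutoff gap inserted in non-wire
#'   frames, A (> 3.4).
#' @param contact_schedule list of contacts, each
#'   `list(donor = "204:ARG", acceptor = "108:ASP", on_frames = <int>)`.
#' @param gate_drift `list(residue = "146:PHE", dz = -2)` for a linear
#'   sidechain z drift over the trajectory, or NULL.
#' @param decoy_waters number of static off-cylinder waters (exercise the
#'   membership test).
#' @param jitter_sd Gaussian xy jitter applied to scaffold arc atoms, A.
#' @param gates include the gate pseudo-residue sidechains (set FALSE for
#'   a bare cylinder, e.g. for analytic pore checks).
#' @param dt_ns frame spacing, ns.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_frames = 200, seed = 1,
                           scaffold = list(radius = 8, length = 36,
                                           atoms_per_ring = 6,
                                           ring_spacing = 1.5),
                           helix_schedules = NULL,
                           wire_fraction = 0.3,
                           wire_spacing = 2.8, gap_size = 4.0,
                           contact_schedule = NULL,
                           gate_drift = NULL,
                           decoy_waters = 6, jitter_sd = 0,
                           gates = TRUE,
                           dt_ns = 0.1) {
  k <- wire_fraction * n_frames
  if (abs(k - round(k)) > 1e-9)
    stop("infeasible spec: wire_fraction * n_frames = ", k,
         " is not an integer")
  if (!(wire_spacing < 3.4 && 3.4 < gap_size))
    stop("require wire_spacing < 3.4 < gap_size")
  if (scaffold$radius <= 0) stop("degenerate scaffold: zero radius")
  structure(list(n_frames = as.integer(n_frames), seed = as.integer(seed),
                 scaffold = scaffold, helix_schedules = helix_schedules,
                 wire_fraction = wire_fraction, wire_spacing = wire_spacing,
                 gap_size = gap_size, contact_schedule = contact_schedule,
                 gate_drift = gate_drift, decoy_waters = decoy_waters,
                 jitter_sd = jitter_sd, gates = gates, dt_ns = dt_ns),
            class = "synthetic_spec")
}

# quadrant center angles (degrees) of the four helices; S2 faces S4
.helix_angles <- c(S1 = 45, S2 = 135, S3 = 225, S4 = 315)

# gate pseudo-residues: resnum, resname, helix
.gate_table <- data.frame(
  resnum = c(108L, 143L, 146L, 178L, 201L, 204L),
  resname = c("ASP", "LEU", "PHE", "PHE", "ARG", "ARG"),
  helix = c("S1", "S2", "S2", "S3", "S4", "S4"),
  stringsAsFactors = FALSE)

#' Generate the four-helix scaffold frame
#'
#' Four quadrant arcs of carbon beads (one residue per ring per helix,
#' numbered inside the helix ranges) around a z-aligned pore, plus gate
#' pseudo-residues (Asp108, Leu143, Phe146, Phe178, Arg201, Arg204) with
#' sidechain heavy atoms and, for the arginines, guanidinium-like
#' hydrogens at 1.0 A ideal bond lengths.
#'
#' @param spec a [synthetic_spec()].
#' @param channel a [channel_definition()] giving helix ranges and the
#'   membrane slab (the scaffold is centered on the slab).
#' @return a `traj_frame`.
#' @export
generate_scaffold <- function(spec = synthetic_spec(),
                              channel = channel_definition()) {
  sc <- spec$scaffold
  if (sc$radius <= 0) stop("degenerate scaffold: zero radius")
  z_mid <- mean(channel$membrane_z)
  n_rings <- floor(sc$length / sc$ring_spacing) + 1
  ring_z <- z_mid - sc$length / 2 + (seq_len(n_rings) - 1) * sc$ring_spacing
  m <- sc$atoms_per_ring
  rec <- list(); coo <- list()
  for (h in names(channel$helix_ranges)) {
    rng <- channel$helix_ranges[[h]]
    th_c <- .helix_angles[[h]]
    ang <- if (m > 1) th_c - 40 + (seq_len(m) - 1) * (80 / (m - 1)) else th_c
    ang <- ang * pi / 180
    for (r in seq_len(n_rings)) {
      resnum <- min(rng[1] + r - 1, rng[2])
      gate <- .gate_table[.gate_table$resnum == resnum &
                            .gate_table$helix == h, ]
      resname <- if (isTRUE(spec$gates) && nrow(gate)) gate$resname else "GLY"
      rec[[length(rec) + 1]] <- data.frame(
        name = "CA", element = "C", resname = resname, resnum = resnum,
        segment = h, stringsAsFactors = FALSE)
      coo[[length(coo) + 1]] <- cbind(sc$radius * cos(ang),
                                      sc$radius * sin(ang),
                                      rep(ring_z[r], m))
      rec[[length(rec)]] <- rec[[length(rec)]][rep(1, m), , drop = FALSE]
    }
  }
  # gate sidechains
  if (isTRUE(spec$gates)) {
    gate_geo <- gate_sidechain_geometry(spec, channel)
    for (g in seq_len(nrow(.gate_table))) {
      info <- .gate_table[g, ]
      if (!info$helix %in% names(channel$helix_ranges)) next
      geo <- gate_geo[[paste0(info$resnum, ":", info$resname)]]
      rec[[length(rec) + 1]] <- data.frame(
        name = geo$names, element = geo$elements, resname = info$resname,
        resnum = info$resnum, segment = info$helix, stringsAsFactors = FALSE)
      coo[[length(coo) + 1]] <- geo$xyz
    }
  }
  atoms_df <- do.call(rbind, rec)
  xyz <- do.call(rbind, coo)
  atoms <- atom_table(seq_len(nrow(atoms_df)), atoms_df$name,
                      atoms_df$resname, atoms_df$resnum, atoms_df$segment,
                      element = atoms_df$element)
  structure(list(atoms = atoms, xyz = xyz, time = 0), class = "traj_frame")
}

# Deterministic sidechain geometries in the base (contact-off) state.
# Acidic carboxylate oxygens sit near the axis on the S1 side; arginine
# guanidinium groups rest ~6 A away toward their own helix wall.
gate_sidechain_geometry <- function(spec, channel) {
  sc <- spec$scaffold
  z_mid <- mean(channel$membrane_z)
  ring_z_of <- function(resnum, helix) {
    rng <- channel$helix_ranges[[helix]]
    z_mid - sc$length / 2 + (resnum - rng[1]) * sc$ring_spacing
  }
  inward <- function(helix, dist, z, perp = 0) {
    th <- .helix_angles[[helix]] * pi / 180
    w <- sc$radius - dist
    c(w * cos(th) - perp * sin(th), w * sin(th) + perp * cos(th), z)
  }
  geo <- list()
  # ASP108 (S1): CB, CG inward; OD1/OD2 flank the axis at x=0-ish
  z108 <- ring_z_of(108, "S1")
  od1 <- c(0, 1.1, z108); od2 <- c(0, -1.1, z108)
  geo[["108:ASP"]] <- list(
    names = c("CB", "CG", "OD1", "OD2"),
    elements = c("C", "C", "O", "O"),
    xyz = rbind(inward("S1", 1.5, z108), inward("S1", 3.0, z108), od1, od2))
  # hydrophobic gates: carbon chains pointing inward
  hydroph <- function(helix, resnum, names) {
    z <- ring_z_of(resnum, helix)
    d <- seq(1.5, by = 1.0, length.out = length(names))
    perp <- rep(c(0, 0.6, -0.6), length.out = length(names))
    list(names = names, elements = rep("C", length(names)),
         xyz = t(mapply(function(di, pi_) inward(helix, di, z, pi_),
                        d, perp)))
  }
  geo[["143:LEU"]] <- hydroph("S2", 143, c("CB", "CG", "CD1", "CD2"))
  geo[["146:PHE"]] <- hydroph("S2", 146,
                              c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  geo[["178:PHE"]] <- hydroph("S3", 178,
                              c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  # arginines (S4): guanidinium resting ~6 A from the Asp oxygens
  arg_geo <- function(resnum) {
    z <- ring_z_of(resnum, "S4")
    cz <- c(6, 0, z)
    ne <- cz + c(1.0, 0.5, 0)
    nh1 <- cz + c(-0.6, 1.1, 0)
    nh2 <- cz + c(-0.6, -1.1, 0)
    list(names = c("CB", "CG", "CD", "NE", "HE", "CZ", "NH1", "HH11",
                   "NH2", "HH21"),
         elements = c("C", "C", "C", "N", "H", "C", "N", "H", "N", "H"),
         xyz = rbind(inward("S4", 1.5, z), inward("S4", 2.5, z),
                     inward("S4", 3.5, z), ne, ne + c(0, 1.0, 0), cz,
                     nh1, nh1 + c(-1.0, 0, 0), nh2, nh2 + c(-1.0, 0, 0)))
  }
  geo[["201:ARG"]] <- arg_geo(201)
  geo[["204:ARG"]] <- arg_geo(204)
  geo
}

#' Generate a synthetic trajectory with its ground-truth manifest
#'
#' Wire frames are drawn by seeded sampling without replacement of exactly
#' `round(wire_fraction * n_frames)` frames. In wire frames an axial water
#' chain spans the membrane slab at `wire_spacing`; in non-wire frames one
#' bond of the chain is widened to `gap_size` at a seeded interior
#' position. Helix z-schedules, contact schedules and gate drift are
#' applied as specified; the manifest records every planted fact.
#'
#' @param spec a [synthetic_spec()].
#' @param channel a [channel_definition()].
#' @return list with `trajectory` and `manifest`
#'   (class `"ground_truth_manifest"`).
#' @export
generate_trajectory <- function(spec = synthetic_spec(),
                                channel = channel_definition()) {
  set.seed(spec$seed)
  nf <- spec$n_frames
  n_wire <- round(spec$wire_fraction * nf)
  wire_frames <- sort(sample.int(nf, n_wire))
  is_wire <- seq_len(nf) %in% wire_frames

  base <- generate_scaffold(spec, channel)
  a <- base$atoms
  if (spec$jitter_sd > 0) {
    arc <- a$name == "CA"
    base$xyz[arc, 1:2] <- base$xyz[arc, 1:2] +
      stats::rnorm(2 * sum(arc), sd = spec$jitter_sd)
  }

  # water chain geometry (axial) --------------------------------------------
  zlo <- channel$membrane_z[1]; zhi <- channel$membrane_z[2]
  mar <- channel$boundary_margin
  sp <- spec$wire_spacing
  start <- zlo - 0.7 * mar
  k <- 1
  while (start + (k - 1) * sp < zhi + 0.2 * mar) k <- k + 1
  chain_z <- start + (seq_len(k) - 1) * sp
  clamp_top <- zhi + 0.8 * mar
  # eligible gap bonds keep both boundary contacts intact and stay clear
  # of the clamp region even after the shift
  bond_lo <- chain_z[-k]
  eligible <- which(bond_lo >= zlo + 2 & bond_lo <= zhi - spec$gap_size - 1)
  if (length(eligible) == 0) stop("no eligible gap positions; slab too thin")
  gap_bond <- integer(nf)
  gap_bond[!is_wire] <- eligible[
    sample.int(length(eligible), sum(!is_wire), replace = TRUE)]

  n_chain <- k
  n_decoy <- spec$decoy_waters
  wat_names <- rep("OH2", n_chain + n_decoy + 1)
  wat_res <- seq_len(n_chain + n_decoy + 1)
  decoy_xyz <- if (n_decoy > 0) {
    th <- 2 * pi * (seq_len(n_decoy) - 1) / n_decoy
    rr <- channel$water_cylinder_radius + 4
    cbind(rr * cos(th), rr * sin(th),
          seq(zlo + 2, zhi - 2, length.out = n_decoy))
  } else matrix(numeric(0), 0, 3)
  # one on-axis water above the selection window (z filter exercise)
  far_xyz <- matrix(c(0, 0, zhi + mar + 3), 1, 3)

  wat_atoms <- atom_table(max(a$index) + seq_along(wat_names), wat_names,
                          "TIP3", wat_res, "WAT", element = "O")
  atoms <- rbind(a, wat_atoms)
  natom <- nrow(atoms)
  chain_rows <- nrow(a) + seq_len(n_chain)
  decoy_rows <- nrow(a) + n_chain + seq_len(n_decoy)
  far_row <- natom

  # schedules ---------------------------------------------------------------
  helix_off <- lapply(channel$helix_ranges, function(...) numeric(nf))
  if (!is.null(spec$helix_schedules)) {
    for (h in names(spec$helix_schedules)) {
      v <- spec$helix_schedules[[h]]
      if (length(v) != nf) stop("helix schedule for ", h,
                                " must have one offset per frame")
      helix_off[[h]] <- v
    }
  }
  contacts <- spec$contact_schedule
  drift <- spec$gate_drift

  xyz <- array(NA_real_, dim = c(natom, 3, nf))
  prot_rows <- seq_len(nrow(a))
  for (f in seq_len(nf)) {
    fx <- base$xyz
    for (h in names(helix_off)) {
      if (helix_off[[h]][f] != 0) {
        rows <- which(a$segment == h)
        fx[rows, 3] <- fx[rows, 3] + helix_off[[h]][f]
      }
    }
    if (!is.null(drift)) {
      p <- parse_residue_spec(drift$residue)
      rows <- resolve_residue(a, p$resnum, p$resname)
      sc_rows <- rows[!(a$name[rows] %in% "CA")]
      frac <- if (nf > 1) (f - 1) / (nf - 1) else 0
      fx[sc_rows, 3] <- fx[sc_rows, 3] + drift$dz * frac
    }
    if (!is.null(contacts)) for (ct in contacts) {
      if (!(f %in% ct$on_frames)) next
      dp <- parse_residue_spec(ct$donor)
      ap <- parse_residue_spec(ct$acceptor)
      drows <- resolve_residue(a, dp$resnum, dp$resname)
      arows <- resolve_residue(a, ap$resnum, ap$resname)
      cz <- fx[drows[a$name[drows] == "CZ"], ]
      for (pair in list(c("NH1", "HH11", "OD1"), c("NH2", "HH21", "OD2"))) {
        nrow_ <- drows[a$name[drows] == pair[1]]
        hrow <- drows[a$name[drows] == pair[2]]
        orow <- arows[a$name[arows] == pair[3]]
        if (!length(nrow_) || !length(orow)) next
        v <- cz - fx[orow, ]
        v <- v / sqrt(sum(v^2))
        fx[nrow_, ] <- fx[orow, ] + 2.9 * v
        fx[hrow, ] <- fx[orow, ] + 1.9 * v
      }
    }
    # waters
    wz <- chain_z
    if (!is_wire[f]) {
      g <- gap_bond[f]
      wz[(g + 1):n_chain] <- wz[(g + 1):n_chain] + (spec$gap_size - sp)
    }
    wz <- pmin(wz, clamp_top)
    wxyz <- rbind(cbind(0, 0, wz), decoy_xyz, far_xyz)
    fx <- rbind(fx[prot_rows, , drop = FALSE], wxyz)
    xyz[, , f] <- fx
  }

  traj <- trajectory(atoms, xyz, time = (seq_len(nf) - 1) * spec$dt_ns)
  manifest <- structure(list(
    seed = spec$seed, n_frames = nf,
    wire_frames = wire_frames, wire_fraction = spec$wire_fraction,
    gap_bond = gap_bond,
    planted_helix_offsets = helix_off,
    planted_contacts = contacts,
    gate_drift = drift,
    pore_radius_by_z = spec$scaffold$radius - vdw_radius_of("C"),
    scaffold = spec$scaffold,
    water_rows = list(chain = chain_rows, decoy = decoy_rows,
                      far = far_row)),
    class = "ground_truth_manifest")
  list(trajectory = traj, manifest = manifest)
}

#' Check a trajectory against its ground-truth manifest
#'
#' Re-runs the analysis stages (water-wire classification, helix
#' z-kinematics, contact schedules, pore radius) and diffs the results
#' against the planted facts. Disagreements are reported, not thrown.
#'
#' @param traj the generated trajectory.
#' @param manifest its `"ground_truth_manifest"`.
#' @param channel a [channel_definition()].
#' @param criteria a [water_wire_criteria()].
#' @param pore_tol tolerance for the analytic pore radius, Angstrom.
#' @return list with `ok` (logical) and `report` (data.frame with one row
#'   per stage: stage, checked, mismatches).
#' @export
verify_manifest <- function(traj, manifest, channel = channel_definition(),
                            criteria = water_wire_criteria(),
                            pore_tol = 0.02) {
  rows <- list()
  add <- function(stage, checked, mism) rows[[length(rows) + 1]] <<-
    data.frame(stage = stage, checked = checked, mismatches = mism,
               stringsAsFactors = FALSE)

  occ <- occupancy_series(traj, channel, criteria)
  expected <- occ$frames %in% manifest$wire_frames
  add("hydration", length(expected), sum(occ$per_frame != expected))

  hz <- helix_z_series(traj, channel, rezero = FALSE)
  off <- do.call(cbind, manifest$planted_helix_offsets)
  rel <- off - rowMeans(off)
  mism <- 0L
  for (h in names(hz)) {
    d <- abs(hz[[h]]$z - rel[, h])
    mism <- mism + sum(d > 1e-6)
  }
  add("kinematics", length(hz) * n_frames(traj), mism)

  if (!is.null(manifest$planted_contacts)) {
    mism <- 0L; checked <- 0L
    for (ct in manifest$planted_contacts) {
      cs <- hbond_count_series(traj, ct$donor, ct$acceptor)
      on <- cs$frames %in% ct$on_frames
      mism <- mism + sum((cs$counts >= 1) != on)
      checked <- checked + length(on)
    }
    add("interactions", checked, mism)
  }

  # analytic pore check on a bare scaffold rebuilt from the manifest
  # (gate sidechains intentionally intrude into the pore, so the flat
  # analytic profile holds for the cylinder alone)
  bare <- generate_scaffold(
    synthetic_spec(n_frames = 1, seed = manifest$seed,
                   scaffold = manifest$scaffold, wire_fraction = 0,
                   gates = FALSE), channel)
  prof <- pore_profile(bare, channel)
  zlo <- channel$membrane_z[1]; zhi <- channel$membrane_z[2]
  interior <- prof$z_grid >= zlo + 3 & prof$z_grid <= zhi - 3
  d <- abs(prof$radii[interior] - manifest$pore_radius_by_z)
  add("pore", sum(interior), sum(d > pore_tol))

  report <- do.call(rbind, rows)
  list(ok = all(report$mismatches == 0), report = report)
}
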