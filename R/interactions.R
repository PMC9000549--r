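# Hydrogen-bond and salt-bridge time series. A hydrogen bond is judged
# geometrically: donor-acceptor heavy-atom distance within a cutoff and
# D-H...A deviation from linearity within an angle cutoff. Salt bridges
# are the subset whose donor is an Arg/Lys sidechain nitrogen and whose
# acceptor is an Asp/Glu carboxylate oxygen.

#' Hydrogen-bond geometric criteria
#'
#' @param distance_cutoff heavy-atom donor-acceptor cutoff, Angstrom
#'   (inclusive `<=`).
#' @param angle_cutoff maximum deviation of D-H...A from 180 degrees.
#' @param distance_mode `"heavy"` measures donor-heavy to acceptor-heavy
#'   distance; `"hydrogen"` measures H to acceptor.
#' @return object of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(distance_cutoff = 3.4, angle_cutoff = 30,
                           distance_mode = c("heavy", "hydrogen")) {
  if (distance_cutoff <= 0 || angle_cutoff <= 0)
    stop("cutoffs must be positive")
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff,
                 distance_mode = match.arg(distance_mode)),
            class = "hbond_criteria")
}

#' Test one donor-hydrogen-acceptor triple
#'
#' @param donor,hydrogen,acceptor length-3 positions (Angstrom).
#' @param criteria an [hbond_criteria()].
#' @return logical.
#' @export
is_hbond <- function(donor, hydrogen, acceptor,
                     criteria = hbond_criteria()) {
  donor <- as.numeric(donor); hydrogen <- as.numeric(hydrogen)
  acceptor <- as.numeric(acceptor)
  dh <- sqrt(sum((hydrogen - donor)^2))
  if (dh > 1.2)
    stop("hydrogen is not covalently bonded to the donor (D-H = ",
         sprintf("%.2f", dh), " A > 1.2 A)")
  d <- if (criteria$distance_mode == "heavy")
    sqrt(sum((acceptor - donor)^2)) else sqrt(sum((acceptor - hydrogen)^2))
  if (d > criteria$distance_cutoff) return(FALSE)
  u <- donor - hydrogen; v <- acceptor - hydrogen
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  (180 - ang) <= criteria$angle_cutoff
}

# Rows of `atoms` belonging to a residue; resname/segment disambiguate.
resolve_residue <- function(atoms, resnum, resname = NULL, segment = NULL) {
  keep <- atoms$resnum == resnum & !is_water(atoms$resname)
  if (!is.null(resname)) keep <- keep & atoms$resname == toupper(resname)
  if (!is.null(segment)) keep <- keep & atoms$segment == segment
  rows <- which(keep)
  if (length(rows) == 0)
    stop("residue not found: ", resnum,
         if (!is.null(resname)) paste0(":", resname) else "")
  rows
}

# Donor (heavy N/O with an attached H), hydrogen, and acceptor (N/O)
# row positions within one residue's rows.
.polar_atoms <- function(atoms, xyz, rows) {
  sub <- atoms[rows, , drop = FALSE]
  heavy <- rows[sub$element %in% c("N", "O")]
  hyd <- rows[sub$element == "H"]
  donors <- list()
  for (h in hyd) {
    if (length(heavy) == 0) next
    dd <- sqrt(rowSums((xyz[heavy, , drop = FALSE] -
                          matrix(xyz[h, ], length(heavy), 3, byrow = TRUE))^2))
    k <- which(dd <= 1.2)
    if (length(k)) donors[[length(donors) + 1L]] <-
        c(donor = heavy[which.min(dd)], hydrogen = h)
  }
  list(donors = donors, acceptors = heavy)
}

#' Per-frame hydrogen-bond count between two residues
#'
#' Counts (donor, H, acceptor) triples satisfying the criteria, in both
#' donor directions across the residue pair.
#'
#' @param traj a trajectory.
#' @param residueA,residueB residue numbers, or `"108:ASP"` strings to
#'   also match the residue name.
#' @param criteria an [hbond_criteria()].
#' @param equil_start first analyzed frame.
#' @return object of class `"contact_series"`: list with `pair`, `frames`,
#'   `counts`.
#' @export
hbond_count_series <- function(traj, residueA, residueB,
                               criteria = hbond_criteria(),
                               equil_start = 1) {
  pa <- parse_residue_spec(residueA)
  pb <- parse_residue_spec(residueB)
  a <- traj$atoms
  rowsA <- resolve_residue(a, pa$resnum, pa$resname)
  rowsB <- resolve_residue(a, pb$resnum, pb$resname)
  has_h <- function(rows) any(a$element[rows] == "H")
  if (!has_h(rowsA) && !has_h(rowsB))
    stop("neither residue carries hydrogens; add hydrogens or use a ",
         "distance-only criterion (angle_cutoff = Inf, distance_mode = 'heavy')")
  frames <- equil_start:n_frames(traj)
  counts <- vapply(frames, function(k) {
    xyz <- traj$xyz[, , k]
    n <- 0L
    for (dir in list(c(1, 2), c(2, 1))) {
      rd <- list(rowsA, rowsB)[[dir[1]]]
      ra <- list(rowsA, rowsB)[[dir[2]]]
      pol <- .polar_atoms(a, xyz, rd)
      acc <- .polar_atoms(a, xyz, ra)$acceptors
      for (dn in pol$donors) for (ac in acc) {
        if (is_hbond(xyz[dn["donor"], ], xyz[dn["hydrogen"], ], xyz[ac, ],
                     criteria)) n <- n + 1L
      }
    }
    n
  }, integer(1))
  structure(list(pair = c(format_residue(pa), format_residue(pb)),
                 frames = frames, counts = counts),
            class = "contact_series")
}

parse_residue_spec <- function(x) {
  if (is.list(x)) return(x)
  if (is.character(x) && grepl(":", x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    return(list(resnum = as.integer(parts[1]), resname = toupper(parts[2])))
  }
  list(resnum = as.integer(x), resname = NULL)
}

format_residue <- function(p) {
  if (is.null(p$resname)) as.character(p$resnum)
  else paste0(p$resnum, ":", p$resname)
}

#' Salt-bridge partner occupancy table
#'
#' For every (basic, acidic) residue pair, the fraction of analyzed frames
#' with at least one hydrogen bond between the basic sidechain nitrogens
#' (Arg NE/NH1/NH2, Lys NZ) and the acidic carboxylate oxygens (Asp
#' OD1/OD2, Glu OE1/OE2). The dominant partner of each acidic residue is
#' the basic residue with the highest occupancy (`"none"` when all zero).
#'
#' @param traj a trajectory.
#' @param basic_residues,acidic_residues vectors of residue specs
#'   (numbers or `"204:ARG"` strings).
#' @param criteria an [hbond_criteria()].
#' @param equil_start first analyzed frame.
#' @return list with `table` (data.frame basic, acidic, occupancy) and
#'   `dominant` (data.frame acidic, partner, occupancy).
#' @export
partner_occupancy_table <- function(traj, basic_residues, acidic_residues,
                                    criteria = hbond_criteria(),
                                    equil_start = 1) {
  if (length(basic_residues) == 0 || length(acidic_residues) == 0)
    stop("residue lists must be non-empty")
  a <- traj$atoms
  frames <- equil_start:n_frames(traj)
  basic_n <- c("NE", "NH1", "NH2", "NZ")
  acidic_o <- c("OD1", "OD2", "OE1", "OE2")
  grid <- expand.grid(b = seq_along(basic_residues),
                      d = seq_along(acidic_residues))
  occ <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pb <- parse_residue_spec(basic_residues[[grid$b[g]]])
    pd <- parse_residue_spec(acidic_residues[[grid$d[g]]])
    rowsB <- resolve_residue(a, pb$resnum, pb$resname)
    rowsD <- resolve_residue(a, pd$resnum, pd$resname)
    nrows <- rowsB[a$name[rowsB] %in% basic_n]
    orows <- rowsD[a$name[rowsD] %in% acidic_o]
    if (length(nrows) == 0 || length(orows) == 0) { occ[g] <- 0; next }
    # donor set: the sidechain nitrogens plus the residue's hydrogens
    hrows <- rowsB[a$element[rowsB] == "H"]
    on <- vapply(frames, function(k) {
      xyz <- traj$xyz[, , k]
      pol <- .polar_atoms(a, xyz, c(nrows, hrows))
      for (dn in pol$donors) for (ac in orows) {
        if (is_hbond(xyz[dn["donor"], ], xyz[dn["hydrogen"], ], xyz[ac, ],
                     criteria)) return(TRUE)
      }
      FALSE
    }, logical(1))
    occ[g] <- mean(on)
  }
  tab <- data.frame(
    basic = vapply(basic_residues[grid$b],
                   function(x) format_residue(parse_residue_spec(x)), ""),
    acidic = vapply(acidic_residues[grid$d],
                    function(x) format_residue(parse_residue_spec(x)), ""),
    occupancy = occ, stringsAsFactors = FALSE)
  dom <- do.call(rbind, lapply(split(tab, tab$acidic), function(s) {
    i <- which.max(s$occupancy)
    data.frame(acidic = s$acidic[1],
               partner = if (s$occupancy[i] > 0) s$basic[i] else "none",
               occupancy = s$occupancy[i], stringsAsFactors = FALSE)
  }))
  rownames(dom) <- NULL
  list(table = tab, dominant = dom)
}
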