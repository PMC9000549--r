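#' Build an atom table
#'
#' The atom table is the topology shared by every frame of a trajectory:
#' one row per atom with its identity, residue assignment, segment label
#' (helix name, "WAT", "MEMB", ...) and van der Waals radius.
#'
#' @param index integer atom serial numbers (unique, >= 0).
#' @param name atom names (e.g. "CA", "OH2", "NH1").
#' @param resname residue names (3-4 characters, e.g. "ARG", "TIP3").
#' @param resnum integer residue numbers.
#' @param segment segment labels (e.g. "S1".."S4", "WAT").
#' @param element element symbols; guessed from `name` when missing.
#' @param vdw van der Waals radii in Angstrom; looked up from `element`
#'   when missing.
#' @return data.frame with columns index, name, element, resname, resnum,
#'   segment, vdw.
#' @export
atom_table <- function(index, name, resname, resnum, segment,
                       element = NULL, vdw = NULL) {
  index <- as.integer(index)
  if (anyDuplicated(index)) stop("atom indices must be unique")
  if (any(index < 0L)) stop("atom indices must be >= 0")
  if (is.null(element)) element <- guess_element(name)
  if (is.null(vdw)) vdw <- vdw_radius_of(element)
  if (any(!is.finite(vdw)) || any(vdw <= 0)) stop("vdW radii must be positive")
  data.frame(index = index, name = as.character(name),
             element = as.character(element),
             resname = as.character(resname), resnum = as.integer(resnum),
             segment = as.character(segment), vdw = as.numeric(vdw),
             stringsAsFactors = FALSE)
}

#' Construct a trajectory
#'
#' @param atoms atom table (see [atom_table()]).
#' @param xyz numeric array of coordinates, dim `c(n_atoms, 3, n_frames)`,
#'   Angstrom. A single `n x 3` matrix is treated as one frame.
#' @param time per-frame time stamps in ns; defaults to 0.1 ns spacing.
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(atoms, xyz, time = NULL) {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  if (dim(xyz)[1] != nrow(atoms))
    stop("coordinate array and atom table disagree on atom count")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  nf <- dim(xyz)[3]
  if (is.null(time)) time <- (seq_len(nf) - 1) * 0.1
  if (length(time) != nf) stop("time stamps must match frame count")
  structure(list(atoms = atoms, xyz = xyz, time = as.numeric(time),
                 topology_checksum = topology_checksum(atoms)),
            class = "trajectory")
}

#' Number of frames / atoms in a trajectory
#' @param traj a trajectory.
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$xyz)[1]

#' Extract one frame
#'
#' @param traj a trajectory.
#' @param i frame index (1-based).
#' @return object of class `"traj_frame"`: list with `atoms`, `xyz`
#'   (`n x 3` matrix) and `time`.
#' @export
get_frame <- function(traj, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  structure(list(atoms = traj$atoms, xyz = traj$xyz[, , i, drop = TRUE],
                 time = traj$time[i]),
            class = "traj_frame")
}

#' Coerce a frame-like object to a traj_frame
#' @param x a `traj_frame`, or a trajectory (first frame taken).
#' @return a `traj_frame`.
#' @export
as_frame <- function(x) {
  if (inherits(x, "traj_frame")) return(x)
  if (inherits(x, "trajectory")) return(get_frame(x, 1L))
  stop("cannot coerce to traj_frame")
}

# Cheap order-sensitive checksum of the topology columns; used only to
# detect accidental mixing of frames from different systems.
topology_checksum <- function(atoms) {
  s <- paste(atoms$index, atoms$name, atoms$resname, atoms$resnum,
             atoms$segment, collapse = "|")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames x ", n_atoms(x), " atoms, ",
      sprintf("%.2f-%.2f ns", min(x$time), max(x$time)),
      "  [", x$topology_checksum, "]\n", sep = "")
  invisible(x)
}

# ---- readers / writers -----------------------------------------------------

#' Read a trajectory from file
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{pdb_multimodel}{fixed-column PDB with MODEL/ENDMDL blocks
#'     (CHARMM-style naming; waters as TIP3/TIP3P/HOH/WAT; segment id in
#'     columns 73-76).}
#'   \item{frame_csv}{long-format CSV with header
#'     `frame,index,name,resname,resnum,segment,x,y,z` (optional `element`),
#'     frames numbered from 1.}
#' }
#' vdW radii are assigned from the bundled element table.
#'
#' @param path input file.
#' @param format `"pdb_multimodel"` or `"frame_csv"`.
#' @param time optional per-frame times (ns).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("pdb_multimodel", "frame_csv"),
                            time = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb_multimodel") read_pdb_multimodel(path, time = time)
  else read_frame_csv(path, time = time)
}

read_pdb_multimodel <- function(path, time = NULL) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    blocks <- mapply(function(s, e) {
      idx <- seq(s, e)
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  if (length(blocks) == 0 || length(blocks[[1]]) == 0)
    stop("no ATOM/HETATM records in ", path)
  counts <- vapply(blocks, length, 1L)
  if (length(unique(counts)) != 1)
    stop("topology error: models have differing atom counts (",
         paste(unique(counts), collapse = ", "), ") in ", path)

  parse_block <- function(ln_idx) {
    ln <- lines[ln_idx]
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    bad <- which(is.na(x) | is.na(y) | is.na(z))
    if (length(bad))
      stop("parse error: malformed coordinates at line ", ln_idx[bad[1]],
           " of ", path)
    list(index = suppressWarnings(as.integer(substr(ln, 7, 11))),
         name = trimws(substr(ln, 13, 16)),
         resname = trimws(substr(ln, 18, 21)),
         resnum = suppressWarnings(as.integer(substr(ln, 23, 26))),
         segment = trimws(substr(ln, 73, 76)),
         element = trimws(substr(ln, 77, 78)),
         xyz = cbind(x, y, z))
  }
  first <- parse_block(blocks[[1]])
  if (anyNA(first$index) || anyNA(first$resnum))
    stop("parse error: malformed serial/residue field in ", path)
  elem <- ifelse(nzchar(first$element), first$element, guess_element(first$name))
  atoms <- atom_table(first$index, first$name, first$resname, first$resnum,
                      ifelse(nzchar(first$segment), first$segment, "MAIN"),
                      element = elem)
  nf <- length(blocks)
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3, nf))
  xyz[, , 1] <- first$xyz
  if (nf > 1) for (k in 2:nf) {
    b <- parse_block(blocks[[k]])
    same <- identical(b$index, first$index) && identical(b$name, first$name) &&
      identical(b$resnum, first$resnum)
    if (!same)
      stop("topology error: model ", k, " does not match model 1 in ", path)
    xyz[, , k] <- b$xyz
  }
  trajectory(atoms, xyz, time = time)
}

read_frame_csv <- function(path, time = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "index", "name", "resname", "resnum", "segment",
            "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: frame_csv missing column(s) ",
         paste(miss, collapse = ", "), " in ", path)
  df <- df[order(df$frame), , drop = FALSE]
  frames <- split(df, df$frame)
  first <- frames[[1]]
  counts <- vapply(frames, nrow, 1L)
  if (length(unique(counts)) != 1)
    stop("topology error: frames have differing atom counts in ", path)
  elem <- if ("element" %in% names(first)) first$element else guess_element(first$name)
  atoms <- atom_table(first$index, first$name, first$resname, first$resnum,
                      first$segment, element = elem)
  xyz <- array(NA_real_, dim = c(nrow(atoms), 3, length(frames)))
  for (k in seq_along(frames)) {
    fk <- frames[[k]]
    if (!identical(fk$index, first$index))
      stop("topology error: frame ", k, " atom identity differs in ", path)
    xyz[, , k] <- cbind(fk$x, fk$y, fk$z)
  }
  trajectory(atoms, xyz, time = time)
}

#' Write a trajectory to file
#'
#' `pdb_multimodel` writes fixed-column records (coordinates at PDB's three
#' decimal places); `frame_csv` writes full-precision coordinates so a
#' round trip is bitwise exact.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"pdb_multimodel"` or `"frame_csv"`.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb_multimodel", "frame_csv")) {
  format <- match.arg(format)
  if (!inherits(traj, "trajectory") || n_frames(traj) < 1)
    stop("non-empty trajectory required")
  a <- traj$atoms
  if (format == "pdb_multimodel") {
    con <- file(path, "w")
    on.exit(close(con))
    chain <- substr(a$segment, 1, 1)
    # atom name convention: pad 1-3 char names with a leading space
    nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                 sprintf(" %-3s", a$name))
    for (k in seq_len(n_frames(traj))) {
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
                         a$index, nm, substr(a$resname, 1, 4), chain, a$resnum,
                         traj$xyz[, 1, k], traj$xyz[, 2, k], traj$xyz[, 3, k],
                         1, 0, substr(a$segment, 1, 4), a$element), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    nf <- n_frames(traj)
    na <- n_atoms(traj)
    df <- data.frame(
      frame = rep(seq_len(nf), each = na),
      index = rep(a$index, nf), name = rep(a$name, nf),
      resname = rep(a$resname, nf), resnum = rep(a$resnum, nf),
      segment = rep(a$segment, nf), element = rep(a$element, nf),
      x = sprintf("%.17g", as.vector(traj$xyz[, 1, ])),
      y = sprintf("%.17g", as.vector(traj$xyz[, 2, ])),
      z = sprintf("%.17g", as.vector(traj$xyz[, 3, ])),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
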