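toy_traj <- function(nf = 2) {
  at <- atom_table(1:5, c("CA", "CA", "OH2", "NH1", "HH11"),
                   c("GLY", "ARG", "TIP3", "ARG", "ARG"),
                   c(97L, 204L, 1L, 204L, 204L),
                   c("S1", "S4", "WAT", "S4", "S4"))
  xyz <- array(0, dim = c(5, 3, nf))
  for (k in seq_len(nf)) xyz[, , k] <- matrix(seq_len(15), 5, 3) / 7 + k
  trajectory(at, xyz)
}

test_that("multi-model PDB round trip preserves counts and coordinates to PDB precision", {
  tr <- toy_traj(2)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f, "pdb_multimodel")
  back <- read_trajectory(f, "pdb_multimodel")
  expect_equal(n_frames(back), 2)
  expect_equal(n_atoms(back), 5)
  expect_lte(max(abs(back$xyz - tr$xyz)), 0.001)
  expect_equal(back$atoms$resname, tr$atoms$resname)
  expect_equal(back$atoms$segment, tr$atoms$segment)
  expect_equal(back$atoms$resnum, tr$atoms$resnum)
})

test_that("a model with a missing atom raises a topology error", {
  tr <- toy_traj(2)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f, "pdb_multimodel")
  lines <- readLines(f)
  atom_lines <- grep("^ATOM", lines)
  lines <- lines[-atom_lines[length(atom_lines)]]  # drop last atom of model 2
  writeLines(lines, f)
  expect_error(read_trajectory(f, "pdb_multimodel"), "topology")
})

test_that("a malformed coordinate field raises a parse error naming the line", {
  tr <- toy_traj(1)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f, "pdb_multimodel")
  lines <- readLines(f)
  i <- grep("^ATOM", lines)[2]
  substr(lines[i], 31, 38) <- "   xx.yz"
  writeLines(lines, f)
  expect_error(read_trajectory(f, "pdb_multimodel"), "parse error")
})

test_that("frame_csv round trip is bitwise exact, including generator output", {
  gen <- generate_trajectory(synthetic_spec(n_frames = 3, seed = 5,
                                            wire_fraction = 1/3))
  f <- tempfile(fileext = ".csv")
  write_trajectory(gen$trajectory, f, "frame_csv")
  back <- read_trajectory(f, "frame_csv")
  expect_identical(back$xyz, gen$trajectory$xyz)
  expect_identical(back$atoms$index, gen$trajectory$atoms$index)
})

test_that("write rejects empty input and preserves frame count on a long trajectory", {
  expect_error(write_trajectory(list(), tempfile(), "pdb_multimodel"),
               "non-empty")
  gen <- generate_trajectory(synthetic_spec(n_frames = 100, seed = 2,
                                            wire_fraction = 0.5,
                                            decoy_waters = 0))
  f <- tempfile(fileext = ".pdb")
  write_trajectory(gen$trajectory, f, "pdb_multimodel")
  expect_equal(n_frames(read_trajectory(f, "pdb_multimodel")), 100)
})

test_that("a single-model PDB without MODEL records reads as one frame", {
  tr <- toy_traj(1)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f, "pdb_multimodel")
  lines <- readLines(f)
  writeLines(lines[grepl("^ATOM|^END$", lines)], f)
  back <- read_trajectory(f, "pdb_multimodel")
  expect_equal(n_frames(back), 1)
  expect_lte(max(abs(back$xyz[, , 1] - tr$xyz[, , 1])), 0.001)
})

test_that("bio3d parses our PDB output consistently (independent reader)", {
  at <- atom_table(1:3, c("CA", "CB", "OD1"), "ASP", rep(108L, 3), "S1")
  xyz <- matrix(c(1.25, 2, 3, 4, 5.5, 6, 7, 8, 9.125), 3, 3, byrow = TRUE)
  tr <- trajectory(at, array(xyz, dim = c(3, 3, 1)))
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f, "pdb_multimodel")
  p <- bio3d::read.pdb(f, multi = TRUE)
  expect_equal(matrix(p$xyz[1, ], 3, 3, byrow = TRUE), xyz,
               tolerance = 1e-8)
  expect_equal(p$atom$resno, rep(108, 3))
})

test_that("vdW radii come from the element table with a warned fallback", {
  expect_equal(vdw_radius_of(c("C", "O", "N")), c(1.70, 1.52, 1.55))
  expect_warning(r <- vdw_radius_of("Xx"), "unknown element")
  expect_equal(r, 1.70)
})
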