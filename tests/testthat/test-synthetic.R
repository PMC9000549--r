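test_that("generation is deterministic for a fixed spec and seed", {
  spec <- synthetic_spec(n_frames = 12, seed = 19, wire_fraction = 0.25)
  g1 <- generate_trajectory(spec)
  g2 <- generate_trajectory(spec)
  expect_identical(g1$trajectory$xyz, g2$trajectory$xyz)
  expect_identical(g1$manifest$wire_frames, g2$manifest$wire_frames)
  # a different seed plants different wire frames (n large enough)
  g3 <- generate_trajectory(synthetic_spec(n_frames = 40, seed = 20,
                                           wire_fraction = 0.25))
  g4 <- generate_trajectory(synthetic_spec(n_frames = 40, seed = 21,
                                           wire_fraction = 0.25))
  expect_false(identical(g3$manifest$wire_frames, g4$manifest$wire_frames))
})

test_that("the scaffold has the predicted atom count and residue ranges", {
  spec <- synthetic_spec(gates = FALSE)
  fr <- generate_scaffold(spec)
  n_rings <- floor(spec$scaffold$length / spec$scaffold$ring_spacing) + 1
  expect_equal(nrow(fr$atoms), 4 * n_rings * spec$scaffold$atoms_per_ring)
  ch <- channel_definition()
  for (h in names(ch$helix_ranges)) {
    res <- fr$atoms$resnum[fr$atoms$segment == h]
    expect_gte(min(res), ch$helix_ranges[[h]][1])
    expect_lte(max(res), ch$helix_ranges[[h]][2])
  }
  # with gates, the extra atoms are the gate sidechains
  fr2 <- generate_scaffold(synthetic_spec())
  expect_gt(nrow(fr2$atoms), nrow(fr$atoms))
  expect_true(all(c("ASP", "PHE", "LEU", "ARG") %in% fr2$atoms$resname))
})

test_that("extreme wire fractions plant all-or-nothing hydration", {
  g0 <- generate_trajectory(synthetic_spec(n_frames = 8, seed = 4,
                                           wire_fraction = 0))
  expect_equal(occupancy_series(g0$trajectory,
                                channel_definition())$occupancy, 0)
  g1 <- generate_trajectory(synthetic_spec(n_frames = 8, seed = 4,
                                           wire_fraction = 1))
  expect_equal(occupancy_series(g1$trajectory,
                                channel_definition())$occupancy, 1)
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(n_frames = 10, wire_fraction = 0.25),
               "not an integer")
  expect_error(synthetic_spec(wire_spacing = 3.5), "wire_spacing")
  expect_error(synthetic_spec(gap_size = 3.0), "wire_spacing")
  expect_error(synthetic_spec(scaffold = list(radius = 0, length = 36,
                                              atoms_per_ring = 6,
                                              ring_spacing = 1.5)),
               "degenerate")
})

test_that("manifest verification passes untouched output and flags perturbations", {
  spec <- synthetic_spec(n_frames = 10, seed = 37, wire_fraction = 0.3,
                         contact_schedule = list(list(donor = "204:ARG",
                                                      acceptor = "108:ASP",
                                                      on_frames = 6:10)))
  gen <- generate_trajectory(spec)
  v <- verify_manifest(gen$trajectory, gen$manifest)
  expect_true(v$ok)
  expect_true(all(v$report$mismatches == 0))
  # widen one wire frame's chain gap by shifting its upper waters
  tr <- gen$trajectory
  wf <- gen$manifest$wire_frames[1]
  chain <- gen$manifest$water_rows$chain
  upper <- chain[seq(ceiling(length(chain) / 2), length(chain))]
  tr$xyz[upper, 3, wf] <- tr$xyz[upper, 3, wf] + 1.2
  v2 <- verify_manifest(tr, gen$manifest)
  expect_false(v2$ok)
  expect_equal(v2$report$mismatches[v2$report$stage == "hydration"], 1)
})

test_that("planted facts are recovered across a sweep of seeds", {
  for (seed in c(101, 202, 303, 404, 505)) {
    spec <- synthetic_spec(n_frames = 10, seed = seed, wire_fraction = 0.4)
    gen <- generate_trajectory(spec)
    v <- verify_manifest(gen$trajectory, gen$manifest)
    expect_true(v$ok)
  }
})
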