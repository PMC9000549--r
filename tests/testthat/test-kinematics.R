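test_that("helix z-series cancel whole-channel translation and split single-helix shifts", {
  n <- 10
  # rigid whole-channel translation: all four helices move together
  spec_all <- synthetic_spec(
    n_frames = n, seed = 2, wire_fraction = 0.5,
    helix_schedules = list(S1 = seq(0, 5, length.out = n),
                           S2 = seq(0, 5, length.out = n),
                           S3 = seq(0, 5, length.out = n),
                           S4 = seq(0, 5, length.out = n)))
  gen <- generate_trajectory(spec_all)
  hz <- helix_z_series(gen$trajectory, channel_definition(), rezero = FALSE)
  for (h in names(hz)) expect_lt(max(abs(hz[[h]]$z)), 1e-9)
  # only S4 moves +2: with equal helix atom counts S4 gets +1.5, rest -0.5
  spec_s4 <- synthetic_spec(n_frames = n, seed = 2, wire_fraction = 0.5,
                            helix_schedules = list(S4 = c(rep(0, 5),
                                                          rep(2, 5))))
  gen2 <- generate_trajectory(spec_s4)
  hz2 <- helix_z_series(gen2$trajectory, channel_definition(),
                        rezero = FALSE)
  expect_equal(hz2$S4$z[6:10], rep(1.5, 5), tolerance = 1e-9)
  expect_equal(hz2$S2$z[6:10], rep(-0.5, 5), tolerance = 1e-9)
  expect_equal(hz2$S1$z[1:5], rep(0, 5), tolerance = 1e-9)
})

test_that("atom-count-weighted helix displacements sum to zero in every frame", {
  n <- 6
  spec <- synthetic_spec(n_frames = n, seed = 5, wire_fraction = 0.5,
                         helix_schedules = list(S2 = seq(0, -3, length.out = n),
                                                S4 = seq(0, 2, length.out = n)))
  gen <- generate_trajectory(spec)
  hz <- helix_z_series(gen$trajectory, channel_definition(), rezero = FALSE)
  # equal alpha-carbon counts per helix in the synthetic scaffold
  total <- Reduce(`+`, lapply(hz, `[[`, "z"))
  expect_lt(max(abs(total)), 1e-9)
})

test_that("sidechain z-series recover a planted linear drift", {
  n <- 11
  spec <- synthetic_spec(n_frames = n, seed = 7, wire_fraction = 0,
                         gate_drift = list(residue = "204:ARG", dz = 10))
  gen <- generate_trajectory(spec)
  s <- sidechain_z_series(gen$trajectory, "204:ARG",
                          superpose_on = "108:ASP")
  drift <- s$z - s$z[1]
  expect_equal(drift, seq(0, 10, length.out = n), tolerance = 1e-6)
  # slope per frame = dz / (n - 1)
  slope <- stats::coef(stats::lm(s$z ~ seq_len(n)))[2]
  expect_equal(unname(slope), 1, tolerance = 1e-6)
})

test_that("anchored superposition removes whole-system translation", {
  gen <- generate_trajectory(synthetic_spec(n_frames = 5, seed = 3,
                                            wire_fraction = 0))
  tr <- gen$trajectory
  for (k in 2:5) tr$xyz[, , k] <- tr$xyz[, , k] + (k - 1) * 1.7
  s <- sidechain_z_series(tr, "146:PHE", superpose_on = "108:ASP")
  expect_lt(max(abs(s$z - s$z[1])), 1e-9)
  # raw series without superposition does see the translation
  raw <- sidechain_z_series(tr, "146:PHE")
  expect_gt(max(abs(raw$z - raw$z[1])), 1)
  # self-anchored tracking of the anchor is constant by construction
  self <- sidechain_z_series(tr, "108:ASP", superpose_on = "108:ASP")
  expect_lt(max(abs(self$z - self$z[1])), 1e-9)
})

test_that("residues without sidechain heavy atoms are rejected", {
  gen <- generate_trajectory(synthetic_spec(n_frames = 2, seed = 1,
                                            wire_fraction = 0.5))
  # scaffold residue 100 is a backbone-only pseudo-glycine
  expect_error(sidechain_z_series(gen$trajectory, 100), "sidechain")
})

test_that("gate z-gap tracks a planted downward gate drift", {
  n <- 8
  gen0 <- generate_trajectory(synthetic_spec(n_frames = n, seed = 11,
                                             wire_fraction = 0))
  gap0 <- gate_z_gap(gen0$trajectory, "146:PHE", "108:ASP")
  expect_lt(max(abs(gap0$z - gap0$z[1])), 1e-9)  # static: constant gap
  spec <- synthetic_spec(n_frames = n, seed = 11, wire_fraction = 0,
                         gate_drift = list(residue = "146:PHE", dz = -2))
  gen <- generate_trajectory(spec)
  gap <- gate_z_gap(gen$trajectory, "146:PHE", "108:ASP")
  expect_equal(gap$z[n] - gap$z[1], -2, tolerance = 0.01)
})

test_that("final-window summary reads the tail of a displacement series", {
  s <- structure(list(label = "S4", frames = 1:10,
                      z = c(rep(0, 8), 2, 2), reference = "four_helix_center"),
                 class = "displacement_series")
  expect_equal(final_displacement(s, 0.2), 2)
})
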