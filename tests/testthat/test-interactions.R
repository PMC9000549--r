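test_that("the donor-hydrogen-acceptor test applies distance and angle cutoffs", {
  d <- c(0, 0, 0); h <- c(1, 0, 0)
  expect_true(is_hbond(d, h, c(2.9, 0, 0)))            # ideal collinear
  expect_false(is_hbond(d, h, c(3.5, 0, 0)))           # beyond cutoff
  # 2.9 A heavy-heavy but 45 degrees off line
  th <- 45 * pi / 180
  a45 <- h + 1.9 * c(cos(th), sin(th), 0)
  dev <- 180 - acos(sum((d - h) * (a45 - h)) /
                      sqrt(sum((d - h)^2) * sum((a45 - h)^2))) * 180 / pi
  expect_equal(dev, 45, tolerance = 1e-9)
  expect_false(is_hbond(d, h, a45,
                        hbond_criteria(distance_cutoff = 10)))
  expect_error(is_hbond(d, c(2, 0, 0), c(2.9, 0, 0)), "not covalently")
})

test_that("the hydrogen distance mode measures H-to-acceptor", {
  d <- c(0, 0, 0); h <- c(1, 0, 0); a <- c(3.3, 0, 0)
  expect_true(is_hbond(d, h, a, hbond_criteria(distance_mode = "hydrogen")))
  a2 <- c(4.5, 0, 0)  # H...A 3.5
  expect_false(is_hbond(d, h, a2, hbond_criteria(distance_mode = "hydrogen")))
})

test_that("a planted bidentate Arg-Asp contact counts exactly two hydrogen bonds", {
  spec <- synthetic_spec(n_frames = 4, seed = 9, wire_fraction = 0.5,
                         contact_schedule = list(list(donor = "204:ARG",
                                                      acceptor = "108:ASP",
                                                      on_frames = 3:4)))
  gen <- generate_trajectory(spec)
  cs <- hbond_count_series(gen$trajectory, "204:ARG", "108:ASP")
  expect_equal(cs$counts, c(0L, 0L, 2L, 2L))
  # symmetric in argument order
  cs2 <- hbond_count_series(gen$trajectory, "108:ASP", "204:ARG")
  expect_equal(cs2$counts, cs$counts)
})

test_that("residues far apart never count and hydrogen-less pairs advise", {
  gen <- generate_trajectory(synthetic_spec(n_frames = 2, seed = 1,
                                            wire_fraction = 0.5))
  cs <- hbond_count_series(gen$trajectory, "204:ARG", "178:PHE")
  expect_true(all(cs$counts == 0))
  expect_error(hbond_count_series(gen$trajectory, "146:PHE", "108:ASP"),
               "distance-only")
})

test_that("loosening either cutoff never decreases per-frame counts", {
  spec <- synthetic_spec(n_frames = 4, seed = 13, wire_fraction = 0.5,
                         contact_schedule = list(list(donor = "204:ARG",
                                                      acceptor = "108:ASP",
                                                      on_frames = c(2, 4))))
  gen <- generate_trajectory(spec)
  tight <- hbond_count_series(gen$trajectory, "204:ARG", "108:ASP",
                              hbond_criteria(3.0, 20))
  loose <- hbond_count_series(gen$trajectory, "204:ARG", "108:ASP",
                              hbond_criteria(3.8, 40))
  expect_true(all(loose$counts >= tight$counts))
})

test_that("partner occupancy captures a scheduled mid-trajectory switch", {
  n <- 20
  spec <- synthetic_spec(
    n_frames = n, seed = 23, wire_fraction = 0.5,
    contact_schedule = list(
      list(donor = "201:ARG", acceptor = "108:ASP", on_frames = 1:(n / 2)),
      list(donor = "204:ARG", acceptor = "108:ASP",
           on_frames = (n / 2 + 1):n)))
  gen <- generate_trajectory(spec)
  tab <- partner_occupancy_table(gen$trajectory, c("201:ARG", "204:ARG"),
                                 c("108:ASP"))
  occ <- tab$table$occupancy
  names(occ) <- tab$table$basic
  expect_equal(unname(occ["201:ARG"]), 0.5)
  expect_equal(unname(occ["204:ARG"]), 0.5)
})

test_that("an always-on pair is dominant and absent contacts give zeros", {
  n <- 6
  spec <- synthetic_spec(n_frames = n, seed = 29, wire_fraction = 0.5,
                         contact_schedule = list(list(donor = "204:ARG",
                                                      acceptor = "108:ASP",
                                                      on_frames = 1:n)))
  gen <- generate_trajectory(spec)
  tab <- partner_occupancy_table(gen$trajectory, c("204:ARG", "201:ARG"),
                                 c("108:ASP"))
  expect_equal(tab$dominant$partner, "204:ARG")
  expect_equal(tab$dominant$occupancy, 1.0)
  # no schedule at all -> all zero, dominant none
  gen0 <- generate_trajectory(synthetic_spec(n_frames = 4, seed = 31,
                                             wire_fraction = 0.5))
  tab0 <- partner_occupancy_table(gen0$trajectory, c("204:ARG", "201:ARG"),
                                  c("108:ASP"))
  expect_true(all(tab0$table$occupancy == 0))
  expect_equal(tab0$dominant$partner, "none")
  expect_error(partner_occupancy_table(gen0$trajectory, list(), c("108:ASP")),
               "non-empty")
})
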