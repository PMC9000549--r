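test_that("channel water selection is a cylinder-plus-margin membership test", {
  tc <- toy_channel_frame(rbind(c(0, 0, 0),        # axis center, mid-membrane
                                c(12, 0, 0),       # 2x radius off-axis
                                c(0, 0, 11),       # inside margin
                                c(0, 0, 13)))      # beyond margin
  sel <- select_channel_waters(tc$frame, tc$channel)
  watix <- tc$frame$atoms$index[tc$frame$atoms$segment == "WAT"]
  expect_true(watix[1] %in% sel)
  expect_false(watix[2] %in% sel)
  expect_true(watix[3] %in% sel)
  expect_false(watix[4] %in% sel)
})

test_that("selection of random waters equals the brute-force cylinder oracle", {
  set.seed(17)
  xyz <- cbind(stats::runif(100, -15, 15), stats::runif(100, -15, 15),
               stats::runif(100, -15, 15))
  tc <- toy_channel_frame(xyz)
  sel <- select_channel_waters(tc$frame, tc$channel)
  watix <- tc$frame$atoms$index[tc$frame$atoms$segment == "WAT"]
  want <- oracle_in_cylinder(xyz, c(0, 0), 6, -10, 10, 2)
  expect_setequal(sel, watix[want])
})

test_that("water adjacency applies a strict O-O cutoff", {
  fr <- water_frame(rbind(c(0, 0, 0), c(2.8, 0, 0)))
  expect_equal(nrow(water_adjacency(1:2, fr)), 1)
  fr2 <- water_frame(rbind(c(0, 0, 0), c(3.4, 0, 0)))
  expect_equal(nrow(water_adjacency(1:2, fr2)), 0)  # "less than", not <=
})

test_that("adjacency on random clouds equals the O(n^2) oracle", {
  for (seed in c(5, 6, 7)) {
    set.seed(seed)
    xyz <- matrix(stats::runif(150, 0, 12), 50, 3)
    fr <- water_frame(xyz)
    edges <- water_adjacency(seq_len(50), fr)
    want <- oracle_adjacency(xyz, 3.4)
    got <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    dimnames(got) <- NULL
    expect_equal(got, want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("a planted axial chain is continuous and a single widened gap breaks it", {
  z <- seq(-11, 11, length.out = 9)  # spacing 2.75 A, ends beyond the slab
  chain <- cbind(0, 0, z)
  tc <- toy_channel_frame(chain)
  cls <- classify_frame(tc$frame, tc$channel)
  expect_true(cls$continuous)
  expect_gte(length(cls$path), 2)
  # the reported path respects the cutoff link-by-link
  pxy <- tc$frame$xyz[match(cls$path, tc$frame$atoms$index), ]
  hops <- sqrt(rowSums(diff(pxy)^2))
  expect_true(all(hops < 3.4))
  # widen one interior bond to 3.5 A
  broken <- chain
  broken[5:nrow(broken), 3] <- broken[5:nrow(broken), 3] + 0.7
  tc2 <- toy_channel_frame(broken)
  expect_false(classify_frame(tc2$frame, tc2$channel)$continuous)
})

test_that("classification of random water clouds equals the union-find oracle", {
  for (seed in c(31, 32, 33, 34)) {
    set.seed(seed)
    n <- 200
    xyz <- cbind(stats::runif(n, -5, 5), stats::runif(n, -5, 5),
                 stats::runif(n, -12, 12))
    tc <- toy_channel_frame(xyz)
    got <- classify_frame(tc$frame, tc$channel)$continuous
    inside <- oracle_in_cylinder(xyz, c(0, 0), 6, -10, 10, 2)
    want <- oracle_spans(xyz[inside, , drop = FALSE], 3.4, -10, 10)
    expect_equal(got, want)
  }
})

test_that("raising the cutoff never breaks continuity (edge-set monotonicity)", {
  set.seed(41)
  for (i in 1:5) {
    xyz <- cbind(stats::runif(60, -4, 4), stats::runif(60, -4, 4),
                 stats::runif(60, -12, 12))
    tc <- toy_channel_frame(xyz)
    tight <- classify_frame(tc$frame, tc$channel, water_wire_criteria(3.0))
    loose <- classify_frame(tc$frame, tc$channel, water_wire_criteria(3.8))
    if (tight$continuous) expect_true(loose$continuous)
  }
})

test_that("classification is invariant to water index permutation", {
  set.seed(51)
  xyz <- cbind(stats::runif(40, -3, 3), stats::runif(40, -3, 3),
               stats::runif(40, -12, 12))
  tc <- toy_channel_frame(xyz)
  base <- classify_frame(tc$frame, tc$channel)
  perm <- sample(40)
  tc2 <- toy_channel_frame(xyz[perm, ])
  expect_equal(classify_frame(tc2$frame, tc2$channel)$continuous,
               base$continuous)
})

test_that("occupancy and run lengths summarize the per-frame classification", {
  gen <- generate_trajectory(synthetic_spec(n_frames = 10, seed = 3,
                                            wire_fraction = 1))
  occ <- occupancy_series(gen$trajectory, channel_definition())
  expect_equal(occ$occupancy, 1.0)
  expect_equal(occ$run_lengths, 10)
  # alternating frames -> all runs of length 1
  spec <- synthetic_spec(n_frames = 6, seed = 1, wire_fraction = 0.5)
  gen2 <- generate_trajectory(spec)
  tr <- gen2$trajectory
  # rebuild an exactly alternating trajectory from wire/non-wire exemplars
  wire_f <- gen2$manifest$wire_frames[1]
  dry_f <- setdiff(1:6, gen2$manifest$wire_frames)[1]
  xyz <- tr$xyz
  for (k in 1:6) xyz[, , k] <- tr$xyz[, , if (k %% 2) wire_f else dry_f]
  alt <- trajectory(tr$atoms, xyz)
  occ2 <- occupancy_series(alt, channel_definition())
  expect_equal(occ2$occupancy, 0.5)
  expect_true(all(occ2$run_lengths == 1))
  expect_error(occupancy_series(tr, channel_definition(), equil_start = 99),
               "empty frame range")
})
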