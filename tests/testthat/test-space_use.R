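test_that("zone_sequence merges equal-label runs and checks contiguity", {
  zs <- zseq_of(c("patch:1", "patch:1", "c12:a", "patch:1"))
  expect_equal(nrow(zs), 3)
  expect_equal(zs$t_end[1] - zs$t_start[1], 2)
  expect_error(zone_sequence(c("patch:1", "patch:2"), c(0, 5), c(1, 6)),
               "contiguous")
  expect_error(zone_sequence(character(0), numeric(0), numeric(0)), "empty")
})

test_that("label_zones segments a hand-built path in order", {
  mz <- build_maze(two_patch_config())
  ch <- mz$channels[[1]]
  pts <- rbind(
    c(mz$patches$cx[1], mz$patches$cy[1]),
    t(sapply(c(0.15, 0.5, 0.85), function(f) ch$p0 + f * ch$length * ch$axis)),
    c(mz$patches$cx[2], mz$patches$cy[2]))
  traj <- trajectory(0:4, pts[, 1], pts[, 2])
  zs <- label_zones(traj, mz)
  expect_equal(zs$label, c("patch:1", "c12:a", "c12:b", "c12:c", "patch:2"))
  # reversed path gives reversed segments
  zs_r <- label_zones(trajectory(0:4, rev(pts[, 1]), rev(pts[, 2])), mz)
  expect_equal(zs_r$label, rev(zs$label))
})

test_that("undetected runs inherit the preceding zone label", {
  mz <- build_maze(two_patch_config())
  x <- rep(mz$patches$cx[1], 6); y <- rep(mz$patches$cy[1], 6)
  x[5:6] <- mz$patches$cx[2]; y[5:6] <- mz$patches$cy[2]
  det <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  x[!det] <- NA; y[!det] <- NA
  traj <- trajectory(0:5, x, y, detected = det)
  zs <- label_zones(traj, mz)
  expect_equal(zs$label, c("patch:1", "patch:2"))
  expect_equal(zs$t_end[1], 4)   # samples 3 and 4 stay with patch 1
})

test_that("the transition machine reproduces the three canonical crossings", {
  full <- count_transitions(zseq_of(c("patch:1", "c12:a", "c12:b", "c12:c", "patch:2")))
  expect_equal(full$direction, 1L)
  expect_equal(full$channel_id, "c12")

  back <- count_transitions(zseq_of(c("patch:1", "c12:a", "c12:b", "c12:a", "patch:1")))
  expect_equal(nrow(back), 0)

  triple <- count_transitions(zseq_of(c(
    "patch:1", "c12:a", "c12:b", "c12:c", "patch:2",
    "c12:c", "c12:b", "c12:a", "patch:1",
    "c12:a", "c12:b", "c12:c", "patch:2")))
  expect_equal(triple$direction, c(1L, -1L, 1L))
})

test_that("transition machine matches the brute-force scan on random strings", {
  set.seed(21)
  for (rep in 1:1000) {
    len <- sample(1:20, 1)
    subs <- sample(c("a", "b", "c"), len, replace = TRUE)
    zs <- zseq_of(paste0("c12:", subs))
    got <- count_transitions(zs)$direction
    expect_identical(got, oracle_crossings(subs))
  }
})

test_that("a patch interruption resets the machine", {
  zs <- zseq_of(c("patch:1", "c12:a", "c12:b", "patch:1", "c12:b", "c12:c", "patch:2"))
  expect_equal(nrow(count_transitions(zs)), 0)
  # and so does hopping to a different channel
  zs2 <- zseq_of(c("c12:a", "c12:b", "c34:c", "c12:c"))
  expect_equal(nrow(count_transitions(zs2)), 0)
})

test_that("reversing complete-traversal sequences negates the event list", {
  # (antisymmetry cannot hold for overlapping partials such as a,b,c,b,a,
  # where the single shared 'c' can complete only one crossing either way;
  # with patch-separated complete traversals it must hold exactly)
  set.seed(22)
  for (rep in 1:50) {
    blocks <- sample(c("fwd", "rev"), sample(1:6, 1), replace = TRUE)
    labs <- "patch:1"
    for (b in blocks) {
      subs <- if (b == "fwd") c("a", "b", "c") else c("c", "b", "a")
      labs <- c(labs, paste0("c12:", subs),
                if (b == "fwd") "patch:2" else "patch:1")
    }
    fwd <- count_transitions(zseq_of(labs))$direction
    expect_identical(fwd, ifelse(blocks == "fwd", 1L, -1L))
    rev_ev <- count_transitions(zseq_of(rev(labs)))$direction
    expect_identical(rev_ev, -rev(fwd))
  }
})

test_that("visits follow the 30-s qualification rule", {
  long <- detect_visits(zseq_of("patch:1", durations = 40))
  expect_true(long$qualifying)
  short <- detect_visits(zseq_of("patch:1", durations = 20))
  expect_equal(nrow(short), 1)
  expect_false(short$qualifying)
})

test_that("a channel excursion without a completed crossing merges the visit", {
  zs <- zseq_of(c("patch:1", "c12:a", "c12:b", "c12:a", "patch:1"),
                durations = c(40, 2, 1, 2, 40))
  v <- detect_visits(zs)
  expect_equal(nrow(v), 1)
  expect_equal(v$duration, 80)     # the 5-s excursion is excluded
  expect_equal(v$t_enter, 0)
  expect_equal(v$t_exit, 85)
  expect_true(v$qualifying)

  # a completed out-and-back crossing splits the visit instead
  zs2 <- zseq_of(c("patch:1", "c12:a", "c12:b", "c12:c", "patch:2",
                   "c12:c", "c12:b", "c12:a", "patch:1"),
                 durations = c(40, 1, 1, 1, 35, 1, 1, 1, 40))
  v2 <- detect_visits(zs2)
  expect_equal(v2$patch_id, c("1", "2", "1"))
  # an excursion through 'outside' splits as well
  zs3 <- zseq_of(c("patch:1", "outside", "patch:1"), durations = c(40, 2, 40))
  expect_equal(nrow(detect_visits(zs3)), 2)
})

test_that("space-use summary implements the four descriptors", {
  mz <- build_maze(two_patch_config())   # patch 1 holds resource
  vis <- data.frame(patch_id = c("1", "1", "1", "2"),
                    t_enter = c(0, 700, 2000, 3900),
                    t_exit = c(600, 1900, 3800, 3950),
                    duration = c(600, 1200, 1800, 50),
                    qualifying = TRUE)
  tr <- data.frame(channel_id = character(0), direction = integer(0),
                   t = numeric(0))
  s <- summarize_space_use(vis, tr, mz, duration = 7200)
  expect_equal(s$gut_min, mean(c(10, 20, 30)))
  expect_equal(s$n_resource_visits, 3)
  expect_equal(s$cumulative_space_m2, 3 * 0.01)
  expect_equal(s$total_time_patches_min, 3650 / 60)
  expect_equal(s$percent_time_patches, 100 * 3650 / 7200)

  # a single qualifying resource visit credits exactly 0.01 m^2
  one <- summarize_space_use(vis[1, ], tr, mz, duration = 7200)
  expect_equal(one$cumulative_space_m2, 0.01)

  # no qualifying resource visits: GUT is missing, not zero
  none <- summarize_space_use(vis[4, ], tr, mz, duration = 7200)
  expect_true(is.na(none$gut_min))
  expect_equal(none$cumulative_space_m2, 0)
})

test_that("occupancy bins split time by zone class", {
  mz <- build_maze(two_patch_config())
  zs <- zone_sequence(c("patch:1", "c12:b", "patch:2"),
                      c(0, 60, 75), c(60, 75, 120))
  occ <- occupancy_bins(zs, mz, bin = 30)
  expect_equal(nrow(occ), 4)
  # patch 1 holds the resource; patch 2 is empty; bin 3 spans [60, 90):
  # 15 s of channel then 15 s of the empty patch
  expect_equal(occ$frac_resource, c(1, 1, 0, 0))
  expect_equal(occ$frac_channel, c(0, 0, 0.5, 0))
  expect_equal(occ$frac_empty, c(0, 0, 0.5, 1))
  expect_true(all(abs(occ$frac_resource + occ$frac_empty +
                        occ$frac_channel + occ$frac_outside - 1) < 1e-9))
})

test_that("segment durations conserve the trajectory span", {
  mz <- default_maze()
  for (seed in 1:5) {
    sim <- simulate_individual(forager_params(mean_residence = 60), mz,
                               duration = 240, seed = seed)
    zs <- label_zones(sim$trajectory, mz)
    span <- max(sim$trajectory$t) - min(sim$trajectory$t)
    expect_equal(sum(zs$t_end - zs$t_start), span, tolerance = 1e-9)
  }
})
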