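test_that("simulation is deterministic under a fixed seed", {
  mz <- default_maze()
  a <- simulate_individual(forager_params(), mz, duration = 60, seed = 101)
  b <- simulate_individual(forager_params(), mz, duration = 60, seed = 101)
  expect_identical(as.data.frame(a$trajectory), as.data.frame(b$trajectory))
  expect_identical(a$ground_truth$labels, b$ground_truth$labels)
  c <- simulate_individual(forager_params(), mz, duration = 60, seed = 102)
  expect_false(identical(a$trajectory$x, c$trajectory$x))
  # the global RNG stream is left untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulate_individual(forager_params(), mz, 10, seed = 5))
  expect_identical(runif(3), before)
})

test_that("a zero-speed forager stays put in its start patch", {
  mz <- default_maze()
  sim <- simulate_individual(forager_params(mean_speed = 0, speed_sd = 0),
                             mz, duration = 30, seed = 3, start_patch = "4")
  expect_true(all(sim$trajectory$x == mz$patches$cx[4]))
  expect_true(all(sim$trajectory$y == mz$patches$cy[4]))
  expect_true(all(sim$ground_truth$labels == "patch:4"))
  expect_equal(nrow(sim$ground_truth$transitions), 0)
})

test_that("simulated positions stay inside the arena footprint", {
  mz <- default_maze()
  for (seed in c(14, 15)) {
    sim <- simulate_individual(forager_params(mean_residence = 60), mz,
                               duration = 600, seed = seed)
    inside <- in_polygon(sim$trajectory$x, sim$trajectory$y, mz$arena)
    expect_true(all(inside))
    # and never outside all zones: labels partition into patch/channel only
    expect_false(any(startsWith(sim$ground_truth$labels, "outside")))
  }
})

test_that("measurement chain reproduces the simulator's own ground truth", {
  mz <- default_maze()
  sim <- simulate_individual(forager_params(mean_residence = 90), mz,
                             duration = 600, seed = 17)
  zs <- label_zones(sim$trajectory, mz)
  vis <- detect_visits(zs)
  trans <- count_transitions(zs)
  gt <- sim$ground_truth
  expect_equal(nrow(vis), nrow(gt$visits))
  expect_equal(vis$patch_id, gt$visits$patch_id)
  expect_equal(vis$duration, gt$visits$duration, tolerance = 1e-9)
  expect_equal(trans$channel_id, gt$transitions$channel_id)
  expect_equal(trans$direction, gt$transitions$direction)
})

test_that("qualifying visit durations match the truncated-exponential mean", {
  mz <- default_maze()
  durs <- unlist(lapply(1:3, function(seed) {
    sim <- simulate_individual(
      forager_params(mean_residence = 600, channel_abort_prob = 0),
      mz, duration = 14400, seed = 200 + seed)
    v <- sim$ground_truth$visits
    v$duration[v$qualifying & v$t_exit < 14350]   # drop the censored tail
  }))
  expect_gt(length(durs), 30)
  # E[X | X >= 30] = 630 for an exponential with mean 600 (memorylessness);
  # patch time also includes the short walk to the channel mouth
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 630), 3 * se + 20)
})

test_that("cohorts draw masses in range and are reproducible", {
  mz <- default_maze()
  spec <- cohort_spec(n = 6, seed = 9, mode = "events")
  coh <- simulate_cohort(spec, mz, duration = 21600)
  masses <- sapply(coh$individuals, `[[`, "mass_mg")
  expect_true(all(masses >= 0.6 & masses <= 12.41))
  coh2 <- simulate_cohort(spec, mz, duration = 21600)
  expect_identical(sapply(coh2$individuals, `[[`, "mass_mg"), masses)
  tab <- cohort_space_use(coh, mz)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$cumulative_space_m2, 0.01 * tab$n_resource_visits)
})

test_that("event-mode cohorts recover the allometric visit exponent", {
  mz <- default_maze()
  cover <- logical(40)
  for (r in 1:40) {
    spec <- cohort_spec(n = 24, seed = 1000 + r, mode = "events")
    tab <- cohort_space_use(simulate_cohort(spec, mz, 21600), mz)
    ok <- tab$cumulative_space_m2 > 0
    fit <- fit_scaling(tab$cumulative_space_m2[ok], tab$mass_mg[ok])
    cover[r] <- fit$exponent_ci[1] <= 0.77 && 0.77 <= fit$exponent_ci[2]
  }
  expect_gte(mean(cover), 0.85)
})

test_that("a mass-independent cohort yields a near-zero exponent", {
  mz <- default_maze()
  est <- sapply(1:20, function(r) {
    spec <- cohort_spec(n = 24, visit_exponent = 0, seed = 2000 + r,
                        mode = "events")
    tab <- cohort_space_use(simulate_cohort(spec, mz, 21600), mz)
    ok <- tab$cumulative_space_m2 > 0
    fit_scaling(tab$cumulative_space_m2[ok], tab$mass_mg[ok])$exponent
  })
  expect_lt(abs(mean(est)), 0.1)
})

test_that("the renderer produces the documented stack layout", {
  mz <- default_maze()
  sim <- simulate_individual(forager_params(), mz, duration = 0.4, seed = 4)
  rv <- render_video(sim$trajectory, mz, frame_size = c(128, 126),
                     noise_sd = 0, seed = 1)
  expect_equal(dim(rv$stack), c(126, 128, nrow(sim$trajectory)))
  expect_true(all(rv$stack >= 0 & rv$stack <= 255))
  expect_equal(nrow(rv$truth), nrow(sim$trajectory))
  # fixed seed: identical stacks even with pixel noise
  rva <- render_video(sim$trajectory, mz, frame_size = c(128, 126),
                      noise_sd = 2, seed = 11)
  rvb <- render_video(sim$trajectory, mz, frame_size = c(128, 126),
                      noise_sd = 2, seed = 11)
  expect_identical(rva$stack, rvb$stack)
  # zero contrast and zero noise: every frame is the clean plate
  rv0 <- render_video(sim$trajectory, mz, contrast = 0, noise_sd = 0,
                      frame_size = c(128, 126))
  expect_true(all(rv0$stack == as.vector(rv0$background)))
  expect_error(render_video(sim$trajectory, mz, body_length_px = 1),
               "body_length_px")
})
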