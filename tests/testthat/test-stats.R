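test_that("Kruskal-Wallis reproduces the defining rank formula", {
  kw <- kruskal_wallis(1:6, rep(1:2, each = 3))
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$df, 1)

  # two identically ranked groups: H = 0
  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_equal(same$H, 0, tolerance = 1e-12)

  # degenerate all-equal data
  flat <- kruskal_wallis(rep(5, 8), rep(1:2, each = 4))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)

  # random (tied) data against the hand-computed formula
  set.seed(41)
  for (rep in 1:20) {
    v <- sample(1:10, 30, replace = TRUE)
    g <- sample(1:3, 30, replace = TRUE)
    if (min(table(g)) == 0) next
    expect_equal(kruskal_wallis(v, g)$H, oracle_kw(v, g), tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(1:5, rep(1, 5)), "2 non-empty groups")
})

test_that("SRH reduces to Kruskal-Wallis on a one-factor tie-free layout", {
  set.seed(42)
  for (rep in 1:10) {
    v <- sample(1000, 24)            # tie-free
    g <- sample(rep(1:3, 8))
    srh <- scheirer_ray_hare(v, g, rep(1, 24))
    expect_equal(srh$H[1], kruskal_wallis(v, g)$H, tolerance = 1e-9)
    expect_true(is.na(srh$H[2]) && is.na(srh$H[3]))
  }
})

test_that("SRH handles degenerate and shifted two-factor layouts", {
  flat <- scheirer_ray_hare(rep(2, 12), rep(1:2, each = 6), rep(1:3, 4))
  expect_true(all(flat$H == 0))
  expect_true(all(flat$p == 1))

  # pure factor-A shift: H_A dominates, interaction stays near its null mean
  set.seed(43)
  HA <- HB <- HI <- numeric(200)
  for (r in 1:200) {
    A <- rep(c("lo", "hi"), each = 10)
    B <- rep(c("x", "y"), 10)
    v <- rnorm(20) + (A == "hi") * 3
    h <- scheirer_ray_hare(v, A, B)$H
    HA[r] <- h[1]; HB[r] <- h[2]; HI[r] <- h[3]
  }
  expect_gt(mean(HA), mean(HB) + 5)
  # B and the interaction stay far below A (the rank test is conservative
  # for the off-factors under a strong main effect, so no exact chi-square
  # calibration is expected here)
  expect_lt(mean(HB), 1.5)
  expect_lt(mean(HI), 1.5)
})

test_that("SRH holds its nominal type-I error under the null", {
  set.seed(44)
  reps <- 400
  rej <- matrix(NA, 3, reps)
  for (r in seq_len(reps)) {
    v <- rnorm(30)
    A <- rep(1:2, each = 15)
    B <- rep(rep(1:3, each = 5), 2)
    rej[, r] <- scheirer_ray_hare(v, A, B)$p < 0.05
  }
  rates <- rowMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.09))
})

test_that("scaling fit recovers exponents and flags bad input", {
  m <- seq(0.6, 12.41, length.out = 24)
  fit <- suppressWarnings(fit_scaling(2 * m^0.77, m))  # exact fit by design
  expect_equal(fit$exponent, 0.77, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # mass-independent response: CI covers zero
  set.seed(45)
  fit0 <- fit_scaling(exp(rnorm(24)), m)
  expect_true(fit0$exponent_ci[1] < 0 && fit0$exponent_ci[2] > 0)

  expect_error(fit_scaling(c(-1, 2, 3), c(1, 2, 3)), "rows: 1")
  expect_error(fit_scaling(1:2, 1:2), "3 observations")

  # ANCOVA-style covariate
  grp <- rep(c("high", "low"), 12)
  y <- 2 * m^0.77 * ifelse(grp == "high", 1.5, 1) * exp(rnorm(24, 0, 0.1))
  fitc <- fit_scaling(y, m, data.frame(resource = grp))
  expect_true("resource" %in% rownames(fitc$anova) ||
                any(grepl("resource", rownames(fitc$anova))))
  expect_lt(abs(fitc$exponent - 0.77), 0.2)
})

test_that("scaling-exponent CI coverage is nominal under lognormal noise", {
  set.seed(46)
  cover <- logical(200)
  for (r in 1:200) {
    m <- runif(24, 0.6, 12.41)
    y <- 2 * m^0.77 * exp(rnorm(24, 0, 0.4))
    ci <- fit_scaling(y, m)$exponent_ci
    cover[r] <- ci[1] <= 0.77 && 0.77 <= ci[2]
  }
  expect_gte(mean(cover), 0.9)
})

test_that("logistic occupancy model recovers a decaying resource preference", {
  set.seed(47)
  n <- 600
  tm <- runif(n); res <- rbinom(n, 1, 0.5)
  eta <- -1 + 2 * res - 2 * tm * res
  d <- data.frame(occupied = rbinom(n, 1, plogis(eta)), time = tm,
                  resource = res)
  fit <- fit_occupancy(d)
  or <- fit$odds_ratios
  expect_gt(or$odds_ratio[or$term == "resource"], 1)
  expect_lt(or$odds_ratio[or$term == "time:resource"], 1)
  expect_false(fit$separation)

  # null resource effect: CI covers an odds ratio of 1
  d0 <- data.frame(occupied = rbinom(n, 1, 0.4), time = tm, resource = res)
  or0 <- fit_occupancy(d0)$odds_ratios
  r0 <- or0[or0$term == "resource", ]
  expect_true(r0$ci_lower < 1 && r0$ci_upper > 1)

  # duplicating the data keeps estimates, narrows CIs
  fit2 <- fit_occupancy(rbind(d, d))
  expect_equal(fit2$odds_ratios$odds_ratio, or$odds_ratio, tolerance = 1e-6)
  width <- function(x) log(x$ci_upper) - log(x$ci_lower)
  expect_true(all(width(fit2$odds_ratios) < width(or) + 1e-9))

  # complete separation triggers the penalized fallback
  sep <- data.frame(occupied = rep(c(0, 1), each = 15),
                    time = rep(c(0, 1), each = 15),
                    resource = rep(c(0, 1), 15))
  fsep <- fit_occupancy(sep)
  expect_true(fsep$separation)
  expect_true(all(is.finite(fsep$odds_ratios$odds_ratio[1:2])))
  expect_error(fit_occupancy(d[1:10, ]), "20 observations")
})

test_that("coefficient of variation is sample SD over mean in percent", {
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_equal(round(coefficient_of_variation(c(8, 12)), 2), 28.28)
  set.seed(48)
  x <- rexp(50)
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})
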