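test_that("dprime matches its worked examples", {
  expect_equal(dprime(0.5, 0.2, 50)$dprime, 0)
  expect_equal(round(dprime(1, 0, 189)$dprime), 12)
  expect_equal(dprime(1, 0, 189)$dprime,
               0.5 / sqrt(0.5 * (106 / 189 - 0.5)^2), tolerance = 1e-12)
  # enumeration oracle: p(0.95, 64) = 39/64, then direct arithmetic
  expect_equal(dprime(0.75, 0.1, 64)$dprime,
               0.25 / sqrt(0.5 * (0.1^2 + (39 / 64 - 0.5)^2)),
               tolerance = 1e-12)
  expect_equal(round(dprime(0.75, 0.1, 64)$dprime, 2), 2.39)
  expect_error(dprime(1.5, 0, 10), "mu_acc")
})

test_that("dprime is monotone in accuracy, spread, and chance spread", {
  base <- dprime(0.8, 0.1, 64)$dprime
  expect_gt(dprime(0.85, 0.1, 64)$dprime, base)
  expect_lt(dprime(0.8, 0.15, 64)$dprime, base)
  # smaller n -> larger chance spread -> smaller d'
  expect_lt(dprime(0.8, 0.1, 32)$dprime, base)
})

test_that("significance flag requires d' > 2 and not below-chance", {
  expect_true(dprime(0.95, 0.02, 100)$significant)
  expect_false(dprime(0.95, 0.02, 100, below_chance = TRUE)$significant)
  expect_false(dprime(0.55, 0.2, 100)$significant)
})

test_that("bootstrap_dprime is seeded, degenerate-safe, and centered", {
  acc <- c(0.7, 0.8, 0.75, 0.9, 0.65, 0.85, 0.8, 0.7)
  b1 <- bootstrap_dprime(acc, 64, B = 500, seed = 4)
  b2 <- bootstrap_dprime(acc, 64, B = 500, seed = 4)
  expect_identical(b1$dprime, b2$dprime)
  expect_lt(b1$ci95[1], b1$ci95[2])

  expect_warning(bd <- bootstrap_dprime(rep(0.8, 8), 64, B = 50, seed = 1),
                 "degenerate")
  expect_true(all(bd$dprime == bd$plug_in))

  # replicate mean close to plug-in across simulated sessions
  set.seed(11)
  ok <- 0
  for (i in 1:20) {
    a <- pmin(1, pmax(0, rnorm(8, 0.75, 0.1)))
    b <- bootstrap_dprime(a, 80, B = 400, seed = i)
    if (abs(b$mean - b$plug_in) < 0.5 * sd(b$dprime)) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("Naka-Rushton fit recovers exact generating parameters", {
  ages <- seq(3, 48, length.out = 12)
  dp <- naka_rushton(ages, 6, 20, 2)
  fit <- fit_naka_rushton(ages, dp)
  expect_equal(fit$dmax, 6, tolerance = 1e-3)
  expect_equal(fit$a_half, 20, tolerance = 1e-3 * 20)
  expect_equal(fit$shape, 2, tolerance = 1e-3 * 2)
  # half-max identity
  expect_equal(naka_rushton(fit$a_half, fit$dmax, fit$a_half, fit$shape),
               fit$dmax / 2, tolerance = 1e-9)
  expect_error(fit_naka_rushton(1:3, 1:3), "at least 4")
})

test_that("fitted parameters respect their bounds on degenerate data", {
  ages <- seq(3, 48, length.out = 8)
  fit0 <- fit_naka_rushton(ages, rep(0, 8))
  expect_lte(fit0$dmax, 1e-6)
  expect_true(is.na(criterion_age(fit0)))
  set.seed(2)
  fit_hi <- fit_naka_rushton(ages, rep(20, 8) + rnorm(8, 0, 0.1))
  expect_lte(fit_hi$dmax, 12)
  expect_lte(fit_hi$shape, 4)
})

test_that("criterion_age inverts the curve analytically", {
  fit <- structure(list(dmax = 6, a_half = 20, shape = 2, d0 = 0),
                   class = "naka_rushton_fit")
  expect_equal(criterion_age(fit, 2), 20 * sqrt(2 / 4), tolerance = 1e-12)
  expect_equal(criterion_age(fit, 2), 14.14214, tolerance = 1e-5)
  expect_equal(criterion_age(fit, 3), 20)  # criterion = dmax/2 -> a_half
  fit$dmax <- 2
  expect_true(is.na(criterion_age(fit, 2)))
  fit$dmax <- 6
  fit$shape <- 0
  expect_true(is.na(criterion_age(fit, 2)))
  fit$shape <- 2
  expect_true(is.na(criterion_age(fit, 2, max_age = 10)))
  expect_equal(criterion_age(fit, 2, max_age = 20), criterion_age(fit, 2))
})

test_that("Eq-2 monotonicity holds for positive shapes", {
  ages <- seq(1, 60, by = 1)
  for (n in c(0.5, 1, 2, 4)) {
    d <- naka_rushton(ages, 6, 20, n)
    expect_true(all(diff(d) > 0))
  }
})

test_that("noisy trajectories still localize the criterion age", {
  # the full 100-replicate parameter-recovery bound lives in the acceptance
  # suite; here a smaller replicate count checks the criterion-age metric
  set.seed(21)
  ages <- seq(3, 48, length.out = 12)
  errs <- replicate(30, {
    f <- fit_naka_rushton(ages, naka_rushton(ages, 6, 20, 2) + rnorm(12, 0, 0.5))
    abs(criterion_age(f, 2) - 20 * sqrt(0.5))
  })
  expect_lte(median(errs, na.rm = TRUE), 2)
})

test_that("trajectory bootstrap produces criterion-age distributions", {
  set.seed(5)
  ages <- seq(4, 46, length.out = 8)
  sessions <- lapply(ages, function(a) {
    mu <- 0.5 + 0.45 * naka_rushton(a, 1, 16, 2)
    list(age = a, fold_accuracies = pmin(1, pmax(0, rnorm(8, mu, 0.05))),
         n = 120)
  })
  bt <- bootstrap_trajectory(sessions, B = 60, seed = 3)
  expect_length(bt$criterion_ages, 60)
  expect_false(is.na(bt$point_age))
  expect_true(bt$ci95[1] <= bt$ci95[2])
  b2 <- bootstrap_trajectory(sessions, B = 60, seed = 3)
  expect_identical(bt$criterion_ages, b2$criterion_ages)
})

test_that("compare_crossing_ages behaves under symmetry and separation", {
  set.seed(9)
  d1 <- structure(list(criterion_ages = rnorm(500, 20, 2)),
                  class = "trajectory_bootstrap")
  d1b <- structure(list(criterion_ages = rnorm(500, 20, 2)),
                   class = "trajectory_bootstrap")
  expect_lt(abs(compare_crossing_ages(d1, d1b) - 0.5), 0.08)  # symmetry
  d2 <- structure(list(criterion_ages = d1$criterion_ages + 0.001),
                  class = "trajectory_bootstrap")
  expect_equal(compare_crossing_ages(d2, d1), 0)   # all strictly older
  expect_equal(compare_crossing_ages(d1, d2), 1)
  # not-reached treated as infinitely old
  d3 <- structure(list(criterion_ages = rep(NA_real_, 500)),
                  class = "trajectory_bootstrap")
  expect_equal(compare_crossing_ages(d1, d3), 1)
  expect_error(compare_crossing_ages(
    structure(list(criterion_ages = numeric(0)), class = "trajectory_bootstrap"),
    d1), "empty")
})
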