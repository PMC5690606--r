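fake_glm <- function(t) structure(list(t = t), class = "glm_result")

test_that("voxel ranking keeps positive responders in t order", {
  rk <- suppressWarnings(rank_voxels(fake_glm(c(5, 3, -1, 4)), 1:4, truncate = 70))
  expect_equal(rk$voxels, c(1L, 4L, 2L))
  expect_false(rk$flagged)

  set.seed(1)
  rk2 <- suppressWarnings(rank_voxels(fake_glm(abs(rnorm(200)) + 0.1), 1:200))
  expect_length(rk2$voxels, 70)
  expect_true(all(diff(rk2$t) <= 0))

  expect_warning(rk3 <- rank_voxels(fake_glm(c(-1, -2, 0)), 1:3), "flagged")
  expect_length(rk3$voxels, 0)
  expect_true(rk3$flagged)
  expect_error(rank_voxels(fake_glm(1:3), integer(0)), "empty")
  # deterministic tie-break by ascending index
  rk4 <- rank_voxels(fake_glm(c(2, 2, 2)), 1:3, truncate = 2)
  expect_equal(rk4$voxels, c(1L, 2L))
})

test_that("pattern assembly applies the one-volume delay", {
  # block covering volumes 5-10 (onset 24 s, duration 36 s, TR 6)
  sched <- structure(data.frame(onset = c(0, 24, 60), duration = c(24, 36, 24),
                                trial_type = c("blank", "concentric_static", "blank")),
                     class = c("stim_schedule", "data.frame"))
  attr(sched, "total_duration") <- 84
  dat <- matrix(0, 2, 14)
  dat[, 6:11] <- 7   # signal sits one volume after the block
  dat[, 1:4] <- 1    # blank epoch + delay -> volumes 2:4 hold value 1... set all
  run <- structure(list(data = dat, tr = 6, schedule = sched,
                        voi = c("V1", "V1"), age = 1), class = "bold_run")
  rk <- structure(list(voxels = 1:2, t = c(1, 1), truncated_at = 70,
                       flagged = FALSE), class = "voxel_ranking")
  pm <- assemble_patterns(run, "stimulus_vs_blank", rk)
  a_row <- pm$x[pm$y == "a", , drop = FALSE]
  expect_equal(unname(a_row[1, ]), c(7, 7))  # means of volumes 6-11 exactly
})

test_that("separable classes give zero within- and positive between-class distance", {
  sess <- tiny_session(age = 40, seed = 2, n_cycles = 4, n_voxels = 10,
                       noise_sd = 0,
                       truth = ground_truth(
                         voi_params = list("V1" = list(dmax = 6, a_half = 5, n = 2)),
                         contrast_params = list(
                           dynamic_vs_static = list(dmax = 6, a_half = 5, n = 2))))
  # noise-free: dynamic and static patterns separate, repeats identical
  sess$glass$voi <- rep("V1", length(sess$glass$voi))
  rk <- structure(list(voxels = 1:10, t = rep(1, 10), truncated_at = 70,
                       flagged = FALSE), class = "voxel_ranking")
  pm <- assemble_patterns(sess$glass, "dynamic_vs_static", rk)
  xa <- pm$x[pm$y == "a", ]
  xb <- pm$x[pm$y == "b", ]
  expect_gt(sqrt(sum((colMeans(xa) - colMeans(xb))^2)), 0)
})

test_that("sessions lacking a pattern class are dropped for that contrast", {
  sess <- tiny_session(n_cycles = 2, n_voxels = 6)
  keep <- !grepl("^random", sess$glass$schedule$trial_type)
  sched2 <- sess$glass$schedule[keep, ]
  class(sched2) <- c("stim_schedule", "data.frame")
  attr(sched2, "total_duration") <- schedule_duration(sess$glass$schedule)
  run2 <- sess$glass
  run2$schedule <- sched2
  rk <- structure(list(voxels = 1:5, t = rep(1, 5), truncated_at = 70,
                       flagged = FALSE), class = "voxel_ranking")
  expect_message(pm <- assemble_patterns(run2, "structured_vs_random", rk),
                 "dropped")
  expect_null(pm)
})

test_that("chance_level matches exhaustive CDF enumeration and is monotone", {
  # independent oracle: cumulative sum of exact binomial pmf terms
  enum_chance <- function(n) {
    cdf <- cumsum(choose(n, 0:n) * 0.5^n)
    (which(cdf >= 0.95)[1] - 1) / n
  }
  for (n in c(2, 4, 17, 64, 100, 189)) {
    expect_equal(chance_level(n)$upper, enum_chance(n), info = n)
  }
  expect_equal(chance_level(100)$upper, 0.58)
  expect_equal(chance_level(4)$upper, 1)
  expect_equal(chance_level(64)$upper, 39 / 64)
  expect_equal(chance_level(189)$upper, 106 / 189)
  expect_equal(chance_level(100)$lower, 0.42)
  # approaches 0.5 from above
  lv <- vapply(c(10, 100, 1000, 10000), function(n) chance_level(n)$upper,
               numeric(1))
  expect_true(all(diff(lv) < 0))
  expect_lt(lv[4], 0.51)
})

test_that("cross-validation folds are disjoint, covering, and balanced", {
  pm <- make_patterns(n_pairs = 24, sep = 0, seed = 3)
  cv <- crossvalidate(pm, pool_size = 20, seed = 9)
  expect_length(cv$fold, pm$n)
  for (f in 1:8) {
    held <- which(cv$fold == f)
    expect_true(length(held) > 0)
    expect_equal(sum(pm$y[held] == "a"), sum(pm$y[held] == "b"))
  }
  expect_equal(sort(unlist(lapply(1:8, function(f) which(cv$fold == f)))),
               seq_len(pm$n))  # every pattern tested exactly once
})

test_that("separable patterns classify perfectly; below-chance data are flagged", {
  pm <- make_patterns(n_pairs = 16, sep = 5, seed = 4)
  cv <- crossvalidate(pm, pool_size = 20, seed = 1)
  expect_equal(cv$fold_accuracies, rep(1, 8))
  expect_false(cv$below_chance)
  expect_equal(dprime(cv$mu_acc, cv$sigma_acc, cv$n)$dprime > 2, TRUE)

  pm0 <- make_patterns(n_pairs = 16, sep = 0, seed = 5)
  cv0 <- crossvalidate(pm0, pool_size = 20, seed = 1)
  expect_true(cv0$mu_acc < chance_level(pm0$n)$upper + 0.2)  # sane range
  expect_error(crossvalidate(make_patterns(n_pairs = 4), pool_size = 5),
               "at least 8")
  expect_warning(crossvalidate(make_patterns(n_pairs = 10, n_vox = 5),
                               pool_size = 50, seed = 1), "truncated")
})

test_that("standardization is fit on training folds only (no leakage)", {
  pm <- make_patterns(n_pairs = 16, sep = 0.8, seed = 6)
  cv <- crossvalidate(pm, pool_size = 20, seed = 21)
  # reproduce fold 1 by hand from the returned assignment
  te <- cv$fold == 1
  xtr <- pm$x[!te, ]; xte <- pm$x[te, ]
  mu <- colMeans(xtr); sd_ <- apply(xtr, 2, sd); sd_[sd_ == 0] <- 1
  m <- svm_linear(scale(xtr, mu, sd_), pm$y[!te])
  acc1 <- mean(predict(m, scale(xte, mu, sd_)) == pm$y[te])
  expect_equal(cv$fold_accuracies[1], acc1)
})

test_that("accuracy trace rises and saturates for strong signal", {
  pm <- make_patterns(n_pairs = 16, n_vox = 30, sep = 1.5, seed = 7)
  cv <- crossvalidate(pm, pool_size = 30, seed = 2, trace = TRUE)
  expect_length(cv$trace, 30)
  expect_gt(mean(cv$trace[20:30]), mean(cv$trace[1:3]))
  expect_gt(mean(cv$trace[25:30]), chance_level(pm$n)$upper)
})

test_that("linear SVM solves a hand-checkable separable problem", {
  x <- matrix(c(-2, -1, 1, 2), 4, 1)
  y <- c("a", "a", "b", "b")
  m <- svm_linear(x, y, C = 100)
  expect_equal(predict(m, x), y)
  # maximum-margin separator for C -> Inf: w = 1, b = 0 (margin at +-1)
  expect_equal(m$b, 0, tolerance = 1e-3)
  expect_equal(m$w[1], 1, tolerance = 0.05)
  expect_error(svm_linear(x, rep("a", 4)), "two classes")
})
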