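test_that("elo_update matches the expectancy formula", {
  expect_equal(elo_update(1500, 1500, 100), c(1550, 1450))
  # derived: winner gain = k * (1 - 1 / (1 + 10^(-0.5)))
  gain <- 100 * (1 - 1 / (1 + 10^(-0.5)))
  u <- elo_update(1600, 1400, 100)
  expect_equal(u[1] - 1600, gain, tolerance = 1e-12)
  expect_equal(u[1] + u[2], 3000)  # conservation
  # symmetry: equal ratings always gain exactly k/2
  for (r in c(0, 1200, 1777.5)) {
    expect_equal(elo_update(r, r, 64)[1] - r, 32)
  }
  expect_error(elo_update(Inf, 1500, 10), "finite")
  expect_error(elo_update(1500, 1500, -1), "positive")
})

test_that("a single match gives 1550/1450 regardless of replay count", {
  m <- data.frame(winner_id = "a", loser_id = "b", judge_id = NA)
  r <- rate_items(m, rating_config(n_randomizations = 25, seed = 1))
  expect_equal(rating_of(r, c("a", "b")), c(a = 1550, b = 1450))
  expect_equal(r$ratings$sd, c(0, 0))
})

test_that("strict dominance survives every ordering (exhaustive oracle)", {
  # A beats B twice, B beats C twice, A beats C twice: 6 matches
  w <- c(1L, 1L, 2L, 2L, 1L, 1L)
  l <- c(2L, 2L, 3L, 3L, 3L, 3L)
  all_perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  all_perms <- all_perms[apply(all_perms, 1, function(p)
    length(unique(p)) == 6), ]
  expect_identical(nrow(all_perms), 720L)
  finals <- t(apply(all_perms, 1, function(p)
    replay_elo_r(w[p], l[p], 3)))
  expect_true(all(finals[, 1] > finals[, 2]))
  expect_true(all(finals[, 2] > finals[, 3]))
  # and the compiled mElo agrees with the mean over all orderings
  m <- data.frame(winner_id = letters[w], loser_id = letters[l])
  r <- rate_items(m, rating_config(n_randomizations = 2000, seed = 4))
  melo <- rating_of(r, c("a", "b", "c"))
  expect_equal(unname(melo), colMeans(finals), tolerance = 1)
})

test_that("ratings are conserved and shift with start_value", {
  lat <- stats::setNames(seq(1300, 1700, length.out = 20),
                         sprintf("i%02d", 1:20))
  m <- simulate_matches(lat, 600, seed = 2)
  r1 <- rate_items(m, rating_config(n_randomizations = 50, seed = 3))
  expect_equal(sum(r1$ratings$melo), 20 * 1500, tolerance = 1e-6)
  r2 <- rate_items(m, rating_config(start_value = 1800,
                                    n_randomizations = 50, seed = 3))
  expect_equal(r2$ratings$melo, r1$ratings$melo + 300, tolerance = 1e-6)
})

test_that("order averaging removes order sensitivity in expectation", {
  # a single Elo pass is order-dependent; mElo converges on the latent
  # ranking as matches accumulate (the order SD itself stays at the k
  # scale for plain Elo, so convergence is measured on the estimate)
  lat <- stats::setNames(seq(1300, 1700, length.out = 12),
                         sprintf("i%02d", 1:12))
  cor_at <- function(n) {
    m <- simulate_matches(lat, n, seed = 6)
    r <- rate_items(m, rating_config(n_randomizations = 60, seed = 6))
    stats::cor(rating_of(r, names(lat)), lat, method = "spearman")
  }
  expect_gt(cor_at(2400), cor_at(60))
  expect_gte(cor_at(2400), 0.95)
})

test_that("rate_items validates its input", {
  expect_error(rate_items(data.frame()), "empty")
  bad <- data.frame(winner_id = "a", loser_id = "a")
  expect_error(rate_items(bad), "differ")
  m <- data.frame(winner_id = "a", loser_id = "b")
  r <- rate_items(m, rating_config(n_randomizations = 2))
  expect_error(rating_of(r, "zzz"), "unknown item")
})

test_that("scale calibration recovers affine maps", {
  expect_equal(calibrate_scales(c(1, 2, 3), c(1, 2, 3))[1:3],
               list(slope = 1, intercept = 0, r2 = 1))
  cal <- calibrate_scales(c(1, 2, 3), c(3, 5, 7))
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 1)
  expect_equal(cal$r2, 1)
  expect_equal(cal$transform(10), 21)
  expect_error(calibrate_scales(rep(1, 5), 1:5), "zero variance")
  expect_error(calibrate_scales(1:2, 1:2), "3 shared")
})

test_that("noisy affine calibration lands in the OLS confidence interval", {
  # n = 21 shared items, like the two-survey overlap
  set.seed(32)
  old <- seq(1100, 1900, length.out = 21)
  new <- 0.8 * old + 150 + stats::rnorm(21, 0, 40)
  cal <- calibrate_scales(old, new)
  fit <- stats::lm(new ~ old)
  ci <- stats::confint(fit)["old", ]
  expect_gte(0.8, ci[1])
  expect_lte(0.8, ci[2])
  expect_equal(cal$slope, unname(stats::coef(fit)[2]))
})
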