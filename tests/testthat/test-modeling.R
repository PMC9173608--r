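test_that("correlation filter keeps everything when nothing is correlated", {
  set.seed(41)
  X <- matrix(stats::rnorm(300), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- stats::rnorm(100)
  expect_setequal(correlation_filter(X, y), c("a", "b", "c"))
})

test_that("duplicated and planted-trio columns resolve to one survivor", {
  set.seed(42)
  a <- stats::rnorm(200)
  X <- cbind(a = a, a_copy = a, z = stats::rnorm(200))
  y <- a + stats::rnorm(200, 0, 0.5)
  kept <- correlation_filter(X, y)
  expect_length(intersect(kept, c("a", "a_copy")), 1)
  expect_true("z" %in% kept)
  # planted trio: r(A, B) = 0.9, A more correlated with y -> B removed
  B <- 0.9 * a + sqrt(1 - 0.81) * stats::rnorm(200)
  X2 <- cbind(A = a, B = B)
  y2 <- a + stats::rnorm(200, 0, 0.3)
  expect_identical(correlation_filter(X2, y2), "A")
})

test_that("constant features are dropped with a warning", {
  X <- cbind(a = stats::rnorm(50), flat = rep(3, 50))
  expect_warning(kept <- correlation_filter(X, stats::rnorm(50)), "constant")
  expect_identical(kept, "a")
})

test_that("backward selection eliminates noise and covers the truth", {
  n_rep <- 200
  hits <- ci_cover <- logical(n_rep)
  set.seed(43)
  for (i in seq_len(n_rep)) {
    n <- 500
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    y <- 2 * x1 + stats::rnorm(n)
    m <- fit_feature_model(cbind(x1 = x1, x2 = x2), y)
    hits[i] <- !("x2" %in% m$terms) && ("x1" %in% m$terms)
    if (hits[i]) {
      # coefficient is on the standardized scale: truth = 2 * sd(x1)
      co <- m$coefficients[m$coefficients$term == "x1", ]
      truth <- 2 * stats::sd(x1)
      ci_cover[i] <- abs(co$estimate - truth) <= 1.96 * co$se
    }
  }
  # noise elimination and CI coverage are both ~95% events at alpha =
  # 0.05, so each marginal is asserted at 0.9 (their joint is ~0.90 by
  # construction and cannot meet a 0.95 bound)
  expect_gte(mean(hits), 0.9)
  expect_gte(mean(ci_cover[hits]), 0.9)
})

test_that("fully active designs leave an empty elimination trace", {
  set.seed(44)
  n <- 400
  X <- matrix(stats::rnorm(3 * n), ncol = 3,
              dimnames = list(NULL, c("p", "q", "r")))
  y <- X %*% c(2, -1.5, 1) + stats::rnorm(n, 0, 0.5)
  m <- fit_feature_model(X, drop(y))
  expect_length(m$elimination_trace, 0)
  expect_setequal(m$terms, c("p", "q", "r"))
  expect_gt(m$r2, 0.8)
  # invariant: every term in the final model is significant at alpha
  expect_true(all(m$coefficients$p <= m$alpha))
})

test_that("model guards against rank deficiency and tiny n", {
  set.seed(45)
  a <- stats::rnorm(30)
  expect_error(fit_feature_model(cbind(a = a, b = a), stats::rnorm(30)),
               "collinear|rank")
  expect_error(fit_feature_model(matrix(stats::rnorm(8), ncol = 4),
                                 stats::rnorm(2)), "n > p")
})

test_that("project_pca matches a hand 2x2 eigendecomposition", {
  set.seed(46)
  n <- 2000
  x1 <- stats::rnorm(n)
  x2 <- 0.6 * x1 + 0.8 * stats::rnorm(n)
  X <- cbind(f1 = x1, f2 = x2)
  y <- x1 + x2 + stats::rnorm(n, 0, 0.2)
  m <- fit_feature_model(X, y)
  pr <- project_pca(m, X)
  # hand eigendecomposition of the 2x2 correlation matrix:
  # eigenvalues 1 +- r
  r <- stats::cor(x1, x2)
  expect_equal(sort(pr$var_fraction, decreasing = TRUE),
               c((1 + r) / 2, (1 - r) / 2), tolerance = 1e-9)
  expect_lt(abs(stats::cov(pr$scores)[1, 2]), 1e-8)
})

test_that("cv plans keep species whole and folds balanced", {
  map <- stats::setNames(rep(sprintf("sp%02d", 1:23), times = 1:23),
                         sprintf("im%03d", seq_len(sum(1:23))))
  plan <- make_cv_plan(map, k = 5, seed = 2)
  # species integrity
  for (sp in unique(map)) {
    expect_length(unique(plan$fold[names(map)[map == sp]]), 1)
  }
  sizes <- table(plan$species_fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(make_cv_plan(map, 5, seed = 2)$fold, plan$fold)
  expect_error(make_cv_plan(stats::setNames("spA", "im1"), k = 5),
               "fewer species")
})

test_that("species aggregation computes max and mean correctly", {
  sc <- c(i1 = 1200, i2 = 1500, i3 = 1400, i4 = 1300)
  map <- c(i1 = "spA", i2 = "spA", i3 = "spA", i4 = "spB")
  out <- species_score(sc, map)
  a <- out[out$species == "spA", ]
  expect_equal(a$score_max, 1500)
  expect_equal(a$score_mean, mean(c(1200, 1500, 1400)))
  expect_equal(a$score, a$score_max)
  b <- out[out$species == "spB", ]
  expect_equal(b$score_max, b$score_mean)  # single image
  expect_true(all(out$score_max >= out$score_mean))
  expect_error(species_score(c(zz = 1), map), "unmapped")
  out_mean <- species_score(sc, map, mode = "mean")
  expect_equal(out_mean$score, out_mean$score_mean)
})
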