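test_that("bivariate Gaussian PCA matches the closed-form variance split", {
  set.seed(14)
  n <- 20000; rho <- 0.9
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  pca <- fit_pca(cbind(a = x, b = y), 2)
  # for standardized bivariate normal, PC1 carries (1 + rho) / 2
  expect_equal(pca$var_fraction[1], (1 + rho) / 2, tolerance = 0.01)
  expect_equal(sum(pca$var_fraction), 1, tolerance = 1e-12)
  S <- stats::cov(pca$scores)
  expect_lt(abs(S[1, 2]), 1e-8)
})

test_that("fit_pca validates shape and constant columns", {
  X <- cbind(a = stats::rnorm(10), flatline = rep(2, 10))
  expect_error(fit_pca(X), "flatline")
  expect_error(fit_pca(matrix(1:6, 2)), "rows")
})

test_that("unit-square corners land in the vertex stratum", {
  set.seed(21)
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  interior <- matrix(stats::runif(200, 0.2, 0.8), ncol = 2)
  X <- rbind(corners, interior)
  sel <- select_survey_set(X, n_vertex = 4, n_fill = 10, seed = 3)
  expect_setequal(sel$vertex_ids, 1:4)
  expect_length(intersect(sel$vertex_ids, sel$fill_ids), 0)
})

test_that("selection is exhaustive, deterministic and disjoint", {
  set.seed(22)
  X <- matrix(stats::rnorm(300), ncol = 3)
  full <- select_survey_set(X, 50, 50, seed = 1)
  expect_identical(full$selected, 1:100)
  s1 <- select_survey_set(X, 10, 20, seed = 5)
  s2 <- select_survey_set(X, 10, 20, seed = 5)
  expect_identical(s1, s2)
  expect_length(intersect(s1$vertex_ids, s1$fill_ids), 0)
  expect_length(s1$selected, 30)
  expect_error(select_survey_set(X, 80, 80, seed = 1), "more images")
})

test_that("collinear clouds fall back to per-axis extremes with a flag", {
  X <- cbind(1:50, 2 * (1:50))
  expect_warning(sel <- select_survey_set(X, 2, 2, seed = 1), "degenerate")
  expect_true(sel$degenerate_hull)
  expect_true(all(c(1, 50) %in% sel$hull_vertices))
})

test_that("support-function vertices are genuine hull vertices in 5D", {
  # 5-D hypercube corners plus interior points: the corners are the only
  # hull vertices, so the finder must return corners and nothing else
  set.seed(23)
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  interior <- matrix(stats::runif(200 * 5, 0.15, 0.85), ncol = 5)
  X <- rbind(corners, interior)
  hv <- reefaesth:::hull_vertex_indices(X, seed = 2)
  expect_true(all(hv <= nrow(corners)))     # no false positives
  expect_setequal(hv, seq_len(nrow(corners)))  # all 32 corners found
})

test_that("vertex stratification covers at least the hull of a random pick", {
  set.seed(24)
  trials <- 100
  wins <- vapply(seq_len(trials), function(i) {
    X <- matrix(stats::rnorm(120), ncol = 2)
    n_sel <- 20
    sel <- select_survey_set(X, n_vertex = 12, n_fill = n_sel - 12, seed = i)
    rnd <- sample(nrow(X), n_sel)
    area <- function(ix) {
      P <- X[ix, , drop = FALSE]
      h <- grDevices::chull(P)
      reefaesth:::polygon_area(P[h, , drop = FALSE])
    }
    area(rnd) <= area(sel$selected) + 1e-9
  }, logical(1))
  expect_true(all(wins))
})

test_that("coverage_check matches the closed-form circle lens", {
  set.seed(25)
  # identical groups: overlap ~ 1
  G <- matrix(stats::rnorm(600), ncol = 2)
  expect_gt(coverage_check(G, G, n_mc = 2e4, seed = 1), 0.99)
  # far-apart groups: overlap ~ 0
  expect_lt(coverage_check(G, sweep(G, 2, c(100, 0), "+"),
                           n_mc = 2e4, seed = 1), 0.01)
  # two unit circles centred 1 apart: Jaccard = lens / (2*pi - lens)
  r <- 1; d <- 1
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  jaccard <- lens / (2 * pi * r^2 - lens)
  # build groups whose 99% ellipses are unit circles at distance 1:
  # isotropic gaussians with sd = 1/sqrt(qchisq(.99, 2))
  s <- 1 / sqrt(stats::qchisq(0.99, 2))
  A <- matrix(stats::rnorm(4e4, 0, s), ncol = 2)
  B <- sweep(matrix(stats::rnorm(4e4, 0, s), ncol = 2), 2, c(d, 0), "+")
  est <- coverage_check(A, B, n_mc = 2e5, seed = 2)
  expect_equal(est, jaccard, tolerance = 0.05)
  expect_error(coverage_check(G[1:2, ], G), ">= 3 points")
})
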