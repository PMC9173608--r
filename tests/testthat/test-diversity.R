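test_that("species age reads pendant branch lengths", {
  cherry <- ape::read.tree(text = "(A:2,B:3);")
  expect_equal(species_age(cherry), c(A = 2, B = 3))
  # 5-tip hand-built tree: ages are the drawn pendant lengths
  tr <- ape::read.tree(
    text = "((A:1.5,B:0.5):1,((C:0.25,D:0.75):2,E:3):0.5);")
  expect_equal(species_age(tr),
               c(A = 1.5, B = 0.5, C = 0.25, D = 0.75, E = 3))
  # ultrametric bound: age <= depth
  st <- simulate_tree_with_trait(30, seed = 2)
  expect_true(all(species_age(st$tree) <= 1 + 1e-9))
  # zero-length pendant branch warns
  z <- ape::read.tree(text = "(A:0,B:1);")
  expect_warning(a <- species_age(z), "zero-length")
  expect_equal(a[["A"]], 0)
})

test_that("multi-tree age averages per species", {
  t1 <- ape::read.tree(text = "(A:2,B:3);")
  t2 <- ape::read.tree(text = "(B:1,A:4);")
  expect_equal(species_age(list(t1, t2)), c(A = 3, B = 2))
})

test_that("fair-proportion ED: two-tip case and conservation", {
  two <- ape::read.tree(text = "(A:1.2,B:3.4);")
  expect_equal(evolutionary_distinctiveness(two), c(A = 1.2, B = 3.4))
  set.seed(3)
  for (i in 1:25) {
    tr <- ape::rtree(sample(5:40, 1))
    ed <- evolutionary_distinctiveness(tr)
    expect_equal(sum(ed), sum(tr$edge.length), tolerance = 1e-12)
  }
})

test_that("ED matches a brute-force edge-sharing oracle on a 4-tip tree", {
  tr <- ape::read.tree(text = "(((A:1,B:2):3,C:4):2,D:7);")
  # oracle: enumerate every edge, divide its length by descendant count
  oracle <- c(A = 0, B = 0, C = 0, D = 0)
  n_tip <- 4
  for (i in seq_len(nrow(tr$edge))) {
    node <- tr$edge[i, 2]
    tips <- if (node <= n_tip) tr$tip.label[node]
      else ape::extract.clade(tr, node)$tip.label
    oracle[tips] <- oracle[tips] + tr$edge.length[i] / length(tips)
  }
  expect_equal(evolutionary_distinctiveness(tr)[names(oracle)], oracle)
  expect_error(evolutionary_distinctiveness(ape::unroot(ape::rtree(5))),
               "rooted")
})

test_that("pagels_lambda: star tree is flat and ties resolve to zero", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  set.seed(4)
  y <- stats::setNames(stats::rnorm(5), star$tip.label)
  s <- pagels_lambda(star, y, n_perm = 19, seed = 1)
  expect_equal(s$lambda, 0)
})

test_that("lambda ML agrees with the nlme/corPagel oracle", {
  skip_if_not_installed("nlme")
  st <- simulate_tree_with_trait(40, lambda_true = 0.7, seed = 11)
  f <- reefaesth:::fit_lambda_ml(
    reefaesth:::lambda_loglik_maker(ape::vcv(st$tree), st$trait))
  d <- data.frame(y = st$trait, sp = names(st$trait))
  g <- nlme::gls(y ~ 1, data = d,
                 correlation = ape::corPagel(0.5, st$tree, form = ~sp),
                 method = "ML")
  lam_oracle <- unname(stats::coef(g$modelStruct$corStruct,
                                   unconstrained = FALSE))
  expect_equal(f$lambda, lam_oracle, tolerance = 1e-3)
})

test_that("generic (non-ultrametric) likelihood path agrees with eigen path", {
  st <- simulate_tree_with_trait(25, lambda_true = 0.5, seed = 21)
  C <- ape::vcv(st$tree)
  ll_eigen <- reefaesth:::lambda_loglik_maker(C, st$trait)
  # force the Cholesky path by perturbing the diagonal infinitesimally
  C2 <- C
  diag(C2) <- diag(C2) + seq(0, 1e-6, length.out = nrow(C2))
  ll_chol <- reefaesth:::lambda_loglik_maker(C2, st$trait)
  for (lam in c(0, 0.3, 0.8, 1))
    expect_equal(ll_eigen(lam), ll_chol(lam), tolerance = 1e-4)
})

test_that("lambda input validation", {
  st <- simulate_tree_with_trait(10, seed = 1)
  bad <- st$trait; names(bad)[1] <- "nope"
  expect_error(pagels_lambda(st$tree, bad, n_perm = 9), "names")
  expect_error(pagels_lambda(ape::rtree(3), stats::rnorm(3), n_perm = 9),
               "4 tips")
})

test_that("Gower distances match the hand-computed 3-species table", {
  tab <- data.frame(species = c("s1", "s2", "s3"),
                    size = c(0, 5, 10),
                    habit = factor(c("reef", "reef", "pelagic")))
  attr(tab, "trait_types") <- c(size = "numeric", habit = "categorical")
  D <- gower_dist(tab)
  # hand: numeric range 10 -> |xi-xj|/10; categorical 0/1; mean of the two
  expect_equal(D["s1", "s2"], (0.5 + 0) / 2, tolerance = 1e-12)
  expect_equal(D["s1", "s3"], (1 + 1) / 2, tolerance = 1e-12)
  expect_equal(D["s2", "s3"], (0.5 + 1) / 2, tolerance = 1e-12)
  di <- gower_distinctiveness(tab)
  expect_equal(di[["s1"]], mean(c(0.25, 1)), tolerance = 1e-12)
})

test_that("Gower agrees with the cluster::daisy oracle on mixed data", {
  tt <- simulate_trait_table(15, 2, 2, 1, seed = 12)
  D <- gower_dist(tt)
  d2 <- as.matrix(cluster::daisy(tt[, -1], metric = "gower"))
  expect_equal(unname(D), unname(d2), tolerance = 1e-10)
  # bounds and symmetry
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("Gower reweights pairwise-missing columns", {
  tab <- data.frame(species = c("a", "b"),
                    x = c(0.2, NA), y = c(0, 1))
  attr(tab, "trait_types") <- c(x = "numeric", y = "numeric")
  D <- gower_dist(tab)
  expect_equal(D["a", "b"], 1)  # only y observed for the pair
  bad <- data.frame(species = c("a", "b"), x = c(NA, NA))
  attr(bad, "trait_types") <- c(x = "numeric")
  expect_error(gower_dist(bad), "all-missing")
})

test_that("PGLS: star tree reduces exactly to OLS", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(5)
  x <- stats::setNames(stats::rnorm(6), star$tip.label)
  y <- stats::setNames(2 * x + stats::rnorm(6), star$tip.label)
  res <- pgls_slope(star, x, y)
  ols <- stats::lm(y ~ x)
  expect_equal(res$slope, unname(stats::coef(ols)[2]), tolerance = 1e-10)
  expect_equal(res$p, summary(ols)$coefficients[2, 4], tolerance = 1e-8)
})

test_that("PGLS matches the explicit 3-tip matrix arithmetic", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  C <- ape::vcv(tr)
  x <- c(A = 1, B = 2, C = 4)
  y <- c(A = 2.2, B = 3.1, C = 7.9)
  X <- cbind(1, x[rownames(C)])
  beta <- solve(t(X) %*% solve(C) %*% X) %*% t(X) %*% solve(C) %*%
    y[rownames(C)]
  expect_equal(pgls_slope(tr, x, y)$slope, beta[2], tolerance = 1e-10)
})

test_that("harmonic-mean combination over trees", {
  expect_equal(harmonic_mean_p(rep(0.03, 7)), 0.03)
  expect_equal(harmonic_mean_p(c(0.01, 0.04)), 2 / (100 + 25))
  expect_error(harmonic_mean_p(c(0.5, 0)), "p-values")
  trees <- lapply(1:5, function(i) {
    st <- simulate_tree_with_trait(12, seed = 30 + i)
    st$tree
  })
  labs <- trees[[1]]$tip.label
  for (i in seq_along(trees)) trees[[i]]$tip.label <- labs
  set.seed(6)
  x <- stats::setNames(stats::rnorm(12), labs)
  y <- stats::setNames(3 * x + stats::rnorm(12, 0, 0.5), labs)
  res <- pgls_slope(trees, x, y)
  expect_equal(res$p, harmonic_mean_p(res$per_tree$p), tolerance = 1e-12)
  expect_equal(res$slope, mean(res$per_tree$slope))
})

test_that("group_compare reproduces the hand ANOVA decomposition", {
  # balanced 3 x 5 example, sums of squares by hand
  g <- rep(c("a", "b", "c"), each = 5)
  v <- c(10, 12, 11, 9, 13, 15, 14, 16, 13, 17, 20, 19, 21, 18, 22)
  gm <- mean(v)
  ssb <- 5 * sum((tapply(v, g, mean) - gm)^2)
  ssw <- sum((v - tapply(v, g, mean)[g])^2)
  F_hand <- (ssb / 2) / (ssw / 12)
  res <- group_compare(v, g)
  expect_equal(res$F, F_hand, tolerance = 1e-10)
  expect_lt(res$p, 0.001)
  expect_identical(nrow(res$tukey), 3L)
})

test_that("two-group Tukey equals the pooled two-sample t-test", {
  set.seed(7)
  v <- c(stats::rnorm(8, 0), stats::rnorm(9, 1))
  g <- rep(c("x", "y"), c(8, 9))
  res <- group_compare(v, g)
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$tukey$p.adj[1], tt$p.value, tolerance = 1e-8)
  expect_error(group_compare(1:5, rep("only", 5)), "2 groups")
  expect_error(group_compare(1:3, c("a", "a", "b")), "2 members")
})

test_that("identical group means give Tukey p ~ 1", {
  set.seed(8)
  base <- stats::rnorm(6)
  v <- c(base, base + 0, base)  # same values per group
  g <- rep(c("a", "b", "c"), each = 6)
  res <- group_compare(v, g)
  expect_true(all(res$tukey$p.adj > 0.999))
})
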