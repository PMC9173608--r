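# number of descendant tips below each node of a phylo tree
descendant_tip_counts <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  cnt <- integer(n_node)
  cnt[seq_len(n_tip)] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge)))
    cnt[po$edge[i, 1]] <- cnt[po$edge[i, 1]] + cnt[po$edge[i, 2]]
  cnt
}

#' Species age from pendant branch lengths
#'
#' The age of a species is the length of the terminal branch subtending
#' its tip (the time since it split from its sister lineage in the tree).
#' Root-to-tip distance would be constant on an ultrametric tree and
#' could not distinguish young from old species. When a set of trees is
#' supplied, ages are averaged per species across trees.
#'
#' @param tree an `ape::phylo`, or a `multiPhylo`/list of trees sharing
#'   tip labels.
#' @return Named numeric vector of ages (branch-length units).
#' @export
species_age <- function(tree) {
  if (inherits(tree, "multiPhylo") || (is.list(tree) && !inherits(tree, "phylo"))) {
    ages <- lapply(tree, species_age)
    labs <- names(ages[[1]])
    return(rowMeans(vapply(ages, function(a) a[labs], numeric(length(labs)))))
  }
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  tip_edge <- match(seq_len(n_tip), tree$edge[, 2])
  age <- tree$edge.length[tip_edge]
  if (any(age == 0)) warning("zero-length pendant branch(es); age 0")
  stats::setNames(age, tree$tip.label)
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Each branch's length is divided equally among the tips descending from
#' it; a species' ED is the sum of its shares along its root-to-tip path.
#' ED is high for species on long unshared branches. The shares of all
#' branches sum to the total tree length.
#'
#' @param tree a rooted `ape::phylo` with branch lengths, or a set of
#'   trees (averaged per species).
#' @return Named numeric vector of ED values.
#' @export
evolutionary_distinctiveness <- function(tree) {
  if (inherits(tree, "multiPhylo") || (is.list(tree) && !inherits(tree, "phylo"))) {
    eds <- lapply(tree, evolutionary_distinctiveness)
    labs <- names(eds[[1]])
    return(rowMeans(vapply(eds, function(a) a[labs], numeric(length(labs)))))
  }
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_input("tree must be rooted")
  if (is.null(tree$edge.length)) stop_input("tree must have branch lengths")
  n_tip <- length(tree$tip.label)
  cnt <- descendant_tip_counts(tree)
  acc <- numeric(n_tip + tree$Nnode)  # accumulated share from root
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))  # preorder: parents before children
  for (i in ord) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    acc[ch] <- acc[p] + po$edge.length[i] / cnt[ch]
  }
  stats::setNames(acc[seq_len(n_tip)], tree$tip.label)
}

# profiled multivariate-normal log-likelihood machinery for Pagel's lambda
lambda_loglik_maker <- function(C, y) {
  n <- length(y)
  d <- diag(C)
  ones <- rep(1, n)
  if (max(d) - min(d) < 1e-9 * max(d)) {
    # ultrametric: C_lambda diagonalizes in the eigenbasis of C
    e <- eigen(C, symmetric = TRUE)
    yt <- crossprod(e$vectors, y)
    it <- crossprod(e$vectors, ones)
    dep <- d[1]
    function(lambda) {
      w <- lambda * e$values + (1 - lambda) * dep
      if (any(w <= 0)) return(-Inf)
      mu <- sum(it * yt / w) / sum(it^2 / w)
      r <- yt - mu * it
      s2 <- sum(r^2 / w) / n
      -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    }
  } else {
    function(lambda) {
      Cl <- lambda_transform(C, lambda)
      L <- tryCatch(chol(Cl), error = function(e) NULL)
      if (is.null(L)) {
        Cl2 <- Cl + diag(1e-8 * mean(diag(Cl)), n)  # jitter once
        L <- tryCatch(chol(Cl2), error = function(e)
          stop_input("singular phylogenetic covariance"))
      }
      z <- backsolve(L, y, transpose = TRUE)
      o <- backsolve(L, ones, transpose = TRUE)
      mu <- sum(o * z) / sum(o^2)
      r <- z - mu * o
      s2 <- sum(r^2) / n
      -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(L))) + n)
    }
  }
}

fit_lambda_ml <- function(ll, tol = 1e-4) {
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, 1)
  vals <- c(ll(0), opt$objective, ll(1))
  best <- max(vals)
  # flat or tied likelihoods resolve toward lambda = 0
  pick <- which(vals >= best - 1e-8)[1]
  list(lambda = cand[pick], loglik = vals[pick], loglik0 = vals[1])
}

#' Pagel's lambda with a randomization p-value
#'
#' Lambda multiplies the off-diagonal entries of the Brownian tip
#' covariance (shared path lengths) while keeping the diagonal: 1 means
#' full phylogenetic signal, 0 none. The GLS mean and rate are profiled
#' out and lambda is estimated by maximum likelihood on `[0, 1]`
#' (tolerance 1e-4, ties resolved toward 0). The p-value is the add-one
#' permutation rank of the observed likelihood gain `ll(lambda_hat) -
#' ll(0)` among tip-label permutations of the trait.
#'
#' @param tree an `ape::phylo` (tips must match `names(trait)`).
#' @param trait named numeric vector.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return Object of class `signal_result`: `lambda`, `loglik`, `p`,
#'   `n_perm`.
#' @export
pagels_lambda <- function(tree, trait, n_perm = 999, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4) stop_input("need at least 4 tips")
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), tree$tip.label))
      stop_input("trait names must match tip labels")
    trait <- trait[tree$tip.label]
  } else if (length(trait) != n) {
    stop_input("trait length must equal number of tips")
  }
  C <- ape::vcv(tree)
  fit <- fit_lambda_ml(lambda_loglik_maker(C, trait))
  gain <- fit$loglik - fit$loglik0
  perm_gain <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    yp <- sample(trait)
    f <- fit_lambda_ml(lambda_loglik_maker(C, yp))
    f$loglik - f$loglik0
  }, numeric(1)))
  p <- (1 + sum(perm_gain >= gain)) / (n_perm + 1)
  structure(list(lambda = fit$lambda, loglik = fit$loglik, p = p,
                 n_perm = n_perm), class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("<signal_result: lambda = %.3f, p = %.4f (%d permutations)>\n",
              x$lambda, x$p, x$n_perm))
  invisible(x)
}

#' Gower distances and functional distinctiveness
#'
#' Mixed-type Gower dissimilarity with equal column weights: numeric
#' traits contribute range-normalized absolute differences, unordered
#' categoricals a 0/1 mismatch, ordinals their range-normalized integer
#' codes. Pairs with missing values reweight over the observed columns.
#' Functional distinctiveness `Di` is a species' mean distance to all
#' other species, bounded in `[0, 1]`.
#'
#' @param traits data.frame with a `species` column (or row names) and
#'   trait columns; column types taken from the `trait_types` attribute
#'   or inferred from the column classes.
#' @return For [gower_dist()], a symmetric distance matrix; for
#'   [gower_distinctiveness()], a named numeric vector `Di`.
#' @export
gower_dist <- function(traits) {
  df <- as.data.frame(traits)
  if ("species" %in% names(df)) {
    ids <- as.character(df$species)
    df$species <- NULL
  } else {
    ids <- rownames(df) %||% as.character(seq_len(nrow(df)))
  }
  n <- nrow(df)
  if (n < 2) stop_input("need at least 2 species")
  types <- attr(traits, "trait_types")
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (nm in names(df)) {
    v <- df[[nm]]
    if (all(is.na(v))) stop_input("all-missing trait column: ", nm)
    ty <- if (!is.null(types) && nm %in% names(types)) types[[nm]]
      else if (is.numeric(v)) "numeric"
      else if (is.ordered(v)) "ordinal" else "categorical"
    obs <- outer(!is.na(v), !is.na(v), "&")
    if (ty == "categorical") {
      d <- outer(as.character(v), as.character(v), "!=") * 1
    } else {
      x <- if (ty == "ordinal") as.numeric(v) else as.numeric(v)
      r <- diff(range(x, na.rm = TRUE))
      d <- if (r == 0) matrix(0, n, n) else abs(outer(x, x, "-")) / r
    }
    d[!obs] <- 0
    num <- num + d
    den <- den + obs
  }
  if (any(den == 0 & upper.tri(den)))
    stop_input("species pair(s) with no commonly observed trait")
  D <- num / pmax(den, 1)
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

#' @rdname gower_dist
#' @export
gower_distinctiveness <- function(traits) {
  D <- gower_dist(traits)
  stats::setNames(rowSums(D) / (nrow(D) - 1), rownames(D))
}

#' Harmonic-mean combination of dependent p-values
#'
#' Unweighted harmonic mean `n / sum(1 / p)`.
#' @param p vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
harmonic_mean_p <- function(p) {
  if (any(p <= 0 | p > 1)) stop_input("p-values must be in (0, 1]")
  length(p) / sum(1 / p)
}

#' Phylogenetic generalized least squares slope
#'
#' GLS regression of `y` on `x` with Brownian error covariance (shared
#' path lengths of the tree); on a star phylogeny this reduces exactly to
#' OLS. Over a set of trees, per-tree p-values are combined with the
#' unweighted harmonic mean and the slope averaged.
#'
#' @param tree an `ape::phylo` or a `multiPhylo`/list of trees.
#' @param x,y named numeric vectors aligned to tip labels.
#' @return For a single tree: list `slope`, `se`, `t`, `p`, `intercept`.
#'   For a tree set: list `slope` (mean), `p` (harmonic mean),
#'   `per_tree` (data.frame).
#' @export
pgls_slope <- function(tree, x, y) {
  if (inherits(tree, "multiPhylo") || (is.list(tree) && !inherits(tree, "phylo"))) {
    per <- lapply(tree, pgls_slope, x = x, y = y)
    slopes <- vapply(per, `[[`, numeric(1), "slope")
    ps <- vapply(per, `[[`, numeric(1), "p")
    return(list(slope = mean(slopes), p = harmonic_mean_p(ps),
                per_tree = data.frame(slope = slopes, p = ps)))
  }
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (!is.null(names(x))) x <- x[labs]
  if (!is.null(names(y))) y <- y[labs]
  n <- length(labs)
  if (length(x) != n || length(y) != n || anyNA(x) || anyNA(y))
    stop_input("x and y must align with the tree tips")
  C <- ape::vcv(tree)
  L <- tryCatch(chol(C), error = function(e)
    stop_input("phylogenetic covariance is not positive definite"))
  X <- cbind(1, x)
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  r <- yw - Xw %*% beta
  s2 <- sum(r^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(XtX)))
  tval <- beta[2] / se[2]
  list(slope = unname(beta[2]), se = unname(se[2]), t = unname(tval),
       p = 2 * stats::pt(-abs(tval), df = n - 2),
       intercept = unname(beta[1]))
}

#' One-way ANOVA with Tukey HSD contrasts
#'
#' Compares a species-level value (for example aesthetic score) across
#' category labels (IUCN groups, fishery-importance groups).
#'
#' @param values numeric vector.
#' @param groups factor or character labels (>= 2 groups, each with >= 2
#'   members).
#' @return List `F`, `p`, `tukey` (data.frame of pairwise comparisons
#'   with adjusted p-values), `fit` (the `aov` object).
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_input("need at least 2 groups")
  if (any(table(groups) < 2)) stop_input("every group needs >= 2 members")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       tukey = data.frame(comparison = rownames(tk), tk, row.names = NULL),
       fit = fit)
}
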