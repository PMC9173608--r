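#' Simulate a pure-birth tree with a lambda-structured trait
#'
#' Generates a binary pure-birth (Yule) tree, rescales it to unit depth,
#' and draws one continuous trait from a multivariate normal with
#' covariance `sigma2 * C_lambda`, where `C` is the Brownian shared
#' path-length matrix of the tree and `C_lambda` keeps the diagonal of `C`
#' while multiplying all off-diagonal entries by `lambda`. `lambda = 1` is
#' full Brownian structure, `lambda = 0` independent tips.
#'
#' @param n_tips number of tips (`>= 3`).
#' @param lambda_true phylogenetic signal parameter in `[0, 1]`.
#' @param sigma2 Brownian rate (positive).
#' @param seed integer seed.
#' @param tree optional existing ultrametric tree to draw the trait on
#'   (used to sample many trait replicates on one fixed topology);
#'   `NULL` simulates a fresh tree.
#' @return A list with elements `tree` (an ultrametric `ape::phylo` of unit
#'   depth) and `trait` (named numeric vector aligned to tip labels).
#' @export
simulate_tree_with_trait <- function(n_tips, lambda_true = 1, sigma2 = 1,
                                     seed = 1L, tree = NULL) {
  if (n_tips < 3) stop_input("`n_tips` must be >= 3")
  if (lambda_true < 0 || lambda_true > 1)
    stop_input("`lambda_true` must be in [0, 1]")
  if (sigma2 <= 0) stop_input("`sigma2` must be positive")
  with_seed(seed, {
    if (is.null(tree)) {
      tree <- ape::rphylo(n_tips, birth = 1, death = 0)
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length / depth
    }
    C <- ape::vcv(tree)
    Cl <- lambda_transform(C, lambda_true)
    L <- chol(sigma2 * Cl)
    trait <- drop(crossprod(L, stats::rnorm(n_tips)))
    names(trait) <- rownames(C)
    trait <- trait[tree$tip.label]
    list(tree = tree, trait = trait)
  })
}

# keep diag(C), multiply off-diagonals by lambda
lambda_transform <- function(C, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}
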