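Package: reefaesth
Title: Aesthetic Value of Reef Fishes from Pairwise Image Judgments
Version: 0.1.0
Authors@R:
    person("Reef", "Aesthetics Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to measure and analyse the aesthetic value of reef-fish
    images. Implements Elo scoring of pairwise image judgments with
    randomized match-order replay, a 17-feature image battery (CIELAB
    K-means colour segmentation, colour-pattern geometry, HSV tone
    statistics, elliptical Fourier outline shape), convex-hull stratified
    survey sampling in principal-component space, feature-based and
    image-based predictive models with species-grouped cross-validation,
    and evolutionary/ecological context metrics (species age,
    fair-proportion evolutionary distinctiveness, Pagel's lambda with
    randomization p-values, Gower functional distinctiveness,
    phylogenetic generalized least squares, ANOVA/Tukey group contrasts).
    A synthetic-data module generates procedural fish images, simulated
    pairwise matches, birth-death trees with lambda-structured traits and
    mixed-type trait tables so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    ape,
    igraph,
    cluster,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
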