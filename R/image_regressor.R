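# bilinear resize of one H x W plane to side x side
resize_plane <- function(M, side) {
  H <- nrow(M); W <- ncol(M)
  yi <- (seq_len(side) - 0.5) / side * H + 0.5
  xi <- (seq_len(side) - 0.5) / side * W + 0.5
  y0 <- pmin(pmax(floor(yi), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xi), 1L), W); x1 <- pmin(x0 + 1L, W)
  wy <- pmin(pmax(yi - y0, 0), 1); wx <- pmin(pmax(xi - x0, 0), 1)
  A <- M[y0, x0, drop = FALSE]; B <- M[y0, x1, drop = FALSE]
  C <- M[y1, x0, drop = FALSE]; D <- M[y1, x1, drop = FALSE]
  top <- A * (1 - wx)[col(A)] + B * wx[col(B)]
  bot <- C * (1 - wx)[col(C)] + D * wx[col(D)]
  top * (1 - wy)[row(top)] + bot * wy[row(bot)]
}

resize_image <- function(img, side) {
  px <- img$pixels
  out <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) out[, , ch] <- resize_plane(px[, , ch], side)
  out
}

# rotate an image array by `deg` degrees (nearest neighbour, white fill)
rotate_image_array <- function(a, deg) {
  if (deg == 0) return(a)
  side <- dim(a)[1]
  th <- deg * pi / 180
  ctr <- (side + 1) / 2
  g <- expand.grid(r = seq_len(side), c = seq_len(side))
  rs <- cos(th) * (g$r - ctr) - sin(th) * (g$c - ctr) + ctr
  cs <- sin(th) * (g$r - ctr) + cos(th) * (g$c - ctr) + ctr
  ri <- round(rs); ci <- round(cs)
  ok <- ri >= 1 & ri <= side & ci >= 1 & ci <= side
  out <- array(1, dim = dim(a))
  for (ch in 1:3) {
    plane <- a[, , ch]
    dst <- matrix(1, side, side)
    dst[cbind(g$r[ok], g$c[ok])] <- plane[cbind(ri[ok], ci[ok])]
    out[, , ch] <- dst
  }
  out
}

# 3x3 convolution, stride 2, ReLU: a is h x w x c_in, w_ is 3x3 x c_in x c_out
conv_block <- function(a, w_, bias) {
  h <- dim(a)[1]; w <- dim(a)[2]
  oi <- seq(2, h - 1, by = 2); oj <- seq(2, w - 1, by = 2)
  c_out <- dim(w_)[4]
  out <- array(0, dim = c(length(oi), length(oj), c_out))
  for (co in seq_len(c_out)) {
    acc <- matrix(bias[co], length(oi), length(oj))
    for (ci in seq_len(dim(a)[3]))
      for (di in -1:1)
        for (dj in -1:1)
          acc <- acc + w_[di + 2, dj + 2, ci, co] *
            a[oi + di, oj + dj, ci]
    out[, , co] <- pmax(acc, 0)  # ReLU
  }
  out
}

# frozen random-weight backbone: raw-channel means + GAP of two conv blocks
make_backbone <- function(channels = c(8L, 16L), seed = 1L) {
  with_seed(seed, {
    w1 <- array(stats::rnorm(3 * 3 * 3 * channels[1], sd = 0.5),
                dim = c(3, 3, 3, channels[1]))
    b1 <- stats::rnorm(channels[1], sd = 0.1)
    w2 <- array(stats::rnorm(3 * 3 * channels[1] * channels[2],
                             sd = sqrt(2 / (9 * channels[1]))),
                dim = c(3, 3, channels[1], channels[2]))
    b2 <- stats::rnorm(channels[2], sd = 0.1)
    list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
  })
}

backbone_features <- function(a, bk) {
  h1 <- conv_block(a, bk$w1, bk$b1)
  h2 <- conv_block(h1, bk$w2, bk$b2)
  c(apply(a, 3, mean), apply(h1, 3, mean), apply(h2, 3, mean))
}

# ridge head with unpenalized intercept
fit_ridge <- function(X, y, lambda) {
  mu <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, mu)
  A <- crossprod(Xc) + lambda * diag(ncol(X))
  beta <- solve(A, crossprod(Xc, y - ym))
  list(beta = beta, mu = mu, ym = ym)
}

predict_ridge <- function(head, X) {
  drop(sweep(X, 2, head$mu) %*% head$beta) + head$ym
}

#' Image-regression harness configuration
#'
#' @param side images are resized to `side x side` before the backbone
#'   (default 224, the conventional input side; the desk-scale smoke
#'   experiments use 64).
#' @param channels widths of the two convolutional blocks.
#' @param lambda_ridge ridge penalty of the regression head.
#' @param augment_deg half-range of the random rotation augmentation in
#'   degrees (0 disables augmentation; the survey-scale default is 5).
#' @param n_aug augmented copies per training image when `augment_deg > 0`.
#' @param seed integer seed (backbone weights, augmentation draws).
#' @return A list of class `regressor_config`.
#' @export
regressor_config <- function(side = 224, channels = c(8L, 16L),
                             lambda_ridge = 1e-3, augment_deg = 0,
                             n_aug = 1L, seed = 1L) {
  structure(list(side = as.integer(side), channels = as.integer(channels),
                 lambda_ridge = lambda_ridge, augment_deg = augment_deg,
                 n_aug = as.integer(n_aug), seed = as.integer(seed)),
            class = "regressor_config")
}

#' Cross-validated image regressor (frozen conv backbone + ridge head)
#'
#' The default backbone is a small randomly initialized convolutional
#' network (two 3x3/stride-2 ReLU blocks) kept frozen; only the
#' single-output regression head is trained, in closed form by ridge
#' regression — the transfer-learning structure (frozen features, tuned
#' last layer) at a scale trainable on one CPU in minutes. Optional
#' rotation augmentation adds rotated copies of the training images.
#' Validation r-squared is the squared Pearson correlation between
#' predictions and targets in each held-out fold; the final predictor is
#' refitted on all data.
#'
#' @param images named list of [masked_image()] objects.
#' @param targets named numeric vector aligned to image names (finite).
#' @param plan a [make_cv_plan()] for the images.
#' @param config a [regressor_config()].
#' @return Object of class `image_regressor`: `fold_r2`, `mean_r2`,
#'   `predictions` (out-of-fold), `backbone`, `head`, `config`.
#' @export
train_image_regressor <- function(images, targets, plan,
                                  config = regressor_config()) {
  stopifnot(inherits(plan, "cv_plan"))
  if (is.null(names(images))) stop_input("`images` must be named")
  if (!all(names(images) %in% names(plan$fold)))
    stop_input("plan is missing folds for some images")
  targets <- targets[names(images)]
  if (anyNA(targets) || !all(is.finite(targets)))
    stop_input("targets must be finite and cover all images")

  bk <- make_backbone(config$channels, config$seed)
  arrs <- lapply(images, resize_image, side = config$side)
  X <- t(vapply(arrs, backbone_features, bk = bk,
                numeric(3 + sum(config$channels))))
  if (!all(is.finite(X))) stop_input("divergence: non-finite features")

  folds <- plan$fold[names(images)]
  fold_r2 <- numeric(plan$k)
  preds <- stats::setNames(rep(NA_real_, length(images)), names(images))
  for (f in seq_len(plan$k)) {
    tr <- which(folds != f); va <- which(folds == f)
    if (length(unique(plan$fold[names(images)[va]])) < 1L || !length(va))
      stop_input("empty validation fold ", f)
    sp_tr <- unique(names(plan$species_fold)[plan$species_fold != f])
    if (length(sp_tr) < 2L) stop_input("fold with < 2 training species")
    Xtr <- X[tr, , drop = FALSE]; ytr <- targets[tr]
    if (config$augment_deg > 0 && config$n_aug > 0) {
      aug <- with_seed(config$seed + f, {
        lapply(seq_len(config$n_aug), function(r) {
          degs <- stats::runif(length(tr), -config$augment_deg,
                               config$augment_deg)
          t(vapply(seq_along(tr), function(i)
            backbone_features(rotate_image_array(arrs[[tr[i]]], degs[i]), bk),
            numeric(ncol(X))))
        })
      })
      Xtr <- rbind(Xtr, do.call(rbind, aug))
      ytr <- c(ytr, rep(targets[tr], config$n_aug))
    }
    head <- fit_ridge(Xtr, ytr, config$lambda_ridge)
    p <- predict_ridge(head, X[va, , drop = FALSE])
    preds[va] <- p
    yv <- targets[va]
    fold_r2[f] <- if (stats::sd(yv) == 0 || stats::sd(p) == 0) {
      warning("constant targets or predictions in fold ", f, "; r2 set to 0")
      0
    } else stats::cor(p, yv)^2
  }
  head_full <- fit_ridge(X, targets, config$lambda_ridge)
  structure(list(fold_r2 = fold_r2, mean_r2 = mean(fold_r2),
                 predictions = preds, backbone = bk, head = head_full,
                 config = config), class = "image_regressor")
}

#' @export
print.image_regressor <- function(x, ...) {
  cat(sprintf("<image_regressor: mean validation r2 = %.3f (folds: %s)>\n",
              x$mean_r2, paste(sprintf("%.2f", x$fold_r2), collapse = " ")))
  invisible(x)
}

#' Predict aesthetic scores for new images
#'
#' @param object an [train_image_regressor()] result.
#' @param newdata named list of [masked_image()] objects.
#' @param ... unused.
#' @return Named numeric vector of predicted scores.
#' @export
predict.image_regressor <- function(object, newdata, ...) {
  arrs <- lapply(newdata, resize_image, side = object$config$side)
  X <- t(vapply(arrs, backbone_features, bk = object$backbone,
                numeric(3 + sum(object$config$channels))))
  stats::setNames(predict_ridge(object$head, X), names(newdata))
}
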