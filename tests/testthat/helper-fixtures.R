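# -- shared fixtures, all generated in code ---------------------------------

# filled ellipse mask, semi-axes (rx, ry), canvas side n
ellipse_mask <- function(n, rx, ry, cx = n / 2, cy = n / 2) {
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), times = n), n)
  ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
}

disc_mask <- function(n, r, cx = n / 2, cy = n / 2) {
  ellipse_mask(n, r, r, cx, cy)
}

# flat-colour masked image on a mask
flat_image <- function(mask, rgb = c(0.5, 0.5, 0.5)) {
  n <- nrow(mask); m <- ncol(mask)
  px <- array(1, dim = c(n, m, 3))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- rgb[ch]
    px[, , ch] <- plane
  }
  masked_image(px, mask)
}

# independent flood-fill component counter (8-connectivity), the oracle
# against which igraph-based patch counting is checked
flood_fill_components <- function(hit) {
  n <- nrow(hit); m <- ncol(hit)
  seen <- matrix(FALSE, n, m)
  comps <- 0L
  for (start in which(hit & !seen)) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% n) + 1L
      cc <- ((cur - 1L) %/% n) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m) {
          j <- (c2 - 1L) * n + r2
          if (hit[j] && !seen[j]) {
            seen[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  comps
}

# plain-R Elo replay, the oracle for the compiled replay loop
replay_elo_r <- function(winner_idx, loser_idx, n_items, k = 100,
                         start = 1500) {
  r <- rep(start, n_items)
  for (i in seq_along(winner_idx)) {
    u <- elo_update(r[winner_idx[i]], r[loser_idx[i]], k)
    r[winner_idx[i]] <- u[1]
    r[loser_idx[i]] <- u[2]
  }
  r
}

# small striped fish used across feature tests
two_tone_fish <- function(n_stripes = 5, canvas = 160, seed = 1) {
  generate_fish_image(fish_spec(
    body_aspect = 2, n_stripes = n_stripes,
    palette = list(c(0.85, 0.15, 0.1), c(0.1, 0.2, 0.9)),
    canvas_px = canvas, seed = seed))
}
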