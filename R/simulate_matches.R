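#' Simulate pairwise aesthetic matches from latent scores
#'
#' Pairs of distinct items are drawn uniformly and the winner is sampled
#' from the Elo/Bradley-Terry expectancy on the base-10, 400-point scale:
#' `P(i beats j) = 1 / (1 + 10^((s_j - s_i) / 400))`. Latent scores and
#' downstream Elo estimates therefore share a scale, which keeps rating
#' recovery experiments interpretable.
#'
#' @param scores named numeric vector of latent scores (Elo scale); names
#'   are the item identifiers.
#' @param n_matches number of matches to simulate (`>= 1`).
#' @param seed integer seed.
#' @param judge_ids optional vector of judge labels to sample matches over.
#' @return A `data.frame` with columns `winner_id`, `loser_id`, `judge_id`.
#' @examples
#' m <- simulate_matches(c(a = 1600, b = 1400), 100, seed = 1)
#' mean(m$winner_id == "a")  # close to 10/11
#' @export
simulate_matches <- function(scores, n_matches, seed = 1L, judge_ids = NULL) {
  if (length(scores) < 2L) stop_input("need at least 2 items")
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop_input("`scores` must have unique names")
  if (!all(is.finite(scores))) stop_input("latent scores must be finite")
  if (n_matches < 1) stop_input("`n_matches` must be >= 1")
  n <- length(scores); ids <- names(scores)
  with_seed(seed, {
    i <- sample.int(n, n_matches, replace = TRUE)
    # uniform second item distinct from the first
    j <- sample.int(n - 1L, n_matches, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    p_i <- 1 / (1 + 10^((scores[j] - scores[i]) / 400))
    i_wins <- stats::runif(n_matches) < p_i
    w <- ifelse(i_wins, i, j); l <- ifelse(i_wins, j, i)
    judge <- if (is.null(judge_ids)) NA_character_ else
      as.character(sample(judge_ids, n_matches, replace = TRUE))
    data.frame(winner_id = ids[w], loser_id = ids[l], judge_id = judge,
               stringsAsFactors = FALSE)
  })
}

#' Read / write a match table
#'
#' CSV columns `winner_id,loser_id,judge_id`.
#' @param matches data.frame as returned by [simulate_matches()].
#' @param path CSV file path.
#' @export
write_matches <- function(matches, path) {
  utils::write.csv(matches[, c("winner_id", "loser_id", "judge_id")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!all(c("winner_id", "loser_id") %in% names(m)))
    stop_input("match CSV must have winner_id and loser_id columns")
  if (is.null(m$judge_id)) m$judge_id <- NA_character_
  m[, c("winner_id", "loser_id", "judge_id")]
}
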