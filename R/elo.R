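#' Single Elo rating update
#'
#' The winner's expected score is
#' `E = 1 / (1 + 10^((r_loser - r_winner) / 400))`; the winner gains
#' `k * (1 - E)` and the loser loses exactly the same amount, so the total
#' rating is conserved.
#'
#' @param r_winner,r_loser current ratings (finite).
#' @param k update constant (positive).
#' @return Numeric vector `c(winner, loser)` of updated ratings.
#' @examples
#' elo_update(1500, 1500, 100)  # c(1550, 1450)
#' @export
elo_update <- function(r_winner, r_loser, k) {
  if (!is.finite(r_winner) || !is.finite(r_loser) || !is.finite(k))
    stop_input("ratings and k must be finite")
  if (k <= 0) stop_input("`k` must be positive")
  e <- 1 / (1 + 10^((r_loser - r_winner) / 400))
  d <- k * (1 - e)
  c(r_winner + d, r_loser - d)
}

#' Rating configuration
#'
#' Defaults follow common pairwise-rating practice: all items start at
#' 1500 and k = 100. Neither value is dictated by the survey protocol, so
#' both are exposed here; the published score range (roughly 1,085-1,910,
#' centred near 1,500) is consistent with these defaults.
#'
#' @param start_value rating every item starts from.
#' @param k_factor Elo update constant (positive).
#' @param n_randomizations number of randomized match-order replays.
#' @param seed integer seed for the replay shuffles.
#' @param resample if `TRUE`, each replay draws matches with replacement
#'   (a bootstrap) instead of permuting the full list.
#' @return A list of class `rating_config`.
#' @export
rating_config <- function(start_value = 1500, k_factor = 100,
                          n_randomizations = 1000, seed = 1L,
                          resample = FALSE) {
  if (k_factor <= 0) stop_input("`k_factor` must be positive")
  if (n_randomizations < 1) stop_input("`n_randomizations` must be >= 1")
  structure(list(start_value = start_value, k_factor = k_factor,
                 n_randomizations = as.integer(n_randomizations),
                 seed = as.integer(seed), resample = isTRUE(resample)),
            class = "rating_config")
}

#' Estimate item ratings from pairwise matches (mElo)
#'
#' For each of `n_randomizations` replays the match list is shuffled
#' uniformly and replayed from `start_value` with [elo_update()]; the
#' per-item final ratings are averaged over replays (mElo) and their
#' spread reported as a standard deviation. Averaging over randomized
#' orders removes the order dependence of a single Elo pass. Judges are
#' pooled; ties are not representable (every match has a winner).
#'
#' @param matches data.frame with columns `winner_id`, `loser_id` (and
#'   optionally `judge_id`); winner and loser must differ in every row.
#' @param config a [rating_config()].
#' @return An object of class `elo_rating`: list with `ratings` (data.frame
#'   `item_id`, `melo`, `sd`), `config`, `n_matches`.
#' @export
rate_items <- function(matches, config = rating_config()) {
  stopifnot(inherits(config, "rating_config"))
  if (is.null(matches) || nrow(matches) == 0L)
    stop_input("empty match list")
  w <- as.character(matches$winner_id)
  l <- as.character(matches$loser_id)
  if (any(w == l)) stop_input("winner and loser must differ in every match")
  items <- sort(unique(c(w, l)))
  res <- with_seed(config$seed,
    elo_replay_cpp(match(w, items), match(l, items), length(items),
                   config$k_factor, config$start_value,
                   config$n_randomizations, config$resample))
  structure(list(ratings = data.frame(item_id = items, melo = res$melo,
                                      sd = res$sd, stringsAsFactors = FALSE),
                 config = config, n_matches = length(w)),
            class = "elo_rating")
}

#' @export
print.elo_rating <- function(x, ...) {
  cat(sprintf("<elo_rating: %d items, %d matches, %d randomizations>\n",
              nrow(x$ratings), x$n_matches, x$config$n_randomizations))
  print(utils::head(x$ratings))
  invisible(x)
}

#' Look up mElo scores for items
#'
#' @param rating an `elo_rating` object.
#' @param item_ids character vector of item identifiers.
#' @return Named numeric vector of mElo scores.
#' @export
rating_of <- function(rating, item_ids) {
  stopifnot(inherits(rating, "elo_rating"))
  i <- match(as.character(item_ids), rating$ratings$item_id)
  if (anyNA(i))
    stop_input("unknown item(s): ",
               paste(item_ids[is.na(i)], collapse = ", "))
  stats::setNames(rating$ratings$melo[i], item_ids)
}

#' Calibrate two rating scales through shared items
#'
#' Ordinary least squares of the new-survey scores on the old-survey
#' scores for the items evaluated in both; the fitted slope and intercept
#' map any old-scale score onto the new scale so the two datasets can be
#' merged.
#'
#' @param shared_scores_old,shared_scores_new equal-length numeric vectors
#'   (>= 3 shared items) of the shared items' scores in each survey.
#' @return List with `slope`, `intercept`, `r2`, and `transform`, a
#'   function mapping old-scale scores to the new scale.
#' @export
calibrate_scales <- function(shared_scores_old, shared_scores_new) {
  if (length(shared_scores_old) != length(shared_scores_new))
    stop_input("score vectors must have equal length")
  if (length(shared_scores_old) < 3L) stop_input("need >= 3 shared items")
  if (stats::sd(shared_scores_old) == 0)
    stop_input("degenerate fit: old scores have zero variance")
  fit <- stats::lm(shared_scores_new ~ shared_scores_old)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  list(slope = slope, intercept = intercept,
       r2 = summary(fit)$r.squared,
       transform = function(x) intercept + slope * x)
}

#' Read / write rating tables
#'
#' CSV columns `item_id,melo,sd`.
#' @param rating an `elo_rating` object.
#' @param path CSV file path.
#' @export
write_ratings <- function(rating, path) {
  utils::write.csv(rating$ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
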