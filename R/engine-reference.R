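# A deliberately naive per-agent engine used as an internal cross-check of
# the vectorized engine. It loops over voters everywhere and recomputes the
# report likelihoods from scratch at every contact, but consumes the random
# stream in the same documented order, so for the same seed it must produce
# an identical result.

ref_clamp <- function(x, lo, hi) {
  if (x < lo) lo else if (x > hi) hi else x
}

ref_likelihood <- function(trust, expertise, row) {
  trust * expertise * row[1] +
    trust * (1 - expertise) * row[2] +
    (1 - trust) * expertise * row[3] +
    (1 - trust) * (1 - expertise) * row[4]
}

#' Reference per-agent simulation engine
#'
#' A slow, loop-based implementation of [run_simulation()] kept for
#' verification: every voter is processed one at a time with scalar
#' arithmetic straight from the belief-revision formula. Intended for small
#' electorates; given the same configuration and seed it returns a result
#' identical to the vectorized engine.
#'
#' @param config A [run_config()].
#' @return An `election_run`, as from [run_simulation()].
#' @export
run_simulation_reference <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pc <- config$population
  if (!is.null(pc$seed)) set.seed(pc$seed)
  n <- pc$n_voters

  draw_field <- function(mean, sd, lo, hi) {
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- ref_clamp(rnorm(1, mean, sd), lo, hi)
    out
  }
  p_candidate <- draw_field(pc$belief_mean, pc$belief_sd, 0.01, 1)
  p_vote <- draw_field(pc$vote_mean, pc$vote_sd, 0.01, 1)
  trust_mtc <- draw_field(pc$cred_mean_mtc, pc$cred_sd, 0.01, 0.99)
  expertise_mtc <- draw_field(pc$cred_mean_mtc, pc$cred_sd, 0.01, 0.99)
  trust_stoch <- draw_field(pc$cred_mean_stoch, pc$cred_sd, 0.01, 0.99)
  expertise_stoch <- draw_field(pc$cred_mean_stoch, pc$cred_sd, 0.01, 0.99)
  cred_mtc <- numeric(n)
  cred_stoch <- numeric(n)
  for (i in seq_len(n)) {
    cred_mtc[i] <- (trust_mtc[i] + expertise_mtc[i]) / 2
    cred_stoch[i] <- (trust_stoch[i] + expertise_stoch[i]) / 2
  }

  rows <- table_rows(config$table)
  th <- config$thresholds

  for (t in seq_len(config$n_ticks)) {
    sels <- vector("list", length(config$candidates))
    for (k in seq_along(config$candidates)) {
      cand <- config$candidates[[k]]
      if (cand$strategy == "targeted") {
        cred <- if (cand$id == "mtc") cred_mtc else cred_stoch
        pool <- integer(0)
        for (i in seq_len(n)) {
          if (p_candidate[i] > th$belief_low && p_candidate[i] < th$belief_high &&
              cred[i] >= th$cred_min && p_vote[i] > th$vote_min) {
            pool <- c(pool, i)
          }
        }
      } else {
        pool <- seq_len(n)
      }
      sels[[k]] <- sample_pool(pool, cand$reach)
    }
    for (k in seq_along(config$candidates)) {
      cand <- config$candidates[[k]]
      for (i in sels[[k]]) {
        if (cand$id == "mtc") {
          l_h <- ref_likelihood(trust_mtc[i], expertise_mtc[i], rows$h)
          l_nh <- ref_likelihood(trust_mtc[i], expertise_mtc[i], rows$not_h)
        } else {
          l_h <- ref_likelihood(trust_stoch[i], expertise_stoch[i], rows$h)
          l_nh <- ref_likelihood(trust_stoch[i], expertise_stoch[i], rows$not_h)
        }
        if (cand$stance == "oppose") {
          l_h <- 1 - l_h
          l_nh <- 1 - l_nh
        }
        num <- p_candidate[i] * l_h
        den <- num + (1 - p_candidate[i]) * l_nh
        if (den > 0) p_candidate[i] <- num / den
      }
    }
  }

  cast <- logical(n)
  for (i in seq_len(n)) cast[i] <- runif(1) < p_vote[i]
  pref_mtc <- logical(n)
  for (i in seq_len(n)) pref_mtc[i] <- p_candidate[i] > 0.5
  for (i in seq_len(n)) {
    if (cast[i] && p_candidate[i] == 0.5) pref_mtc[i] <- runif(1) < 0.5
  }
  votes_mtc <- 0L
  votes_stoch <- 0L
  for (i in seq_len(n)) {
    if (cast[i]) {
      if (pref_mtc[i]) votes_mtc <- votes_mtc + 1L else votes_stoch <- votes_stoch + 1L
    }
  }
  total <- votes_mtc + votes_stoch

  voters <- tibble(
    voter_id = seq_len(n),
    p_candidate = p_candidate,
    p_vote = p_vote,
    trust_mtc = trust_mtc,
    expertise_mtc = expertise_mtc,
    trust_stoch = trust_stoch,
    expertise_stoch = expertise_stoch,
    cred_mtc = cred_mtc,
    cred_stoch = cred_stoch
  )
  result <- tibble(
    votes_mtc = votes_mtc,
    votes_stoch = votes_stoch,
    abstentions = n - total,
    turnout = total / n,
    share_mtc = if (total > 0) votes_mtc / total else NA_real_
  )
  result$final_belief_mean <- mean(p_candidate)
  structure(list(result = result, voters = voters, config = config),
            class = "election_run")
}
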