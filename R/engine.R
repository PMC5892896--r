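#' Configuration of one simulated campaign
#'
#' Bundles everything a single run needs: the electorate, the two candidate
#' specifications, the micro-targeting thresholds, the campaign length and
#' the conditional report table. One integer seed makes the whole run — the
#' population draw, every day's contact sampling, and the election-day
#' turnout and tie-break draws — reproducible.
#'
#' @param population A [population_config()].
#' @param candidates A list of two [candidate_spec()]s with distinct `id`s.
#'   They act in list order within each tick (contact lists are drawn, then
#'   belief updates applied, first for the first candidate).
#' @param thresholds A [targeting_thresholds()] used by targeted candidates.
#' @param n_ticks Number of campaign days before the election (default 50).
#' @param table A [credibility_table()].
#' @param seed Optional integer seed for the run.
#'
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(population_config(n_voters = 500), seed = 1)
#' @export
run_config <- function(population = population_config(),
                       candidates = list(mtc_candidate(20), stochastic_candidate(20)),
                       thresholds = targeting_thresholds(),
                       n_ticks = 50,
                       table = credibility_table(),
                       seed = NULL) {
  stopifnot(inherits(population, "population_config"),
            inherits(thresholds, "targeting_thresholds"))
  if (length(candidates) != 2L ||
      !all(vapply(candidates, inherits, logical(1), "candidate_spec"))) {
    abort("`candidates` must be a list of two candidate_spec objects.")
  }
  ids <- vapply(candidates, `[[`, character(1), "id")
  if (anyDuplicated(ids)) abort("The two candidates must have distinct ids.")
  n_ticks <- check_count(n_ticks, "n_ticks", min = 1L)
  table_rows(table) # validates
  structure(list(population = population, candidates = candidates,
                 thresholds = thresholds, n_ticks = n_ticks,
                 table = table, seed = seed),
            class = "run_config")
}

# Per-candidate stance-adjusted likelihood vectors for the whole electorate.
# Perceptions never change during a run, so these are computed once.
candidate_likelihoods <- function(candidate, voters, table) {
  if (candidate$id == "mtc") {
    lik <- marginal_likelihoods(voters$trust_mtc, voters$expertise_mtc, table)
  } else {
    lik <- marginal_likelihoods(voters$trust_stoch, voters$expertise_stoch, table)
  }
  if (candidate$stance == "oppose") {
    list(l_h = 1 - lik$p_rep_given_h, l_not_h = 1 - lik$p_rep_given_not_h)
  } else {
    list(l_h = lik$p_rep_given_h, l_not_h = lik$p_rep_given_not_h)
  }
}

# Bayes update of the belief vector at the contacted indices.
apply_contacts <- function(p, idx, lik) {
  if (length(idx) == 0L) return(p)
  prior <- p[idx]
  num <- prior * lik$l_h[idx]
  den <- num + (1 - prior) * lik$l_not_h[idx]
  post <- num / den
  zero <- den == 0
  if (any(zero)) post[zero] <- prior[zero]
  p[idx] <- post
  p
}

# Which rows pass the targeting screen, given the contacting candidate.
screen_rows <- function(candidate, p, voters, thresholds) {
  cred <- if (candidate$id == "mtc") voters$cred_mtc else voters$cred_stoch
  which(p > thresholds$belief_low & p < thresholds$belief_high &
          cred >= thresholds$cred_min & voters$p_vote > thresholds$vote_min)
}

# One campaign day on the belief vector: all contact lists are drawn from
# start-of-tick state (targeted pools screened on current beliefs), then
# updates are applied in candidate order.
tick_step <- function(p, voters, config, liks) {
  sels <- vector("list", length(config$candidates))
  for (k in seq_along(config$candidates)) {
    cand <- config$candidates[[k]]
    pool <- if (cand$strategy == "targeted") {
      screen_rows(cand, p, voters, config$thresholds)
    } else {
      seq_len(nrow(voters))
    }
    sels[[k]] <- sample_pool(pool, cand$reach)
  }
  for (k in seq_along(config$candidates)) {
    p <- apply_contacts(p, sels[[k]], liks[[k]])
  }
  p
}

#' Advance a campaign by one day
#'
#' Runs a single contact phase on a voter tibble: the targeted campaign
#' screens and samples its eligible pool, the broadcast campaign samples the
#' whole electorate, and every contacted voter replaces `p_candidate` with
#' the Bayesian posterior given the contacting candidate's message. Updates
#' are applied in candidate order, so a voter contacted by both campaigns
#' receives the two updates sequentially. Consumes the current R random
#' stream.
#'
#' @param voters A voter tibble.
#' @param config A [run_config()].
#' @return The voter tibble with updated `p_candidate`.
#' @export
run_tick <- function(voters, config) {
  liks <- lapply(config$candidates, candidate_likelihoods,
                 voters = voters, table = config$table)
  voters$p_candidate <- tick_step(voters$p_candidate, voters, config, liks)
  voters
}

#' Hold the election
#'
#' Each voter casts a ballot with probability `p_vote`; cast ballots go to
#' the micro-targeting candidate when `p_candidate > 0.5`, to the broadcast
#' candidate when `p_candidate < 0.5`, and are decided by a fair coin at
#' exactly 0.5. Turnout draws are made for all voters in id order, then the
#' tie-break coins in id order, off the current R random stream.
#'
#' @param voters A voter tibble.
#' @return A one-row tibble: `votes_mtc`, `votes_stoch`, `abstentions`,
#'   `turnout`, `share_mtc` (share of cast votes; `NA` if none are cast).
#' @export
hold_election <- function(voters) {
  n <- nrow(voters)
  cast <- runif(n) < voters$p_vote
  pref_mtc <- voters$p_candidate > 0.5
  ties <- which(cast & voters$p_candidate == 0.5)
  if (length(ties) > 0L) pref_mtc[ties] <- runif(length(ties)) < 0.5
  votes_mtc <- sum(cast & pref_mtc)
  votes_stoch <- sum(cast & !pref_mtc)
  total <- votes_mtc + votes_stoch
  tibble(
    votes_mtc = votes_mtc,
    votes_stoch = votes_stoch,
    abstentions = n - total,
    turnout = total / n,
    share_mtc = if (total > 0) votes_mtc / total else NA_real_
  )
}

#' Run one full simulated campaign
#'
#' Spin-up (population draw), `n_ticks` daily contact/update phases, then
#' the election. With a seed in the configuration the entire run is
#' reproducible; random draws occur in a documented fixed order (population
#' fields, then per tick the contact samples in candidate order, then the
#' election draws).
#'
#' @param config A [run_config()].
#' @return An object of class `election_run`: a list with `result` (one-row
#'   tibble of tallies plus `final_belief_mean`), `voters` (final voter
#'   state) and `config`. Supports [tidy()], [glance()] and `print()`.
#' @examples
#' run <- run_simulation(run_config(population_config(n_voters = 500), seed = 7))
#' glance(run)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  voters <- sample_population(config$population)
  liks <- lapply(config$candidates, candidate_likelihoods,
                 voters = voters, table = config$table)
  p <- voters$p_candidate
  for (t in seq_len(config$n_ticks)) {
    p <- tick_step(p, voters, config, liks)
  }
  voters$p_candidate <- p
  result <- hold_election(voters)
  result$final_belief_mean <- mean(p)
  structure(list(result = result, voters = voters, config = config),
            class = "election_run")
}

#' @export
print.election_run <- function(x, ...) {
  r <- x$result
  cat("Simulated election (", nrow(x$voters), " voters, ",
      x$config$n_ticks, " ticks)\n", sep = "")
  cat(sprintf("  MTC candidate:       %d votes\n", r$votes_mtc))
  cat(sprintf("  Broadcast candidate: %d votes\n", r$votes_stoch))
  cat(sprintf("  Abstentions:         %d\n", r$abstentions))
  cat(sprintf("  Turnout %.3f | MTC share of cast votes %.4f\n",
              r$turnout, r$share_mtc))
  invisible(x)
}

#' Tidy an election run into per-candidate rows
#'
#' @param x An `election_run`.
#' @param ... Unused.
#' @return A tibble with one row per candidate: `candidate`, `votes`,
#'   `vote_share`.
#' @method tidy election_run
#' @export
tidy.election_run <- function(x, ...) {
  r <- x$result
  total <- r$votes_mtc + r$votes_stoch
  tibble(
    candidate = c("mtc", "stochastic"),
    votes = c(r$votes_mtc, r$votes_stoch),
    vote_share = if (total > 0) c(r$votes_mtc, r$votes_stoch) / total
                 else c(NA_real_, NA_real_)
  )
}

#' One-row summary of an election run
#'
#' @param x An `election_run`.
#' @param ... Unused.
#' @return A one-row tibble with tallies, turnout, MTC vote share, the mean
#'   final belief, and the run dimensions.
#' @method glance election_run
#' @export
glance.election_run <- function(x, ...) {
  dplyr::bind_cols(
    x$result,
    tibble(n_voters = nrow(x$voters), n_ticks = x$config$n_ticks)
  )
}
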