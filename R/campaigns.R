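#' Candidate campaign specification
#'
#' A candidate is defined by a contact-selection strategy, the stance of the
#' message it sends about the hypothesis "the micro-targeting candidate is
#' the right choice", and a daily reach. The canonical two-candidate race
#' pairs [mtc_candidate()] (targeted selection, endorsing messages) against
#' [stochastic_candidate()] (uniform broadcast, opposing messages); the
#' constructor itself is unconstrained so that hybrid designs (e.g. a
#' targeted campaign with the filter switched off) can be studied.
#'
#' @param id `"mtc"` or `"stochastic"`; which candidate's perceived
#'   credibility the voters apply when updating.
#' @param strategy `"targeted"` (sample from the eligible pool) or
#'   `"broadcast"` (sample uniformly from the whole electorate).
#' @param stance `"endorse"` or `"oppose"`.
#' @param reach Number of voters contacted per tick (day).
#'
#' @return A list of class `candidate_spec`.
#' @examples
#' mtc_candidate(reach = 20)
#' stochastic_candidate(reach = 40)
#' @export
candidate_spec <- function(id = c("mtc", "stochastic"),
                           strategy = c("targeted", "broadcast"),
                           stance = c("endorse", "oppose"),
                           reach = 20) {
  id <- match.arg(id)
  strategy <- match.arg(strategy)
  stance <- match.arg(stance)
  reach <- check_count(reach, "reach", min = 0L)
  structure(list(id = id, strategy = strategy, stance = stance, reach = reach),
            class = "candidate_spec")
}

#' @rdname candidate_spec
#' @export
mtc_candidate <- function(reach = 20) {
  candidate_spec("mtc", "targeted", "endorse", reach)
}

#' @rdname candidate_spec
#' @export
stochastic_candidate <- function(reach = 20) {
  candidate_spec("stochastic", "broadcast", "oppose", reach)
}

#' Micro-targeting eligibility thresholds
#'
#' The screening rule of the micro-targeted campaign: contact only voters who
#' are persuadable (belief strictly between `belief_low` and `belief_high`),
#' perceive the candidate as credible (credibility score at least
#' `cred_min`, inclusive), and are likely to turn out (`p_vote` strictly
#' above `vote_min`).
#'
#' @param belief_low,belief_high Exclusive bounds of the persuadable belief
#'   range (defaults 0.25 and 0.75).
#' @param cred_min Inclusive minimum credibility score (default 0.5).
#' @param vote_min Exclusive minimum turnout propensity (default 0.5).
#' @return A list of class `targeting_thresholds`.
#' @examples
#' targeting_thresholds()
#' @export
targeting_thresholds <- function(belief_low = 0.25, belief_high = 0.75,
                                 cred_min = 0.5, vote_min = 0.5) {
  vals <- c(belief_low, belief_high, cred_min, vote_min)
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("Thresholds must be finite numbers.")
  }
  if (!(belief_low >= 0 && belief_low < belief_high && belief_high <= 1)) {
    abort("Need 0 <= belief_low < belief_high <= 1.")
  }
  structure(list(belief_low = belief_low, belief_high = belief_high,
                 cred_min = cred_min, vote_min = vote_min),
            class = "targeting_thresholds")
}

#' Voters eligible for micro-targeted contact
#'
#' Applies the screening predicate to the current population state: belief in
#' the open interval (`belief_low`, `belief_high`), credibility score for the
#' micro-targeting candidate at least `cred_min`, and turnout propensity
#' above `vote_min`.
#'
#' @param voters A voter tibble (see [sample_population()]).
#' @param thresholds A [targeting_thresholds()].
#' @return An integer vector of eligible `voter_id`s.
#' @examples
#' voters <- sample_population(population_config(n_voters = 100, seed = 1))
#' length(eligible_targets(voters))
#' @export
eligible_targets <- function(voters, thresholds = targeting_thresholds()) {
  stopifnot(inherits(thresholds, "targeting_thresholds"))
  if (nrow(voters) == 0L) abort("`voters` must be non-empty.")
  keep <- voters$p_candidate > thresholds$belief_low &
    voters$p_candidate < thresholds$belief_high &
    voters$cred_mtc >= thresholds$cred_min &
    voters$p_vote > thresholds$vote_min
  voters$voter_id[keep]
}

#' Select the voters a campaign contacts on one day
#'
#' A targeted campaign samples uniformly without replacement from the
#' eligible pool; a broadcast campaign samples uniformly without replacement
#' from the whole electorate. Either way no voter is contacted twice by the
#' same campaign on one day, while the two campaigns may both reach the same
#' voter. Draws come from the current R random-number stream.
#'
#' @param candidate A [candidate_spec()].
#' @param voters A voter tibble.
#' @param eligible Integer `voter_id`s of the eligible pool; required for a
#'   targeted candidate, ignored for broadcast.
#' @return An integer vector of at most `reach` voter ids.
#' @export
select_contacts <- function(candidate, voters, eligible = NULL) {
  stopifnot(inherits(candidate, "candidate_spec"))
  pool <- if (candidate$strategy == "targeted") {
    if (is.null(eligible)) abort("A targeted candidate needs an `eligible` pool.")
    eligible
  } else {
    voters$voter_id
  }
  sample_pool(pool, candidate$reach)
}
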