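#' Electorate sampling configuration
#'
#' Parameters of the heterogeneous voter population. Each voter draws a prior
#' candidate preference `p_candidate` and a turnout propensity `p_vote` from
#' normal distributions bounded to \[0.01, 1\], and an independent
#' trustworthiness and expertise perception of each candidate from normal
#' distributions bounded to \[0.01, 0.99\].
#'
#' @param n_voters Number of voters (default 10,000).
#' @param belief_mean,belief_sd Mean and sd of the initial belief draw
#'   (defaults 0.5, 0.25).
#' @param vote_mean,vote_sd Mean and sd of the turnout-propensity draw
#'   (defaults 0.5, 0.25).
#' @param cred_mean_mtc,cred_mean_stoch Means of the trust and expertise
#'   draws for the micro-targeting and the broadcast candidate; the study
#'   design varies these over \{0.4, 0.5, 0.6\}.
#' @param cred_sd Shared sd of the trust/expertise draws (default 0.25).
#' @param seed Optional integer seed; when supplied, [sample_population()]
#'   seeds the generator so the same configuration always yields the same
#'   population.
#'
#' @return A list of class `population_config`.
#' @examples
#' population_config(n_voters = 100, seed = 1)
#' @export
population_config <- function(n_voters = 10000,
                              belief_mean = 0.5, belief_sd = 0.25,
                              vote_mean = 0.5, vote_sd = 0.25,
                              cred_mean_mtc = 0.5, cred_mean_stoch = 0.5,
                              cred_sd = 0.25,
                              seed = NULL) {
  n_voters <- check_count(n_voters, "n_voters", min = 1L)
  vals <- c(belief_mean, belief_sd, vote_mean, vote_sd,
            cred_mean_mtc, cred_mean_stoch, cred_sd)
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("All population parameters must be finite numbers.")
  }
  if (belief_sd < 0 || vote_sd < 0 || cred_sd < 0) {
    abort("Standard deviations must be non-negative.")
  }
  structure(
    list(n_voters = n_voters,
         belief_mean = belief_mean, belief_sd = belief_sd,
         vote_mean = vote_mean, vote_sd = vote_sd,
         cred_mean_mtc = cred_mean_mtc, cred_mean_stoch = cred_mean_stoch,
         cred_sd = cred_sd, seed = seed),
    class = "population_config"
  )
}

#' Sample a heterogeneous voter population
#'
#' Draws the electorate described by a [population_config()]. Draws are made
#' in a fixed order — beliefs, turnout propensities, trust then expertise for
#' the micro-targeting candidate, trust then expertise for the broadcast
#' candidate — so a seed pins down the whole population. Beliefs and turnout
#' propensities are clamped to \[0.01, 1\]; source perceptions to
#' \[0.01, 0.99\].
#'
#' @param config A [population_config()].
#' @return A tibble with one row per voter: `voter_id`, `p_candidate`,
#'   `p_vote`, `trust_mtc`, `expertise_mtc`, `trust_stoch`,
#'   `expertise_stoch`, plus the derived credibility scores `cred_mtc` and
#'   `cred_stoch`.
#' @examples
#' voters <- sample_population(population_config(n_voters = 5, seed = 42))
#' voters
#' @export
sample_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_voters
  p_candidate <- clamp(rnorm(n, config$belief_mean, config$belief_sd), 0.01, 1)
  p_vote <- clamp(rnorm(n, config$vote_mean, config$vote_sd), 0.01, 1)
  trust_mtc <- clamp(rnorm(n, config$cred_mean_mtc, config$cred_sd), 0.01, 0.99)
  expertise_mtc <- clamp(rnorm(n, config$cred_mean_mtc, config$cred_sd), 0.01, 0.99)
  trust_stoch <- clamp(rnorm(n, config$cred_mean_stoch, config$cred_sd), 0.01, 0.99)
  expertise_stoch <- clamp(rnorm(n, config$cred_mean_stoch, config$cred_sd), 0.01, 0.99)
  tibble(
    voter_id = seq_len(n),
    p_candidate = p_candidate,
    p_vote = p_vote,
    trust_mtc = trust_mtc,
    expertise_mtc = expertise_mtc,
    trust_stoch = trust_stoch,
    expertise_stoch = expertise_stoch,
    cred_mtc = credibility_score(trust_mtc, expertise_mtc),
    cred_stoch = credibility_score(trust_stoch, expertise_stoch)
  )
}

#' Write or read a voter population as CSV
#'
#' The on-disk format keeps the seven primary per-voter columns
#' (`voter_id`, `p_candidate`, `p_vote`, `trust_mtc`, `expertise_mtc`,
#' `trust_stoch`, `expertise_stoch`); the derived credibility scores are
#' recomputed on read.
#'
#' @param voters A voter tibble from [sample_population()].
#' @param path File path.
#' @return `write_population()` returns `voters` invisibly;
#'   `read_population()` returns a voter tibble.
#' @export
write_population <- function(voters, path) {
  cols <- c("voter_id", "p_candidate", "p_vote",
            "trust_mtc", "expertise_mtc", "trust_stoch", "expertise_stoch")
  readr::write_csv(voters[cols], path)
  invisible(voters)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  voters <- readr::read_csv(path, col_types = readr::cols(
    voter_id = readr::col_integer(),
    .default = readr::col_double()
  ))
  dplyr::mutate(voters,
    cred_mtc = credibility_score(.data$trust_mtc, .data$expertise_mtc),
    cred_stoch = credibility_score(.data$trust_stoch, .data$expertise_stoch)
  )
}
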