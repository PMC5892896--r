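# Shared fixture builders. Everything is generated in code at test time.

# A hand-built voter tibble with full control over every field.
make_voters <- function(p_candidate, p_vote = 1,
                        trust_mtc = 0.6, expertise_mtc = 0.6,
                        trust_stoch = 0.6, expertise_stoch = 0.6) {
  n <- length(p_candidate)
  tibble::tibble(
    voter_id = seq_len(n),
    p_candidate = p_candidate,
    p_vote = rep_len(p_vote, n),
    trust_mtc = rep_len(trust_mtc, n),
    expertise_mtc = rep_len(expertise_mtc, n),
    trust_stoch = rep_len(trust_stoch, n),
    expertise_stoch = rep_len(expertise_stoch, n)
  ) |>
    dplyr::mutate(
      cred_mtc = (trust_mtc + expertise_mtc) / 2,
      cred_stoch = (trust_stoch + expertise_stoch) / 2
    )
}

# Independent oracle for the report likelihoods: explicit enumeration of the
# four (trust, expertise) states against the printed table rows.
oracle_likelihoods <- function(trust, expertise,
                               h = c(0.80, 0.58, 0.34, 0.18),
                               not_h = c(0.22, 0.42, 0.59, 0.71)) {
  states <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))
  lh <- 0
  lnh <- 0
  for (k in seq_along(states)) {
    wt <- if (states[[k]][1]) trust else 1 - trust
    we <- if (states[[k]][2]) expertise else 1 - expertise
    lh <- lh + wt * we * h[k]
    lnh <- lnh + wt * we * not_h[k]
  }
  c(lh, lnh)
}

# Independent oracle for the posterior: Bayes' rule written out directly.
oracle_posterior <- function(prior, lh, lnh, oppose = FALSE) {
  if (oppose) {
    lh <- 1 - lh
    lnh <- 1 - lnh
  }
  prior * lh / (prior * lh + (1 - prior) * lnh)
}

small_run_config <- function(n_voters = 200, seed = 1, mu_mtc = 0.6,
                             mu_stoch = 0.5, reach_mtc = 5, reach_stoch = 12,
                             n_ticks = 20) {
  run_config(
    population = population_config(n_voters = n_voters,
                                   cred_mean_mtc = mu_mtc,
                                   cred_mean_stoch = mu_stoch),
    candidates = list(mtc_candidate(reach_mtc),
                      stochastic_candidate(reach_stoch)),
    n_ticks = n_ticks,
    seed = seed
  )
}
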